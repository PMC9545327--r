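# Shared fixture builders for the suite. Everything is generated in code;
# no data files.

# A three-species tree with divergences of 10*Ne and 20*Ne generations:
# deep enough for near-complete lineage sorting.
deep_tree <- "((A:10000,B:10000):10000,C:20000);"

deep_config <- function(seed = 1, n_ind = 4, n_loci = 50, mu = 5e-6,
                        locus_length = 300, Ne = 1000, events = NULL,
                        f1 = NULL, missing_rate = 0, foundress = NA_real_) {
  sim_config(deep_tree,
             tibble::tibble(name = c("A", "B", "C"), n_individuals = n_ind,
                            Ne = Ne, foundress = foundress),
             n_loci = n_loci, locus_length = locus_length, mu = mu,
             events = events, f1_injections = f1,
             missing_rate = missing_rate, seed = seed)
}

one_pop_config <- function(seed = 1, n_ind = 1, Ne = 1000, n_loci = 1,
                           locus_length = 100, mu = 1e-6) {
  sim_config("A;", tibble::tibble(name = "A", n_individuals = n_ind, Ne = Ne),
             n_loci = n_loci, locus_length = locus_length, mu = mu, seed = seed)
}

# Phased toy alignment: named character vector -> locus_aln, with
# "<ind>_a1"/"<ind>_a2" labels already in the names.
toy_aln <- function(..., locus_id = "toy") {
  locus_aln(locus_id, c(...))
}

# Independent brute-force oracles ---------------------------------------

# pi by explicit enumeration of all pairs
oracle_pi <- function(mat) {
  n <- nrow(mat)
  vals <- c()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- mat[i, ] %in% c("A", "C", "G", "T") & mat[j, ] %in% c("A", "C", "G", "T")
    vals <- c(vals, if (sum(ok) == 0) 0 else sum(mat[i, ok] != mat[j, ok]) / sum(ok))
  }
  mean(vals)
}

oracle_seg_sites <- function(mat) {
  sum(vapply(seq_len(ncol(mat)), function(j) {
    b <- mat[, j]
    length(unique(b[b %in% c("A", "C", "G", "T")])) >= 2
  }, logical(1)))
}

# mid-ranks by hand (average position of tied values), then Pearson by the
# textbook sums formula
oracle_spearman_rho <- function(x, y) {
  midrank <- function(v) {
    r <- numeric(length(v))
    for (u in unique(v)) {
      pos <- which(v == u)
      sorted_below <- sum(v < u)
      r[pos] <- mean(sorted_below + seq_along(pos))
    }
    r
  }
  rx <- midrank(x); ry <- midrank(y)
  n <- length(x)
  num <- sum(rx * ry) - n * mean(rx) * mean(ry)
  den <- sqrt((sum(rx^2) - n * mean(rx)^2) * (sum(ry^2) - n * mean(ry)^2))
  num / den
}

# Split test by graph bipartition: drop one edge from the tree graph and
# read off the connected component tip sets.
oracle_is_split <- function(tree, tips) {
  ntip <- ape::Ntip(tree)
  edges <- tree$edge
  nodes <- sort(unique(as.vector(edges)))
  for (drop in seq_len(nrow(edges))) {
    adj <- edges[-drop, , drop = FALSE]
    # BFS from one endpoint of the dropped edge
    comp <- edges[drop, 1]
    repeat {
      nb <- unique(c(adj[adj[, 1] %in% comp, 2], adj[adj[, 2] %in% comp, 1]))
      new <- setdiff(nb, comp)
      if (length(new) == 0) break
      comp <- c(comp, new)
    }
    side <- tree$tip.label[intersect(comp, seq_len(ntip))]
    if (setequal(side, tips) || setequal(setdiff(tree$tip.label, side), tips)) {
      return(TRUE)
    }
  }
  FALSE
}
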