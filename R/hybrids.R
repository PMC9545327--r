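#' Diagnostic loci between two parental species
#'
#' A SNP is diagnostic when the minor-allele frequency difference
#' between the two parental panels (computed on non-missing genotypes)
#' is at least `min_freq_diff`; the default 1.0 demands fixed
#' differences. The returned orientation records which allele is
#' characteristic of `parentB`, which is what the hybrid index counts.
#'
#' @param snps A `snp_tbl` from [extract_unlinked_snps()].
#' @param map Species-map tibble.
#' @param parentA,parentB Species labels; each needs >= 2 individuals
#'   with data.
#' @param min_freq_diff Minimum absolute frequency difference, in
#'   (0, 1]. Default 1.0.
#' @return Tibble with `locus`, `freq_a`, `freq_b` (minor-allele
#'   frequencies per panel), `diff`, and `b_allele` (`"minor"` or
#'   `"major"`): which allele marks parentB ancestry. Empty (with a
#'   warning) when nothing qualifies.
#' @export
diagnostic_loci <- function(snps, map, parentA, parentB, min_freq_diff = 1.0) {
  stopifnot(min_freq_diff > 0, min_freq_diff <= 1)
  m <- snp_matrix(snps)
  sp <- map$species[match(rownames(m), map$individual)]
  for (p in c(parentA, parentB)) {
    if (sum(sp == p, na.rm = TRUE) < 2) {
      abort(sprintf("parent species '%s' needs >= 2 individuals in the SNP table", p))
    }
  }
  fa <- colMeans(m[sp == parentA, , drop = FALSE], na.rm = TRUE) / 2
  fb <- colMeans(m[sp == parentB, , drop = FALSE], na.rm = TRUE) / 2
  ok <- !is.nan(fa) & !is.nan(fb) & abs(fa - fb) >= min_freq_diff
  out <- tibble(locus = colnames(m)[ok], freq_a = unname(fa[ok]),
                freq_b = unname(fb[ok]), diff = unname(abs(fa - fb)[ok]),
                b_allele = ifelse(fb[ok] > fa[ok], "minor", "major"))
  if (nrow(out) == 0) {
    warn(sprintf("no diagnostic loci between '%s' and '%s' at min_freq_diff = %g",
                 parentA, parentB, min_freq_diff))
  }
  out
}

#' Hybrid index and interspecific heterozygosity per individual
#'
#' Over the diagnostic loci with data for an individual, the hybrid
#' index is the fraction of allele copies carrying the parentB
#' diagnostic allele (0 = pure parentA, 1 = pure parentB, 0.5 for a
#' true F1) and `het` is the fraction of those loci at which the
#' individual is heterozygous. An F1 daughter should sit at (0.5, 1);
#' a first-generation backcross to A at roughly (0.25, 0.5).
#'
#' @param snps A `snp_tbl`.
#' @param diagnostics Tibble from [diagnostic_loci()].
#' @param individuals Individuals to score (default: all rows of
#'   `snps`).
#' @return Tibble with `individual`, `hybrid_index`, `het`,
#'   `n_diagnostic` (loci with data; index/het NA when 0).
#' @export
hybrid_scores <- function(snps, diagnostics, individuals = NULL) {
  m <- snp_matrix(snps)
  if (is.null(individuals)) individuals <- rownames(m)
  loci <- intersect(diagnostics$locus, colnames(m))
  d <- diagnostics[match(loci, diagnostics$locus), ]
  purrr::map_dfr(individuals, function(ind) {
    g <- m[ind, loci]
    has <- !is.na(g)
    n <- sum(has)
    if (n == 0) {
      return(tibble(individual = ind, hybrid_index = NA_real_,
                    het = NA_real_, n_diagnostic = 0L))
    }
    b_copies <- ifelse(d$b_allele[has] == "minor", g[has], 2 - g[has])
    tibble(individual = ind,
           hybrid_index = sum(b_copies) / (2 * n),
           het = mean(g[has] == 1),
           n_diagnostic = as.integer(n))
  })
}

#' Classify scored individuals as pure, F1-like or backcross-like
#'
#' Deterministic windows on (hybrid index, heterozygosity): pure when
#' the index falls at or below `pure_max` or at or above `1 -
#' pure_max`; F1-like inside the `f1_index` window with `het >=
#' f1_het`; everything else backcross-like. Individuals with fewer than
#' `min_diagnostic` informative loci are ambiguous regardless of their
#' scores.
#'
#' @param scores Tibble from [hybrid_scores()].
#' @param parentA,parentB Species labels recorded on the calls.
#' @param f1_index Hybrid-index window for F1 calls (default
#'   `c(0.4, 0.6)`).
#' @param f1_het Minimum heterozygosity for an F1 call (default 0.9).
#' @param pure_max Maximum index for a pure call at either end
#'   (default 0.05).
#' @param min_diagnostic Minimum informative loci for any
#'   non-ambiguous call (default 20).
#' @return `scores` with added `parentA`, `parentB` and `klass`
#'   (`pure-A`, `pure-B`, `F1-like`, `backcross-like`, `ambiguous`).
#' @export
classify_hybrids <- function(scores, parentA = "A", parentB = "B",
                             f1_index = c(0.4, 0.6), f1_het = 0.9,
                             pure_max = 0.05, min_diagnostic = 20L) {
  klass <- dplyr::case_when(
    scores$n_diagnostic < min_diagnostic ~ "ambiguous",
    scores$hybrid_index <= pure_max ~ "pure-A",
    scores$hybrid_index >= 1 - pure_max ~ "pure-B",
    scores$hybrid_index >= f1_index[1] & scores$hybrid_index <= f1_index[2] &
      scores$het >= f1_het ~ "F1-like",
    TRUE ~ "backcross-like")
  dplyr::mutate(scores, parentA = parentA, parentB = parentB, klass = klass)
}

#' Run the full admixture screen for one species pair
#'
#' Subsets the alignments to the two parental species plus any putative
#' hybrids, applies the completeness filter within that subset (the
#' same per-system processing used for host-sharing wasp systems),
#' extracts unlinked SNPs, finds diagnostic loci and classifies every
#' individual.
#'
#' @param alignments Named list of phased [locus_aln()] objects.
#' @param map Species-map tibble.
#' @param parentA,parentB Parental species labels.
#' @param extra_individuals Additional individuals (e.g. suspected
#'   hybrids) to include and score.
#' @param threshold Completeness threshold within the subset (default
#'   0.70).
#' @param min_freq_diff,seed,... Passed to [diagnostic_loci()],
#'   [extract_unlinked_snps()] and [classify_hybrids()].
#' @return List of class `hyb_screen`: `calls` (classified tibble),
#'   `diagnostics`, `snps`, `pca` (a [snp_pca()] of the subset),
#'   `parentA`, `parentB`.
#' @export
screen_pair <- function(alignments, map, parentA, parentB,
                        extra_individuals = character(), threshold = 0.70,
                        min_freq_diff = 1.0, seed = 1L, ...) {
  inds <- c(map$individual[map$species %in% c(parentA, parentB)],
            extra_individuals)
  sub_map <- map[map$individual %in% inds, ]
  sub_aln <- lapply(alignments, function(aln) {
    keep <- strip_allele(aln_labels(aln)) %in% inds
    if (sum(keep) < 2) return(NULL)
    locus_aln(aln$locus_id, aln$mat[keep, , drop = FALSE])
  })
  sub_aln <- sub_aln[!vapply(sub_aln, is.null, logical(1))]
  sub_aln <- filter_by_completeness(sub_aln, sub_map, threshold, quiet = TRUE)
  snps <- extract_unlinked_snps(sub_aln, sub_map, seed = seed)
  diags <- diagnostic_loci(snps, sub_map, parentA, parentB,
                           min_freq_diff = min_freq_diff)
  scores <- hybrid_scores(snps, diags)
  calls <- classify_hybrids(scores, parentA, parentB, ...)
  calls$species <- sub_map$species[match(calls$individual, sub_map$individual)]
  pca <- if (ncol(snps) > 1 && nrow(snps) >= 2) snp_pca(snps, sub_map) else NULL
  structure(list(calls = calls, diagnostics = diags, snps = snps, pca = pca,
                 parentA = parentA, parentB = parentB),
            class = "hyb_screen")
}

#' @export
print.hyb_screen <- function(x, ...) {
  cat(sprintf("<hyb_screen> %s vs %s: %d diagnostic loci\n",
              x$parentA, x$parentB, nrow(x$diagnostics)))
  print(table(x$calls$klass))
  invisible(x)
}

#' @rdname screen_pair
#' @param object A `hyb_screen`.
#' @export
autoplot.hyb_screen <- function(object, ...) {
  ggplot2::ggplot(object$calls,
                  ggplot2::aes(.data$hybrid_index, .data$het,
                               colour = .data$klass)) +
    ggplot2::geom_point(size = 2, na.rm = TRUE) +
    ggplot2::xlim(0, 1) + ggplot2::ylim(0, 1) +
    ggplot2::labs(x = sprintf("hybrid index (fraction %s alleles)", object$parentB),
                  y = "interspecific heterozygosity") +
    ggplot2::theme_minimal()
}
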