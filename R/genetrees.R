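#' Jukes-Cantor corrected pairwise distance matrix
#'
#' For each sequence pair, the raw proportion of differences `p` is
#' computed over comparable sites (both bases unambiguous, pairwise
#' deletion) and corrected as `d = -(3/4) log(1 - 4p/3)`. Saturated
#' pairs (`p >= 0.75`) are set to `cap` with a warning; pairs with no
#' comparable sites are left missing and make the matrix incomplete.
#'
#' @param alignment A [locus_aln()] with >= 2 sequences.
#' @param cap Distance assigned to saturated pairs (default 5.0
#'   substitutions/site).
#' @param require_complete Error when any pair has no comparable sites
#'   (default TRUE).
#' @return Symmetric numeric matrix with zero diagonal, labelled by
#'   sequence names.
#' @examples
#' aln <- locus_aln("l", c(a = "AAAAAAAAAA", b = "AAAAAAAAAT"))
#' jc_distance_matrix(aln)["a", "b"]  # -(3/4) log(1 - 4*0.1/3)
#' @export
jc_distance_matrix <- function(alignment, cap = 5.0, require_complete = TRUE) {
  mat <- alignment$mat
  n <- nrow(mat)
  if (n < 2) abort("distance matrix needs >= 2 sequences")
  good <- mat == "A" | mat == "C" | mat == "G" | mat == "T"
  d <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  saturated <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      comp <- good[i, ] & good[j, ]
      nc <- sum(comp)
      if (nc == 0) {
        d[i, j] <- d[j, i] <- NA_real_
        next
      }
      p <- sum(mat[i, comp] != mat[j, comp]) / nc
      if (p >= 0.75) {
        d[i, j] <- d[j, i] <- cap
        saturated <- saturated + 1L
      } else {
        d[i, j] <- d[j, i] <- -0.75 * log(1 - 4 * p / 3)
      }
    }
  }
  if (saturated > 0) {
    warn(sprintf("locus '%s': %d saturated pair(s) (p >= 0.75) capped at %g",
                 alignment$locus_id, saturated, cap))
  }
  if (require_complete && anyNA(d)) {
    abort(sprintf("locus '%s': incomplete distance matrix (pairs with no comparable sites)",
                  alignment$locus_id))
  }
  d
}

#' Neighbor-joining gene tree from a distance matrix or alignment
#'
#' A light wrapper around the Saitou-Nei neighbor-joining algorithm
#' (`ape::nj()`), the package's desk-scale stand-in for per-locus
#' maximum-likelihood tree search. Negative branch lengths, which NJ can
#' produce on non-additive inputs, are clamped to zero with a message.
#'
#' @param x A square symmetric distance matrix (n >= 3) or a
#'   [locus_aln()] (distances then come from [jc_distance_matrix()]).
#' @return An unrooted `phylo` tree with branch lengths in
#'   substitutions/site.
#' @export
nj_gene_tree <- function(x) {
  d <- if (inherits(x, "locus_aln")) jc_distance_matrix(x) else x
  if (!is.matrix(d) || nrow(d) != ncol(d)) abort("need a square distance matrix")
  if (nrow(d) < 3) abort("neighbor joining needs >= 3 taxa")
  tr <- ape::nj(stats::as.dist(d))
  if (any(tr$edge.length < 0)) {
    message(sprintf("%d negative NJ branch length(s) clamped to 0",
                    sum(tr$edge.length < 0)))
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  tr
}

#' Test whether a tip set is monophyletic (bipartition semantics)
#'
#' A tip subset is monophyletic when the removal of some internal edge
#' splits the tips into exactly that subset and its complement. This
#' unrooted (split-based) test coincides with rooted clade monophyly
#' whenever the outgroup lies outside the subset.
#'
#' @param tree A `phylo` (rooted or unrooted).
#' @param tips Character vector of tip labels, at least 2, all present in
#'   the tree.
#' @return Logical flag.
#' @examples
#' tr <- ape::read.tree(text = "((A1,A2),(B1,B2));")
#' is_monophyletic(tr, c("A1", "A2"))  # TRUE
#' is_monophyletic(tr, c("A1", "B1"))  # FALSE
#' @export
is_monophyletic <- function(tree, tips) {
  if (!all(tips %in% tree$tip.label)) {
    abort("subset contains labels not in the tree")
  }
  if (length(tips) < 2) abort("subset must contain >= 2 tips")
  ntip <- ape::Ntip(tree)
  if (length(tips) == ntip) return(TRUE)
  in_set <- tree$tip.label %in% tips
  # postorder accumulation of (tips-in-subset, tips-total) per node; the
  # clade below any non-root node is one side of the split its parent
  # edge induces, so checking all node clades covers all edges.
  po <- ape::reorder.phylo(tree, "postorder")
  n_in <- c(as.numeric(in_set), numeric(tree$Nnode))
  n_tot <- c(rep(1, ntip), numeric(tree$Nnode))
  for (i in seq_len(nrow(po$edge))) {
    p <- po$edge[i, 1]; ch <- po$edge[i, 2]
    n_in[p] <- n_in[p] + n_in[ch]
    n_tot[p] <- n_tot[p] + n_tot[ch]
  }
  k <- length(tips)
  nodes <- setdiff(seq_along(n_in), ntip + 1L)  # every non-root node = one edge
  any((n_in[nodes] == k & n_tot[nodes] == k) |
        (n_in[nodes] == 0 & n_tot[nodes] == ntip - k))
}

#' Monophyly proportion per species across gene trees
#'
#' For every species, counts the proportion of gene trees in which its
#' sampled individuals form a monophyletic group. Allele tips
#' (`_a1`/`_a2`) are collapsed to their individual, and a tree only
#' counts as tested for a species when at least two of its individuals
#' have at least one tip in that tree.
#'
#' @param trees List of `phylo` gene trees (e.g. true simulated
#'   genealogies, NJ estimates, or trees read from Newick).
#' @param map Species-map tibble.
#' @return Tibble with `species`, `n_trees_tested`, `n_monophyletic`,
#'   `proportion` (NA when no tree was testable).
#' @export
monophyly_proportions <- function(trees, map) {
  species <- unique(map$species)
  tested <- setNames(integer(length(species)), species)
  mono <- setNames(integer(length(species)), species)
  for (tr in trees) {
    tip_ind <- strip_allele(tr$tip.label)
    for (sp in species) {
      inds <- map$individual[map$species == sp]
      tips <- tr$tip.label[tip_ind %in% inds]
      if (length(unique(tip_ind[tip_ind %in% inds])) < 2) next
      tested[sp] <- tested[sp] + 1L
      if (is_monophyletic(tr, tips)) mono[sp] <- mono[sp] + 1L
    }
  }
  tibble(species = species,
         n_trees_tested = as.integer(unname(tested)),
         n_monophyletic = as.integer(unname(mono)),
         proportion = unname(ifelse(tested > 0, mono / tested, NA_real_)))
}

#' Summarise monophyly proportions against thresholds
#'
#' Reports, for each threshold, the percentage of species whose
#' monophyly proportion meets or exceeds it (half-up rounded to whole
#' percent), along with the minimum proportion and the species falling
#' below 0.90.
#'
#' @param reports Tibble from [monophyly_proportions()] (or any tibble
#'   with `species` and `proportion`). Species with NA proportions are
#'   excluded.
#' @param thresholds Numeric thresholds in (0, 1]; default `c(0.90,
#'   0.95)`.
#' @return List with `summary` (tibble: `threshold`,
#'   `percent_species`, `n_species`), `min_proportion`, and
#'   `below_090` (character vector of species).
#' @export
threshold_summary <- function(reports, thresholds = c(0.90, 0.95)) {
  stopifnot(all(thresholds > 0), all(thresholds <= 1))
  props <- reports$proportion[!is.na(reports$proportion)]
  if (length(props) == 0) abort("no species with a defined monophyly proportion")
  summary <- tibble(
    threshold = thresholds,
    percent_species = vapply(thresholds, function(t) {
      round_half_up(100 * mean(props >= t))
    }, numeric(1)),
    n_species = vapply(thresholds, function(t) sum(props >= t), integer(1)))
  list(summary = summary,
       min_proportion = min(props),
       below_090 = reports$species[!is.na(reports$proportion) &
                                     reports$proportion < 0.90])
}

#' Estimate NJ gene trees for a set of loci
#'
#' Convenience wrapper: Jukes-Cantor distances then neighbor joining per
#' locus. Loci with fewer than 3 sequences or an incomplete distance
#' matrix are skipped with a message.
#'
#' @param alignments Named list of [locus_aln()] objects.
#' @return Named list of `phylo` trees.
#' @export
estimate_gene_trees <- function(alignments) {
  out <- list()
  skipped <- 0L
  for (aln in alignments) {
    tr <- tryCatch(suppressWarnings(nj_gene_tree(aln)),
                   error = function(e) NULL)
    if (is.null(tr)) { skipped <- skipped + 1L; next }
    out[[aln$locus_id]] <- tr
  }
  if (skipped > 0) message(sprintf("%d locus/loci skipped (too few sequences or incomplete matrix)", skipped))
  out
}
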