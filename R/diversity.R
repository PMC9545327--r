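#' Per-locus nucleotide diversity (pi)
#'
#' Mean over all allele pairs of the number of pairwise differences
#' divided by the number of pairwise comparable sites, where a site is
#' comparable for a pair only when both alleles carry an unambiguous base
#' (A/C/G/T). Gaps and Ns are handled by pairwise deletion.
#'
#' @param alignment A [locus_aln()].
#' @param alleles Optional character vector of sequence labels to
#'   restrict to (default: all sequences in the alignment).
#' @return Per-site diversity (a single number). Returns 0 with a warning
#'   when no pair has any comparable site.
#' @examples
#' aln <- locus_aln("l", c(a = "AAAA", b = "AAAT"))
#' locus_pi(aln)  # 1 difference / 4 sites = 0.25
#' @export
locus_pi <- function(alignment, alleles = NULL) {
  mat <- subset_aln(alignment, alleles)
  n <- nrow(mat)
  if (n < 2) abort("nucleotide diversity needs >= 2 alleles")
  good <- mat == "A" | mat == "C" | mat == "G" | mat == "T"
  vals <- numeric(0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      comp <- good[i, ] & good[j, ]
      nc <- sum(comp)
      if (nc > 0) vals <- c(vals, sum(mat[i, comp] != mat[j, comp]) / nc)
    }
  }
  if (length(vals) == 0) {
    warn(sprintf("locus '%s': no comparable sites in any pair; pi set to 0",
                 alignment$locus_id))
    return(0)
  }
  # pairs with zero comparable sites contribute nothing to the mean
  mean(c(vals, numeric(choose(n, 2) - length(vals))))
}

#' Per-locus number of segregating sites
#'
#' Counts alignment columns carrying at least two distinct unambiguous
#' bases among the selected alleles.
#'
#' @inheritParams locus_pi
#' @return Integer count of segregating sites.
#' @export
locus_segregating_sites <- function(alignment, alleles = NULL) {
  mat <- subset_aln(alignment, alleles)
  if (nrow(mat) < 2) abort("segregating sites need >= 2 alleles")
  sum(apply(mat, 2, function(col) {
    length(unique(col[col %in% c("A", "C", "G", "T")])) >= 2
  }))
}

#' Per-locus Watterson's theta (per site)
#'
#' `theta_w = S / (a_{n-1} * L_eff)` where `S` is the number of
#' segregating sites, `a_{n-1} = sum_{i=1}^{n-1} 1/i` the harmonic number
#' for `n` sampled alleles, and `L_eff` the number of columns with at
#' least two unambiguous bases among the subset (the columns where a
#' segregating site could have been observed).
#'
#' @inheritParams locus_pi
#' @return Per-site estimate; 0 with a warning when `L_eff = 0`.
#' @export
locus_watterson <- function(alignment, alleles = NULL) {
  mat <- subset_aln(alignment, alleles)
  n <- nrow(mat)
  if (n < 2) abort("Watterson's theta needs >= 2 alleles")
  s <- locus_segregating_sites(alignment, alleles)
  l_eff <- sum(apply(mat, 2, function(col) {
    sum(col %in% c("A", "C", "G", "T")) >= 2
  }))
  if (l_eff == 0) {
    warn(sprintf("locus '%s': no column with >= 2 unambiguous bases; theta set to 0",
                 alignment$locus_id))
    return(0)
  }
  a_n <- sum(1 / seq_len(n - 1))
  s / (a_n * l_eff)
}

subset_aln <- function(alignment, alleles) {
  mat <- alignment$mat
  if (!is.null(alleles)) {
    missing <- setdiff(alleles, rownames(mat))
    if (length(missing) > 0) {
      abort(sprintf("alleles not in locus '%s': %s", alignment$locus_id,
                    paste(missing, collapse = ", ")))
    }
    mat <- mat[alleles, , drop = FALSE]
  }
  mat
}

#' Per-species diversity summary across loci
#'
#' For every species, computes pi, segregating sites and Watterson's
#' theta per locus over that species' alleles (loci where the species has
#' fewer than two alleles are skipped), then summarises mean and SD
#' across loci. The SD uses the population convention (divisor n).
#'
#' @param alignments Named list of [locus_aln()] objects.
#' @param map Species-map tibble.
#' @return A tibble with one row per species: `species`, `n_loci`,
#'   `mean_pi`, `sd_pi`, `mean_ss`, `sd_ss`, `mean_theta_w`,
#'   `sd_theta_w`. Species with < 2 alleles at every locus get `n_loci =
#'   0` and NA statistics.
#' @export
species_diversity <- function(alignments, map) {
  sd_pop <- function(x) sqrt(mean((x - mean(x))^2))
  purrr::map_dfr(unique(map$species), function(sp) {
    inds <- map$individual[map$species == sp]
    per_locus <- purrr::map_dfr(alignments, function(aln) {
      alle <- aln_labels(aln)[strip_allele(aln_labels(aln)) %in% inds]
      if (length(alle) < 2) return(NULL)
      tibble(pi = locus_pi(aln, alle),
             ss = locus_segregating_sites(aln, alle),
             tw = locus_watterson(aln, alle))
    })
    if (nrow(per_locus) == 0) {
      return(tibble(species = sp, n_loci = 0L, mean_pi = NA_real_,
                    sd_pi = NA_real_, mean_ss = NA_real_, sd_ss = NA_real_,
                    mean_theta_w = NA_real_, sd_theta_w = NA_real_))
    }
    tibble(species = sp, n_loci = nrow(per_locus),
           mean_pi = mean(per_locus$pi), sd_pi = sd_pop(per_locus$pi),
           mean_ss = mean(per_locus$ss), sd_ss = sd_pop(per_locus$ss),
           mean_theta_w = mean(per_locus$tw), sd_theta_w = sd_pop(per_locus$tw))
  })
}

#' Spearman rank correlation with mid-rank ties
#'
#' Computes rho as the Pearson correlation of mid-rank vectors. The
#' p-value is obtained by exhaustive permutation of one rank vector for
#' n <= 9 pairs (two-sided: fraction of permutations with |rho| at least
#' the observed) and otherwise by the usual t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom.
#' Rho, which is deterministic under mid-ranks, is the quantity of
#' record; the p-value is reported for orientation.
#'
#' @param data Optional data frame; when supplied, `x` and `y` are
#'   evaluated as columns of it, so the function pipes naturally.
#' @param x,y Paired numeric vectors (or column names when `data` is
#'   given).
#' @param drop_na Drop pairs with NA in either member (default TRUE).
#' @return An object of class `hyb_spearman` with elements `rho`,
#'   `p_value`, `n` and `method`; see [tidy.hyb_spearman()].
#' @examples
#' spearman_cor(x = c(1, 2, 3, 4), y = c(2, 3, 5, 7))
#' @export
spearman_cor <- function(data = NULL, x, y, drop_na = TRUE) {
  if (!is.null(data)) {
    x <- data[[rlang::as_name(rlang::enquo(x))]]
    y <- data[[rlang::as_name(rlang::enquo(y))]]
  }
  stopifnot(length(x) == length(y))
  if (drop_na) {
    ok <- !is.na(x) & !is.na(y)
    x <- x[ok]; y <- y[ok]
  } else if (anyNA(x) || anyNA(y)) {
    abort("NA present; set drop_na = TRUE to drop incomplete pairs")
  }
  n <- length(x)
  if (n < 3) abort("Spearman correlation needs >= 3 complete pairs")
  rx <- rank(x); ry <- rank(y)
  if (stats::var(rx) == 0 || stats::var(ry) == 0) {
    warn("constant ranks in one vector; rho undefined")
    return(structure(list(rho = NA_real_, p_value = NA_real_, n = n,
                          method = "degenerate"),
                     class = "hyb_spearman"))
  }
  rho <- cor(rx, ry)
  if (n <= 9) {
    perms <- permutations_of(n)
    # rho for every permutation at once: only the cross-product varies
    sp <- as.vector(matrix(ry[perms], nrow = nrow(perms)) %*% rx)
    num <- sp - n * mean(rx) * mean(ry)
    den <- sqrt((sum(rx^2) - n * mean(rx)^2) * (sum(ry^2) - n * mean(ry)^2))
    rho_perm <- num / den
    p_value <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
    method <- "exact-permutation"
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p_value <- 2 * stats::pt(-abs(tstat), df = n - 2)
    method <- "t-approximation"
  }
  structure(list(rho = rho, p_value = p_value, n = n, method = method),
            class = "hyb_spearman")
}

# All permutations of 1..n as an n! x n matrix (n <= 9).
permutations_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  for (pos in seq_len(n)) {
    rows <- (pos - 1L) * nrow(sub) + seq_len(nrow(sub))
    out[rows, pos] <- n
    out[rows, -pos] <- sub
  }
  out
}

#' @export
print.hyb_spearman <- function(x, ...) {
  cat(sprintf("Spearman rank correlation: rho = %.3f, p = %.3g (n = %d, %s)\n",
              x$rho, x$p_value, x$n, x$method))
  invisible(x)
}

#' Tidy a Spearman correlation result
#'
#' @param x A `hyb_spearman` object.
#' @param ... Unused.
#' @return One-row tibble with `estimate`, `p.value`, `n`, `method`.
#' @export
tidy.hyb_spearman <- function(x, ...) {
  tibble(estimate = x$rho, p.value = x$p_value, n = x$n, method = x$method)
}

#' @rdname tidy.hyb_spearman
#' @export
glance.hyb_spearman <- function(x, ...) tidy(x)

#' Correlate foundress number with per-species statistics
#'
#' Joins a per-species statistic table to the foundress numbers in the
#' species map and runs [spearman_cor()] for each requested statistic,
#' dropping species without foundress data.
#'
#' @param stats_tbl Tibble with a `species` column plus statistic columns
#'   (e.g. the output of [species_diversity()], optionally joined with a
#'   monophyly `proportion` column).
#' @param map Species-map tibble carrying `foundress`.
#' @param stats Character vector of statistic column names to test.
#' @return Tibble with one row per statistic: `statistic`, `rho`,
#'   `p_value`, `n`, `method`.
#' @export
foundress_correlations <- function(stats_tbl, map,
                                   stats = intersect(c("mean_pi", "mean_ss",
                                                       "mean_theta_w", "proportion"),
                                                     names(stats_tbl))) {
  fo <- dplyr::distinct(map[!is.na(map$foundress), ], .data$species, .data$foundress)
  joined <- dplyr::inner_join(stats_tbl, fo, by = "species")
  purrr::map_dfr(stats, function(st) {
    ok <- !is.na(joined[[st]])
    res <- spearman_cor(x = joined$foundress[ok], y = joined[[st]][ok])
    tibble(statistic = st, rho = res$rho, p_value = res$p_value,
           n = res$n, method = res$method)
  })
}
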