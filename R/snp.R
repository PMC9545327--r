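#' Extract one unlinked biallelic SNP per locus
#'
#' Scans each phased locus alignment for candidate SNP columns: exactly
#' two distinct unambiguous bases among the non-missing alleles (gap/N =
#' missing; columns with three or more bases are excluded). The
#' candidate with the highest sample coverage -- counted in allele
#' copies -- is selected; coverage ties are broken uniformly at random
#' under `seed`, so the choice is reproducible. Invariant loci
#' contribute nothing, giving at most one SNP per locus (unlinked by
#' construction).
#'
#' Genotypes count copies of the minor allele, the globally less
#' frequent base at the chosen column (ties broken alphabetically), and
#' are missing when either of an individual's two alleles is missing
#' there.
#'
#' @param alignments Named list of phased [locus_aln()] objects (two
#'   allele rows per diploid individual at each locus where it appears).
#' @param map Species-map tibble (defines the individual set and order).
#' @param seed Integer seed for coverage tie-breaking.
#' @param coverage_unit Whether sample coverage is counted in allele
#'   copies (`"alleles"`, the default, finer-grained) or in individuals
#'   with both alleles observed (`"individuals"`).
#' @return A tibble of class `snp_tbl`: column `individual` then one
#'   integer column per retained locus with genotypes in {0, 1, 2, NA}.
#'   Attribute `snp_info` records per-locus column (1-based), minor and
#'   major allele and coverage.
#' @export
extract_unlinked_snps <- function(alignments, map, seed = 1L,
                                  coverage_unit = c("alleles", "individuals")) {
  coverage_unit <- match.arg(coverage_unit)
  set.seed(seed)
  inds <- map$individual
  geno_cols <- list()
  info <- list()
  for (aln in alignments) {
    labs <- aln_labels(aln)
    owner <- strip_allele(labs)
    present <- intersect(unique(owner), inds)
    if (length(present) == 0) next
    bad <- present[vapply(present, function(i) sum(owner == i) != 2L, logical(1))]
    if (length(bad) > 0) {
      abort(sprintf("locus '%s': individual(s) without exactly 2 alleles: %s",
                    aln$locus_id, paste(bad, collapse = ", ")))
    }
    mat <- aln$mat
    is_base <- mat == "A" | mat == "C" | mat == "G" | mat == "T"
    n_alleles_col <- colSums(is_base)
    n_distinct <- apply(mat, 2, function(col) {
      length(unique(col[col %in% c("A", "C", "G", "T")]))
    })
    cand <- which(n_distinct == 2L)
    if (length(cand) == 0) next
    cov <- if (coverage_unit == "alleles") {
      n_alleles_col[cand]
    } else {
      a1 <- match(paste0(present, "_a1"), labs)
      a2 <- match(paste0(present, "_a2"), labs)
      vapply(cand, function(cl) sum(is_base[a1, cl] & is_base[a2, cl]),
             numeric(1))
    }
    best <- cand[cov == max(cov)]
    col <- if (length(best) == 1L) best else best[sample.int(length(best), 1)]

    bases <- mat[, col]
    counts <- table(bases[bases %in% c("A", "C", "G", "T")])
    alleles <- sort(names(counts))
    minor <- if (counts[[alleles[1]]] == counts[[alleles[2]]]) alleles[1] else
      names(counts)[which.min(counts)]
    major <- setdiff(alleles, minor)

    g <- vapply(inds, function(i) {
      if (!i %in% present) return(NA_integer_)
      b <- bases[match(paste0(i, c("_a1", "_a2")), labs)]
      if (!all(b %in% c("A", "C", "G", "T"))) return(NA_integer_)
      sum(b == minor)
    }, integer(1))
    geno_cols[[aln$locus_id]] <- unname(g)
    info[[aln$locus_id]] <- tibble(locus = aln$locus_id, column = as.integer(col),
                                   minor = minor, major = major,
                                   coverage = as.integer(max(cov)))
  }
  out <- if (length(geno_cols) == 0) tibble(individual = inds) else
    dplyr::bind_cols(tibble(individual = inds), as_tibble(geno_cols))
  attr(out, "snp_info") <- if (length(info)) dplyr::bind_rows(info) else
    tibble(locus = character(), column = integer(), minor = character(),
           major = character(), coverage = integer())
  class(out) <- c("snp_tbl", class(out))
  out
}

snp_matrix <- function(snps) {
  m <- as.matrix(snps[, setdiff(names(snps), "individual"), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- snps$individual
  m
}

#' Write a SNP genotype table as TSV
#'
#' Header row of locus IDs, `NA` for missing genotypes.
#'
#' @param snps A `snp_tbl` from [extract_unlinked_snps()].
#' @param path Output file.
#' @export
write_snp_tsv <- function(snps, path) {
  readr::write_tsv(as_tibble(snps), path, na = "NA")
  invisible(path)
}

#' Principal components of the SNP matrix with species-mean imputation
#'
#' Missing genotypes are replaced by the within-species mean genotype
#' for that SNP (falling back to the across-individuals mean when a
#' species has no data at the SNP); columns are then centred (not
#' scaled) and decomposed by SVD. Columns with no observed data at all
#' are dropped with a warning.
#'
#' @param snps A `snp_tbl`.
#' @param map Species-map tibble.
#' @param n_components Number of axes to retain (default 2).
#' @return An object of class `hyb_pca`: `coordinates` (tibble:
#'   individual, species, PC1..), `variance_explained` (fraction per
#'   retained axis), `n_snps`.
#' @export
snp_pca <- function(snps, map, n_components = 2) {
  m <- snp_matrix(snps)
  if (nrow(m) < 2 || ncol(m) < 1) abort("PCA needs >= 2 individuals and >= 1 SNP")
  sp <- map$species[match(rownames(m), map$individual)]
  all_missing <- colSums(!is.na(m)) == 0
  if (any(all_missing)) {
    warn(sprintf("%d SNP column(s) with no observed genotypes dropped",
                 sum(all_missing)))
    m <- m[, !all_missing, drop = FALSE]
  }
  for (j in seq_len(ncol(m))) {
    miss <- is.na(m[, j])
    if (!any(miss)) next
    col_mean <- mean(m[, j], na.rm = TRUE)
    for (s in unique(sp[miss])) {
      rows <- miss & sp == s
      sp_mean <- mean(m[sp == s, j], na.rm = TRUE)
      m[rows, j] <- if (is.nan(sp_mean)) col_mean else sp_mean
    }
  }
  centred <- scale(m, center = TRUE, scale = FALSE)
  sv <- svd(centred)
  k <- min(n_components, length(sv$d))
  var_frac <- sv$d^2 / sum(sv$d^2)
  coords <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  colnames(coords) <- paste0("PC", seq_len(k))
  structure(list(
    coordinates = dplyr::bind_cols(
      tibble(individual = rownames(m), species = sp), as_tibble(coords)),
    variance_explained = var_frac[seq_len(k)],
    n_snps = ncol(m)),
    class = "hyb_pca")
}

#' @export
print.hyb_pca <- function(x, ...) {
  cat(sprintf("<hyb_pca> %d individuals x %d SNPs; variance explained: %s\n",
              nrow(x$coordinates), x$n_snps,
              paste(sprintf("%.1f%%", 100 * x$variance_explained), collapse = ", ")))
  invisible(x)
}

#' Tidy/plot methods for PCA results
#'
#' `tidy()` returns the coordinates in long form, `glance()` the
#' variance explained, and `autoplot()` a PC1/PC2 scatter coloured by
#' species.
#'
#' @param x A `hyb_pca`.
#' @param ... Unused.
#' @export
tidy.hyb_pca <- function(x, ...) {
  tidyr::pivot_longer(x$coordinates, dplyr::starts_with("PC"),
                      names_to = "component", values_to = "value")
}

#' @rdname tidy.hyb_pca
#' @export
glance.hyb_pca <- function(x, ...) {
  tibble(component = paste0("PC", seq_along(x$variance_explained)),
         variance_explained = x$variance_explained, n_snps = x$n_snps)
}

#' @rdname tidy.hyb_pca
#' @param object A `hyb_pca`.
#' @export
autoplot.hyb_pca <- function(object, ...) {
  ggplot2::ggplot(object$coordinates,
                  ggplot2::aes(.data$PC1, .data$PC2, colour = .data$species)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$variance_explained[1]),
      y = if (length(object$variance_explained) > 1)
        sprintf("PC2 (%.1f%%)", 100 * object$variance_explained[2]) else "PC2") +
    ggplot2::theme_minimal()
}
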