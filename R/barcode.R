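#' Model-corrected pairwise distances (JC or pairwise-ML GTR)
#'
#' Under `model = "jc"` this is [jc_distance_matrix()]. Under
#' `model = "gtr"` a general time-reversible substitution model is fit
#' once to the whole alignment -- base frequencies taken empirically,
#' the six exchangeabilities maximised numerically against the pooled
#' pairwise site-pattern counts -- and each pair's distance is then the
#' branch length maximising the two-sequence GTR likelihood (bounded
#' one-dimensional optimisation). If the global fit fails to converge
#' the function falls back to JC with a warning.
#'
#' @param alignment A [locus_aln()] with >= 2 sequences.
#' @param model `"jc"` or `"gtr"`.
#' @param rates Optional fixed exchangeabilities (length 6, order AC,
#'   AG, AT, CG, CT, GT) overriding estimation.
#' @param base_freq Optional fixed base frequencies (A, C, G, T).
#' @param cap Distance cap for saturated/unresolvable pairs.
#' @return Symmetric non-negative matrix with zero diagonal.
#' @export
corrected_distances <- function(alignment, model = c("jc", "gtr"),
                                rates = NULL, base_freq = NULL, cap = 5.0) {
  model <- match.arg(model)
  if (model == "jc") return(jc_distance_matrix(alignment, cap = cap))
  mat <- alignment$mat
  n <- nrow(mat)
  if (n < 2) abort("distance matrix needs >= 2 sequences")
  code <- matrix(match(mat, c("A", "C", "G", "T")), nrow = n)

  if (is.null(base_freq)) {
    tab <- tabulate(code, 4)
    base_freq <- (tab + 1) / sum(tab + 1)  # add-one keeps all freqs positive
  }
  base_freq <- base_freq / sum(base_freq)

  # pooled symmetric site-pattern counts over all pairs
  F_pool <- matrix(0, 4, 4)
  pair_counts <- vector("list", n * (n - 1) / 2)
  idx <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      comp <- !is.na(code[i, ]) & !is.na(code[j, ])
      idx <- idx + 1L
      if (!any(comp)) { pair_counts[idx] <- list(NULL); next }
      f <- matrix(0, 4, 4)
      tt <- table(factor(code[i, comp], 1:4), factor(code[j, comp], 1:4))
      f[, ] <- as.numeric(tt)
      f <- (f + t(f)) / 2
      pair_counts[[idx]] <- f
      F_pool <- F_pool + f
    }
  }

  fitted <- if (is.null(rates)) {
    tryCatch(fit_gtr_rates(F_pool, base_freq),
             error = function(e) NULL)
  } else rates
  if (is.null(fitted)) {
    warn("GTR rate estimation did not converge; falling back to JC distances")
    return(jc_distance_matrix(alignment, cap = cap))
  }
  Q <- gtr_Q(fitted, base_freq)

  d <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  idx <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      idx <- idx + 1L
      f <- pair_counts[[idx]]
      if (is.null(f)) { d[i, j] <- d[j, i] <- NA_real_; next }
      if (sum(f) - sum(diag(f)) == 0) next  # identical pair: distance 0
      opt <- optimize(function(t) gtr_pair_loglik(t, f, Q, base_freq),
                      interval = c(1e-9, cap), maximum = TRUE, tol = 1e-10)
      d[i, j] <- d[j, i] <- min(opt$maximum, cap)
    }
  }
  if (anyNA(d)) {
    abort(sprintf("locus '%s': incomplete distance matrix (pairs with no comparable sites)",
                  alignment$locus_id))
  }
  d
}

# Build the normalised GTR rate matrix: Q[i,j] = s[ij] * pi[j], diagonal
# makes rows sum to zero, scaled to one expected substitution per unit
# time so optimised branch lengths are substitutions/site.
gtr_Q <- function(rates, base_freq) {
  stopifnot(length(rates) == 6, all(rates > 0))
  S <- matrix(0, 4, 4)
  S[lower.tri(S)] <- rates  # column-major lower triangle = AC,AG,AT,CG,CT,GT
  S <- S + t(S)
  Q <- S * rep(base_freq, each = 4)
  diag(Q) <- -rowSums(Q)
  Q / sum(base_freq * -diag(Q))
}

# P(t) = exp(Qt) via the symmetrised eigendecomposition (Q reversible).
gtr_P <- function(Q, base_freq, t) {
  rs <- sqrt(base_freq)
  Sy <- Q * (rs / rep(rs, each = 4))  # diag(rs) Q diag(1/rs), symmetric
  Sy <- (Sy + t(Sy)) / 2
  e <- eigen(Sy, symmetric = TRUE)
  P <- (e$vectors %*% (exp(e$values * t) * t(e$vectors))) * (rep(rs, each = 4) / rs)
  pmax(P, 1e-12)
}

gtr_pair_loglik <- function(t, f, Q, base_freq) {
  P <- gtr_P(Q, base_freq, t)
  sum(f * log(base_freq * P))
}

# Maximise the pooled two-sequence likelihood over log-exchangeabilities
# (GT fixed to 1) and a common log-branch-length nuisance parameter.
fit_gtr_rates <- function(F_pool, base_freq) {
  nll <- function(par) {
    rates <- c(exp(par[1:5]), 1)
    t <- exp(par[6])
    Q <- gtr_Q(rates, base_freq)
    -gtr_pair_loglik(t, F_pool, Q, base_freq)
  }
  p_obs <- 1 - sum(diag(F_pool)) / sum(F_pool)
  t0 <- if (p_obs < 0.7) max(-0.75 * log(1 - 4 * min(p_obs, 0.74) / 3), 1e-4) else 1
  fit <- optim(c(rep(0, 5), log(t0)), nll, method = "BFGS",
               control = list(maxit = 500))
  if (fit$convergence != 0) abort("optim did not converge")
  c(exp(fit$par[1:5]), 1)
}

#' Barcode-gap analysis of a corrected distance matrix
#'
#' Summarises intraspecific versus interspecific divergence the way
#' mtDNA barcoding studies do: per-species mean intraspecific distance
#' (species needing >= 2 sequences; others NA and excluded), per
#' species-pair mean interspecific distance, unweighted overall means of
#' each, and a barcode-gap flag set when the smallest pair mean exceeds
#' the largest species mean.
#'
#' @param dist_matrix Symmetric distance matrix with individual labels.
#' @param map Species-map tibble covering the matrix labels.
#' @return List of class `hyb_barcode`: `intra` (tibble species,
#'   n, mean_dist), `inter` (tibble speciesA, speciesB, mean_dist),
#'   `overall_intra`, `overall_inter` (unweighted means, NA if
#'   undefined), `gap` (flag), and the same two overall figures as
#'   percentages (`intra_pct`, `inter_pct`).
#' @export
barcode_gap <- function(dist_matrix, map) {
  labs <- rownames(dist_matrix)
  sp <- map$species[match(strip_allele(labs), map$individual)]
  if (anyNA(sp)) abort("distance matrix labels missing from species map")
  species <- unique(sp)
  if (length(species) < 2) abort("barcode gap needs >= 2 species")

  intra <- purrr::map_dfr(species, function(s) {
    idx <- which(sp == s)
    m <- if (length(idx) >= 2) {
      mean(dist_matrix[idx, idx][upper.tri(matrix(0, length(idx), length(idx)))])
    } else NA_real_
    tibble(species = s, n = length(idx), mean_dist = m)
  })
  pairs <- utils::combn(species, 2)
  inter <- purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    a <- which(sp == pairs[1, k]); b <- which(sp == pairs[2, k])
    tibble(speciesA = pairs[1, k], speciesB = pairs[2, k],
           mean_dist = mean(dist_matrix[a, b]))
  })
  overall_intra <- if (all(is.na(intra$mean_dist))) NA_real_ else
    mean(intra$mean_dist, na.rm = TRUE)
  overall_inter <- mean(inter$mean_dist)
  gap <- !is.na(overall_intra) &&
    min(inter$mean_dist) > max(intra$mean_dist, na.rm = TRUE)
  structure(list(intra = intra, inter = inter,
                 overall_intra = overall_intra, overall_inter = overall_inter,
                 intra_pct = 100 * overall_intra, inter_pct = 100 * overall_inter,
                 gap = gap),
            class = "hyb_barcode")
}

#' @export
print.hyb_barcode <- function(x, ...) {
  cat(sprintf("Barcode gap: intraspecific %.2f%% vs interspecific %.2f%% -- gap %s\n",
              x$intra_pct, x$inter_pct, if (isTRUE(x$gap)) "present" else "absent"))
  invisible(x)
}
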