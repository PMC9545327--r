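#' Probability of detecting at least one hybrid in a finite sample
#'
#' Under binomial sampling, the chance that a sample of `n` individuals
#' contains one or more hybrids when hybrids occur at frequency `f` is
#' `1 - (1 - f)^n`. With the published F1 brood frequency of 0.009 and
#' a sample of 14 wasps this is 11.9%.
#'
#' @param f Hybrid frequency in [0, 1].
#' @param n Sample size (>= 0).
#' @return Detection probability in [0, 1].
#' @examples
#' detect_prob(0.009, 14)  # 0.1188...
#' @export
detect_prob <- function(f, n) {
  if (any(f < 0 | f > 1)) abort("f must be in [0, 1]")
  if (any(n < 0)) abort("n must be >= 0")
  1 - (1 - f)^n
}

#' Sample size required to reach a target detection probability
#'
#' The smallest integer `n` with `detect_prob(f, n) >= target`, i.e.
#' `ceiling(log(1 - target) / log(1 - f))`. At `f = 0.009` a 50% chance
#' of sampling at least one F1 needs 77 individuals.
#'
#' @param f Hybrid frequency in (0, 1).
#' @param target Target detection probability in (0, 1).
#' @return Integer sample size.
#' @examples
#' required_n(0.009, 0.5)  # 77
#' @export
required_n <- function(f, target) {
  if (f <= 0 || f >= 1) abort("f must be in (0, 1); f = 0 admits no finite n")
  if (target <= 0 || target >= 1) abort("target must be in (0, 1)")
  n <- as.integer(ceiling(log(1 - target) / log(1 - f)))
  # guard against floating-point landing one off the true minimum
  while (detect_prob(f, n) < target) n <- n + 1L
  while (n > 1L && detect_prob(f, n - 1L) >= target) n <- n - 1L
  n
}

#' Island-model differentiation implied by a migration rate
#'
#' Wright's infinite-island equilibrium `F_ST = 1 / (1 + 4 Ne m)`,
#' with the effective number of migrants `Nm = Ne * m`. If an F1
#' formation rate of 0.009 acted as a migration rate in populations of
#' effective size above 1000, Nm would exceed 9 and differentiation
#' would be held below F_ST = 0.03.
#'
#' @param Ne Effective population size (> 0).
#' @param m Migration rate in [0, 1].
#' @return Tibble with `Nm` and `Fst` (`Fst = 1` flagged by message
#'   when `m = 0`).
#' @examples
#' island_fst(1000, 0.009)  # Nm = 9, Fst = 1/37
#' @export
island_fst <- function(Ne, m) {
  if (any(Ne <= 0)) abort("Ne must be > 0")
  if (any(m < 0 | m > 1)) abort("m must be in [0, 1]")
  if (any(m == 0)) message("m = 0: no migration, F_ST = 1 by convention")
  nm <- Ne * m
  m_v <- rep_len(m, length(nm))
  tibble(Nm = nm, Fst = ifelse(m_v == 0, 1, 1 / (1 + 4 * nm)))
}
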