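# helper: snp_tbl-like tibble from a plain genotype matrix
as_snp_tbl <- function(m) {
  out <- dplyr::bind_cols(tibble::tibble(individual = rownames(m)),
                          tibble::as_tibble(m))
  class(out) <- c("snp_tbl", class(out))
  out
}

test_that("PCA separates fixed species on PC1 with all the variance", {
  m <- rbind(matrix(0L, 4, 10), matrix(2L, 4, 10))
  rownames(m) <- c(paste0("a", 1:4), paste0("b", 1:4))
  colnames(m) <- paste0("l", 1:10)
  map <- species_map(rownames(m), rep(c("A", "B"), each = 4))
  p <- snp_pca(as_snp_tbl(m), map)
  expect_equal(p$variance_explained[1], 1)
  within_a <- p$coordinates$PC1[p$coordinates$species == "A"]
  within_b <- p$coordinates$PC1[p$coordinates$species == "B"]
  expect_equal(diff(range(within_a)), 0)
  expect_equal(diff(range(within_b)), 0)
  expect_gt(abs(mean(within_a) - mean(within_b)), 0)
})

test_that("variance explained matches a dense covariance eigendecomposition", {
  set.seed(55)
  m <- matrix(sample(0:2, 20, replace = TRUE), 5, 4,
              dimnames = list(paste0("i", 1:5), paste0("l", 1:4)))
  map <- species_map(paste0("i", 1:5), rep("S", 5))
  p <- snp_pca(as_snp_tbl(m), map, n_components = 4)
  ev <- eigen(stats::cov(scale(m, center = TRUE, scale = FALSE)))$values
  # cov uses divisor n-1, the svd variance ratio is scale free
  expect_equal(p$variance_explained, (ev / sum(ev))[seq_along(p$variance_explained)],
               tolerance = 1e-8)
})

test_that("species-mean imputation fills holes and PCA order-invariance holds", {
  set.seed(66)
  m <- rbind(matrix(0L, 4, 12), matrix(2L, 4, 12))
  rownames(m) <- c(paste0("a", 1:4), paste0("b", 1:4))
  colnames(m) <- paste0("l", 1:12)
  m[1, 3] <- NA; m[5, 7] <- NA
  map <- species_map(rownames(m), rep(c("A", "B"), each = 4))
  p <- snp_pca(as_snp_tbl(m), map)
  # imputing the species mean restores the rank-1 separation exactly
  expect_equal(p$variance_explained[1], 1)

  perm <- sample(8)
  p2 <- snp_pca(as_snp_tbl(m[perm, ]), map)
  a <- p$coordinates$PC1[match(rownames(m), p$coordinates$individual)]
  b <- p2$coordinates$PC1[match(rownames(m), p2$coordinates$individual)]
  expect_equal(abs(a), abs(b), tolerance = 1e-9)

  # an entirely unobserved SNP column is dropped with a warning
  m2 <- m; m2[, 12] <- NA
  expect_warning(p3 <- snp_pca(as_snp_tbl(m2), map), "dropped")
  expect_equal(p3$n_snps, 11L)
})

test_that("an injected F1 sits midway between the parental centroids", {
  b <- simulate_community(deep_config(
    seed = 25, n_loci = 120, n_ind = 6,
    f1 = tibble::tibble(parentA = "A", parentB = "B", count = 1L)))
  scr <- screen_pair(b$alignments, b$map, "A", "B",
                     extra_individuals = b$map$individual[grepl("f1", b$map$individual)])
  co <- scr$pca$coordinates
  mid <- (mean(co$PC1[co$species == "A"]) + mean(co$PC1[co$species == "B"])) / 2
  spread <- max(stats::sd(co$PC1[co$species == "A"]),
                stats::sd(co$PC1[co$species == "B"]), 1e-9)
  f1 <- co$PC1[grepl("f1", co$individual)]
  gap <- abs(mean(co$PC1[co$species == "A"]) - mean(co$PC1[co$species == "B"]))
  expect_lt(abs(f1 - mid), max(spread, 0.02 * gap))
})

test_that("diagnostic loci follow the frequency-difference rule exactly", {
  m <- cbind(l1 = c(0, 0, 0, 2, 2, 2),      # fixed difference
             l2 = c(0, 0, 0, 0, 0, 0),      # identical panels
             l3 = c(0, 1, 0, 2, 2, 1),      # freqs 1/6 vs 5/6 -> diff 2/3
             l4 = c(NA, 0, 0, 2, NA, 2))    # fixed difference with missing
  rownames(m) <- paste0("i", 1:6)
  m <- matrix(as.double(m), 6, 4, dimnames = dimnames(m))
  map <- species_map(paste0("i", 1:6), rep(c("P", "Q"), each = 3))
  snps <- as_snp_tbl(m)
  expect_setequal(diagnostic_loci(snps, map, "P", "Q")$locus, c("l1", "l4"))
  d08 <- diagnostic_loci(snps, map, "P", "Q", min_freq_diff = 0.6)
  expect_setequal(d08$locus, c("l1", "l3", "l4"))
  expect_equal(d08$diff[d08$locus == "l3"], 2 / 3, tolerance = 1e-12)
  ident <- as_snp_tbl(m[, 2, drop = FALSE])
  expect_warning(empty <- diagnostic_loci(ident, map, "P", "Q"), "no diagnostic")
  expect_equal(nrow(empty), 0L)
})

test_that("hybrid scores recover pure, F1 and backcross genotype logic", {
  n_loci <- 50
  diag_tbl <- tibble::tibble(locus = paste0("l", seq_len(n_loci)),
                             freq_a = 0, freq_b = 1, diff = 1,
                             b_allele = "minor")
  pureA <- matrix(0, 1, n_loci, dimnames = list("pa", diag_tbl$locus))
  f1 <- matrix(1, 1, n_loci, dimnames = list("f1", diag_tbl$locus))
  sc <- hybrid_scores(as_snp_tbl(rbind(pureA, f1)), diag_tbl)
  expect_equal(sc$hybrid_index[sc$individual == "pa"], 0)
  expect_equal(sc$het[sc$individual == "pa"], 0)
  expect_equal(sc$hybrid_index[sc$individual == "f1"], 0.5)
  expect_equal(sc$het[sc$individual == "f1"], 1)

  # Mendelian oracle: a first-generation backcross to A carries one A
  # allele plus a 50/50 allele from the F1 parent at every diagnostic
  # locus, so E[index] = 0.25 and E[het] = 0.5
  set.seed(77)
  bc <- t(vapply(1:200, function(i) rbinom(n_loci, 1, 0.5), numeric(n_loci)))
  rownames(bc) <- paste0("bc", 1:200)
  colnames(bc) <- diag_tbl$locus
  sc_bc <- hybrid_scores(as_snp_tbl(bc), diag_tbl)
  expect_lt(abs(mean(sc_bc$hybrid_index) - 0.25), 0.02)
  expect_lt(abs(mean(sc_bc$het) - 0.5), 0.04)
})

test_that("classification windows and the ambiguity guard apply", {
  sc <- tibble::tibble(individual = c("p", "q", "f", "b", "amb"),
                       hybrid_index = c(0.0, 1.0, 0.5, 0.25, 0.5),
                       het = c(0, 0, 1, 0.5, 1),
                       n_diagnostic = c(50L, 50L, 50L, 50L, 5L))
  cl <- classify_hybrids(sc)
  expect_equal(cl$klass, c("pure-A", "pure-B", "F1-like", "backcross-like",
                           "ambiguous"))
})
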