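test_that("JC distances match the closed form and an independent library", {
  ident <- toy_aln(a_a1 = "ACGTACGTAC", b_a1 = "ACGTACGTAC")
  expect_equal(jc_distance_matrix(ident)[1, 2], 0)

  pair <- locus_aln("l", c(x = strrep("A", 10),
                           y = paste0(strrep("A", 9), "T")))
  expect_equal(jc_distance_matrix(pair)["x", "y"], -0.75 * log(13 / 15))

  set.seed(31)
  mat <- matrix(sample(c("A", "C", "G", "T", "N"), 6 * 200, replace = TRUE,
                       prob = c(0.4, 0.3, 0.15, 0.1, 0.05)),
                nrow = 6, dimnames = list(paste0("s", 1:6), NULL))
  # keep p below saturation by copying with few changes
  base <- sample(c("A", "C", "G", "T"), 200, replace = TRUE)
  for (i in 1:6) {
    mat[i, ] <- base
    flip <- sample(200, 15 + i)
    mat[i, flip] <- sample(c("A", "C", "G", "T"), length(flip), replace = TRUE)
    mat[i, sample(200, 8)] <- "N"
  }
  aln <- locus_aln("r", mat)
  ours <- jc_distance_matrix(aln)
  bin <- ape::as.DNAbin(tolower(mat))
  theirs <- as.matrix(ape::dist.dna(bin, model = "JC69",
                                    pairwise.deletion = TRUE))
  expect_equal(ours, theirs[rownames(ours), colnames(ours)], tolerance = 1e-10)
  expect_true(isSymmetric(ours))
  expect_true(all(diag(ours) == 0))
})

test_that("saturated pairs are capped and empty overlap is an error", {
  div <- locus_aln("l", c(x = strrep("A", 20), y = strrep("C", 20)))
  expect_warning(d <- jc_distance_matrix(div, cap = 5), "saturated")
  expect_equal(d["x", "y"], 5)
  none <- locus_aln("l", c(x = "AC--", y = "--GT"))
  expect_error(suppressWarnings(jc_distance_matrix(none)), "incomplete")
})

test_that("neighbor joining recovers an additive four-taxon tree exactly", {
  # tree ((A:1,B:2):1,(C:3,D:1)): path lengths are additive
  d <- matrix(c(0, 3, 5, 3,
                3, 0, 6, 4,
                5, 6, 0, 4,
                3, 4, 4, 0), 4, 4,
              dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  tr <- nj_gene_tree(d)
  expect_true(is_monophyletic(tr, c("A", "B")))
  expect_true(is_monophyletic(tr, c("C", "D")))
  expect_equal(as.matrix(ape::cophenetic.phylo(tr))[rownames(d), colnames(d)],
               d, tolerance = 1e-12)
})

test_that("three taxa resolve by the three-point formulas", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_gene_tree(d)
  lens <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(lens[["a"]], 1)
  expect_equal(lens[["b"]], 2)
  expect_equal(lens[["c"]], 3)
  expect_error(nj_gene_tree(d[1:2, 1:2]), ">= 3")
})

test_that("taxon input order does not change the NJ tree", {
  set.seed(5)
  n <- 7
  coords <- matrix(runif(n * 3), n)
  d <- as.matrix(dist(coords))
  dimnames(d) <- list(letters[1:n], letters[1:n])
  t1 <- nj_gene_tree(d)
  perm <- sample(n)
  t2 <- nj_gene_tree(d[perm, perm])
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(t1), ape::unroot(t2))), 0)
  expect_equal(as.matrix(ape::cophenetic.phylo(t1))[letters[1:n], letters[1:n]],
               as.matrix(ape::cophenetic.phylo(t2))[letters[1:n], letters[1:n]],
               tolerance = 1e-12)
})

test_that("monophyly test agrees with exhaustive bipartition enumeration", {
  expect_true(is_monophyletic(ape::read.tree(text = "((A1,A2),(B1,B2));"),
                              c("A1", "A2")))
  expect_false(is_monophyletic(ape::read.tree(text = "((A1,A2),(B1,B2));"),
                               c("A1", "B1")))
  expect_error(is_monophyletic(ape::read.tree(text = "((A1,A2),(B1,B2));"),
                               c("A1", "Z")), "not in the tree")
  set.seed(99)
  for (rep in 1:400) {
    tr <- ape::rtree(8)
    k <- sample(2:6, 1)
    tips <- sample(tr$tip.label, k)
    expect_equal(is_monophyletic(tr, tips), oracle_is_split(tr, tips),
                 info = paste(tips, collapse = ","))
  }
})

test_that("monophyly is invariant to re-rooting outside the subset", {
  set.seed(17)
  for (rep in 1:30) {
    tr <- ape::rtree(10)
    tips <- sample(tr$tip.label, 3)
    ref <- is_monophyletic(tr, tips)
    out <- setdiff(tr$tip.label, tips)
    for (og in sample(out, 2)) {
      expect_equal(is_monophyletic(ape::root(tr, og, resolve.root = TRUE), tips),
                   ref)
    }
  }
})

test_that("monophyly proportions collapse alleles and track testability", {
  map <- species_map(c("A1", "A2", "B1", "B2", "Z1"),
                     c("spA", "spA", "spB", "spB", "spZ"))
  t1 <- ape::read.tree(text = "(((A1_a1,A1_a2),(A2_a1,A2_a2)),((B1_a1,B2_a1),B2_a2));")
  t2 <- ape::read.tree(text = "(((A1_a1,B1_a1),A2_a1),(B2_a1,B2_a2));")
  rep <- monophyly_proportions(list(t1, t2), map)
  expect_equal(rep$proportion[rep$species == "spA"], 0.5)  # mono in t1 only
  expect_equal(rep$n_trees_tested[rep$species == "spB"], 2L)
  expect_equal(rep$proportion[rep$species == "spB"], 0.5)  # t2 interleaves B2 away
  expect_true(is.na(rep$proportion[rep$species == "spZ"]))

  # a species with only one individual in a tree is not tested there
  t3 <- ape::read.tree(text = "((A1_a1,A1_a2),(B1_a1,B2_a1));")
  rep3 <- monophyly_proportions(list(t3), map)
  expect_equal(rep3$n_trees_tested[rep3$species == "spA"], 0L)
})

test_that("threshold summaries report percent of species half-up", {
  all_one <- tibble::tibble(species = letters[1:4], proportion = 1)
  ts <- threshold_summary(all_one, c(0.5, 0.9, 1))
  expect_true(all(ts$summary$percent_species == 100))
  expect_error(threshold_summary(tibble::tibble(species = "a",
                                                proportion = NA_real_)),
               "no species")
  mixed <- tibble::tibble(species = letters[1:3],
                          proportion = c(0.96, 0.91, 0.80))
  ts2 <- threshold_summary(mixed)
  expect_equal(ts2$summary$percent_species[ts2$summary$threshold == 0.95], 33)
  expect_equal(ts2$summary$percent_species[ts2$summary$threshold == 0.90], 67)
  expect_equal(ts2$min_proportion, 0.80)
  expect_equal(ts2$below_090, "c")
})

test_that("NJ trees recover simulated monophyly nearly as well as the truth", {
  b <- simulate_community(deep_config(seed = 13, n_loci = 40))
  true_rep <- monophyly_proportions(b$true_gene_trees, b$map)
  nj_rep <- monophyly_proportions(estimate_gene_trees(b$alignments), b$map)
  expect_true(all(abs(true_rep$proportion - nj_rep$proportion) <= 0.05))
})
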