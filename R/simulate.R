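#' Configure a synthetic wasp community simulation
#'
#' Builds the configuration object for the multispecies-coalescent (MSC)
#' community simulator. Time is measured in generations throughout:
#' species-tree branch lengths, introgression-event times and coalescent
#' waiting times all share that unit, and the mutation rate `mu` is per
#' site per generation.
#'
#' The simulator draws one genealogy per locus under the MSC (lineages
#' coalesce only within their current population, with pair rate
#' 1/(2 Ne) for diploid nuclear loci), reroutes lineages across an
#' introgression pulse with the stated probability, and then evolves
#' finite-sites Jukes-Cantor sequences along the genealogy.
#'
#' @param species_tree Rooted, ultrametric Newick string (or `phylo`) with
#'   branch lengths in generations; tip labels are the species names.
#' @param species Tibble/data frame with columns `name`, `n_individuals`,
#'   `Ne`, and optionally `foundress` (mean foundresses per syconium) and
#'   `host`. All sampled individuals are diploid females.
#' @param n_loci Number of nuclear loci (>= 1).
#' @param locus_length Alignment length in bp per nuclear locus.
#' @param mu Mutation rate per site per generation (> 0).
#' @param events Optional tibble with columns `donor`, `recipient`,
#'   `time` (generations before present) and `proportion` (fraction of
#'   recipient lineages rerouted into the donor population, in [0, 1]).
#' @param f1_injections Optional tibble with columns `parentA`, `parentB`,
#'   `count`: first-generation hybrids added after simulation.
#' @param missing_rate Per-locus probability that a given individual is
#'   dropped entirely (both alleles) from that locus, in [0, 1).
#' @param seed Integer seed; the whole bundle is a pure function of the
#'   configuration including this seed.
#' @param ancestral_Ne Effective size of ancestral (internal-branch)
#'   populations; defaults to the mean of the tip `Ne` values.
#' @param mtdna_scale mtDNA effective size as a fraction of the nuclear
#'   `Ne` (haploid, maternally inherited); default 0.5.
#' @param mtdna_length mtDNA alignment length in bp (default 816).
#' @param foundress_ne Optional base effective size; when supplied, tip
#'   sizes are overridden by the monotone map `Ne = foundress_ne *
#'   foundress` (species with missing foundress keep their own `Ne`).
#'   Disabled (NULL) by default.
#' @return An object of class `sim_config`.
#' @examples
#' cfg <- sim_config(
#'   species_tree = "((A:10000,B:10000):10000,C:20000);",
#'   species = tibble::tibble(name = c("A", "B", "C"),
#'                            n_individuals = 4, Ne = 1000),
#'   n_loci = 10, locus_length = 200, mu = 1e-6, seed = 1)
#' @seealso [simulate_community()], [simulate_gene_tree()]
#' @export
sim_config <- function(species_tree, species, n_loci, locus_length, mu,
                       events = NULL, f1_injections = NULL,
                       missing_rate = 0, seed = 1L,
                       ancestral_Ne = NULL, mtdna_scale = 0.5,
                       mtdna_length = 816L, foundress_ne = NULL) {
  single <- is.character(species_tree) && !grepl("\\(", species_tree)
  tree <- if (inherits(species_tree, "phylo")) species_tree else if (single) {
    # degenerate one-species "tree": a single panmictic population
    structure(list(edge = matrix(c(2L, 1L), 1, 2),
                   tip.label = sub(";", "", trimws(species_tree)),
                   edge.length = 0, Nnode = 1L), class = "phylo")
  } else {
    tryCatch(ape::read.tree(text = species_tree), error = function(e) NULL)
  }
  if (is.null(tree)) abort("species_tree could not be parsed as Newick")
  if (!single) {
    if (!ape::is.rooted(tree)) abort("species_tree must be rooted")
    if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
      abort("species_tree must have branch lengths (generations)")
    }
  }
  species <- as_tibble(species)
  stopifnot(all(c("name", "n_individuals", "Ne") %in% names(species)))
  if (!"foundress" %in% names(species)) species$foundress <- NA_real_
  if (!"host" %in% names(species)) species$host <- paste0("Ficus_", species$name)
  if (!setequal(species$name, tree$tip.label)) {
    abort("species names must match species_tree tip labels exactly")
  }
  if (any(species$n_individuals < 1)) abort("n_individuals must be >= 1")
  if (any(species$Ne <= 0)) abort("Ne must be > 0")
  if (any(!is.na(species$foundress) & species$foundress < 1)) {
    abort("foundress must be >= 1 where present")
  }
  if (!is.null(foundress_ne)) {
    link <- !is.na(species$foundress)
    species$Ne[link] <- foundress_ne * species$foundress[link]
  }
  stopifnot(n_loci >= 1, locus_length >= 1, mu > 0,
            missing_rate >= 0, missing_rate < 1)

  ages <- node_ages(tree)
  if (!single && max(abs(ages[seq_len(ape::Ntip(tree))])) > 1e-6 * max(ages)) {
    abort("species_tree must be ultrametric (contemporaneous tips)")
  }
  if (!is.null(events)) {
    events <- as_tibble(events)
    stopifnot(all(c("donor", "recipient", "time", "proportion") %in% names(events)))
    for (i in seq_len(nrow(events))) {
      ev <- events[i, ]
      if (ev$donor == ev$recipient) abort("introgression donor must differ from recipient")
      if (ev$proportion < 0 || ev$proportion > 1) abort("proportion must be in [0,1]")
      lim <- min(parent_age(tree, ages, ev$donor), parent_age(tree, ages, ev$recipient))
      if (ev$time <= 0 || ev$time >= lim) {
        abort(sprintf("event %d: time must lie in (0, %g), before either species joins an ancestor",
                      i, lim))
      }
    }
  }
  if (!is.null(f1_injections)) {
    f1_injections <- as_tibble(f1_injections)
    stopifnot(all(c("parentA", "parentB", "count") %in% names(f1_injections)))
  }
  if (is.null(ancestral_Ne)) ancestral_Ne <- mean(species$Ne)
  structure(list(tree = tree, ages = ages, species = species,
                 n_loci = as.integer(n_loci),
                 locus_length = as.integer(locus_length), mu = mu,
                 events = events, f1_injections = f1_injections,
                 missing_rate = missing_rate, seed = as.integer(seed),
                 ancestral_Ne = ancestral_Ne, mtdna_scale = mtdna_scale,
                 mtdna_length = as.integer(mtdna_length)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> %d species, %d loci x %d bp, mu = %g, seed = %d\n",
              nrow(x$species), x$n_loci, x$locus_length, x$mu, x$seed))
  if (!is.null(x$events)) cat(sprintf("  %d introgression event(s)\n", nrow(x$events)))
  if (!is.null(x$f1_injections)) {
    cat(sprintf("  %d F1 injection(s)\n", sum(x$f1_injections$count)))
  }
  invisible(x)
}

# Node ages (generations before present); tips at ~0 for ultrametric trees.
node_ages <- function(tree) {
  nn <- ape::Ntip(tree) + tree$Nnode
  depth <- numeric(nn)
  root <- ape::Ntip(tree) + 1L
  # preorder: parents before children
  edges <- ape::reorder.phylo(tree, "cladewise")$edge
  el <- ape::reorder.phylo(tree, "cladewise")$edge.length
  for (i in seq_len(nrow(edges))) {
    depth[edges[i, 2]] <- depth[edges[i, 1]] + el[i]
  }
  max(depth) - depth
}

parent_age <- function(tree, ages, label) {
  tip <- match(label, tree$tip.label)
  if (is.na(tip)) abort(sprintf("unknown species label '%s'", label))
  ages[tree$edge[tree$edge[, 2] == tip, 1]]
}

# --- multispecies coalescent -------------------------------------------

# Simulate one genealogy for the sampled alleles under the MSC with
# introgression pulses. `tips_by_species`: named list, species -> vector of
# allele tip labels. `coal_denom`: named vector of per-population
# coalescent denominators for tip populations (2*Ne diploid nuclear,
# mtdna_scale*Ne haploid), plus value for ancestral populations via
# `ancestral_denom`. Uses the current RNG stream.
msc_simulate <- function(config, tips_by_species, coal_denom, ancestral_denom) {
  tree <- config$tree
  ages <- config$ages
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L

  # active lineages per population (population = species-tree node id)
  lin <- vector("list", ntip + tree$Nnode)
  denom <- numeric(ntip + tree$Nnode)
  for (s in names(tips_by_species)) {
    pop <- match(s, tree$tip.label)
    labs <- tips_by_species[[s]]
    lin[[pop]] <- lapply(labs, function(l) list(s = l, h = 0))
    denom[pop] <- coal_denom[[s]]
  }
  internal <- setdiff(seq_len(ntip + tree$Nnode), seq_len(ntip))
  denom[internal] <- ancestral_denom

  # timeline: introgression pulses + species-tree merges, ascending
  sched <- tibble(time = ages[internal], kind = "merge",
                  node = internal, donor = NA_integer_,
                  recipient = NA_integer_, proportion = NA_real_)
  # zero-strength pulses are dropped so they cannot perturb the RNG
  # stream: a seed-matched run with proportion 0 equals a run without
  # the event
  if (!is.null(config$events) && any(config$events$proportion > 0)) {
    ev <- config$events[config$events$proportion > 0, ]
    sched <- dplyr::bind_rows(sched, tibble(
      time = ev$time, kind = "pulse", node = NA_integer_,
      donor = match(ev$donor, tree$tip.label),
      recipient = match(ev$recipient, tree$tip.label),
      proportion = ev$proportion))
  }
  sched <- sched[order(sched$time), ]

  coalesce_in <- function(pop, t0, t1) {
    l <- lin[[pop]]
    repeat {
      k <- length(l)
      if (k < 2) break
      w <- rexp(1, rate = choose(k, 2) / denom[pop])
      if (t0 + w > t1) break
      t0 <- t0 + w
      pair <- sample.int(k, 2)
      a <- l[[pair[1]]]; b <- l[[pair[2]]]
      merged <- list(
        s = sprintf("(%s:%.8f,%s:%.8f)", a$s, t0 - a$h, b$s, t0 - b$h),
        h = t0)
      l[pair] <- NULL
      l[[length(l) + 1L]] <- merged
    }
    lin[[pop]] <<- l
    invisible(NULL)
  }

  t_now <- 0
  for (i in seq_len(nrow(sched))) {
    t_next <- sched$time[i]
    for (pop in which(lengths(lin) > 0)) coalesce_in(pop, t_now, t_next)
    if (sched$kind[i] == "merge") {
      node <- sched$node[i]
      kids <- tree$edge[tree$edge[, 1] == node, 2]
      lin[[node]] <- c(lin[[node]], unlist(lin[kids], recursive = FALSE))
      lin[kids] <- rep(list(NULL), length(kids))
    } else {
      p <- sched$proportion[i]
      from <- sched$recipient[i]; to <- sched$donor[i]
      k <- length(lin[[from]])
      if (k > 0 && p > 0) {
        move <- if (p >= 1) rep(TRUE, k) else runif(k) < p
        if (any(move)) {
          lin[[to]] <- c(lin[[to]], lin[[from]][move])
          lin[[from]] <- lin[[from]][!move]
        }
      }
    }
    t_now <- t_next
  }
  coalesce_in(root, t_now, Inf)
  stopifnot(length(lin[[root]]) == 1L)
  ape::read.tree(text = paste0(lin[[root]][[1]]$s, ";"))
}

individual_names <- function(species) {
  unlist(lapply(seq_len(nrow(species)), function(i) {
    sprintf("%s_%02d", species$name[i], seq_len(species$n_individuals[i]))
  }))
}

#' Simulate one gene tree under the multispecies coalescent
#'
#' Draws the genealogy of all sampled alleles for a single locus:
#' two allele lineages per diploid individual for nuclear loci (pair
#' coalescence rate 1/(2 Ne) within each population) or one lineage per
#' individual for the haploid, maternally inherited mtDNA locus (rate
#' 1/(`mtdna_scale` * Ne)). At each introgression pulse, every lineage
#' currently in the recipient population is independently rerouted to the
#' donor population with the pulse's probability.
#'
#' @param config A [sim_config()].
#' @param locus_index Locus number, used to derive the locus seed from
#'   `config$seed` (locus 0 is the mtDNA locus).
#' @param type `"nuclear"` or `"mtdna"`.
#' @param seed Optional override seed; by default the locus seed is
#'   derived deterministically from the config seed and `locus_index`, so
#'   any locus can be re-simulated in isolation.
#' @return An ultrametric `phylo` genealogy with branch lengths in
#'   generations; nuclear tips are `<individual>_a1` / `<individual>_a2`.
#' @export
simulate_gene_tree <- function(config, locus_index = 1L,
                               type = c("nuclear", "mtdna"), seed = NULL) {
  type <- match.arg(type)
  set.seed(if (is.null(seed)) child_seed(config$seed, locus_index) else seed)
  msc_draw(config, type)
}

# RNG-stream version (no seeding); used internally by simulate_community.
msc_draw <- function(config, type = "nuclear") {
  sp <- config$species
  if (type == "nuclear") {
    tips <- setNames(lapply(seq_len(nrow(sp)), function(i) {
      inds <- sprintf("%s_%02d", sp$name[i], seq_len(sp$n_individuals[i]))
      as.vector(rbind(paste0(inds, "_a1"), paste0(inds, "_a2")))
    }), sp$name)
    denom <- setNames(2 * sp$Ne, sp$name)
    anc <- 2 * config$ancestral_Ne
  } else {
    tips <- setNames(lapply(seq_len(nrow(sp)), function(i) {
      sprintf("%s_%02d", sp$name[i], seq_len(sp$n_individuals[i]))
    }), sp$name)
    denom <- setNames(config$mtdna_scale * sp$Ne, sp$name)
    anc <- config$mtdna_scale * config$ancestral_Ne
  }
  msc_simulate(config, tips, denom, anc)
}

#' Evolve sequences along a genealogy (finite-sites Jukes-Cantor)
#'
#' A uniform-random root sequence over {A,C,G,T} is propagated down the
#' tree; on each branch the number of substitution events is
#' Poisson(`mu` x branch length x `length`), each event hitting a uniform
#' random site and replacing its base with one of the three alternatives
#' (so repeat hits can revert, giving the exact Jukes-Cantor saturation
#' behaviour).
#'
#' @param tree `phylo` with branch lengths in generations.
#' @param length Sequence length in bp.
#' @param mu Substitution rate per site per generation (>= 0).
#' @param locus_id Label for the resulting alignment.
#' @param seed Optional seed; defaults to the current RNG stream.
#' @return A [locus_aln()] with one sequence per tip.
#' @export
evolve_sequences <- function(tree, length, mu, locus_id = "locus", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (any(tree$edge.length < 0)) abort("negative branch length")
  stopifnot(mu >= 0, length >= 1)
  ntip <- ape::Ntip(tree)
  ord <- ape::reorder.phylo(tree, "cladewise")
  seqs <- vector("list", ntip + tree$Nnode)
  seqs[[ntip + 1L]] <- sample.int(4L, length, replace = TRUE)
  for (i in seq_len(nrow(ord$edge))) {
    parent <- ord$edge[i, 1]; child <- ord$edge[i, 2]
    s <- seqs[[parent]]
    n_ev <- rpois(1, mu * ord$edge.length[i] * length)
    if (n_ev > 0) {
      sites <- sample.int(length, n_ev, replace = TRUE)
      for (site in sites) {
        s[site] <- sample(setdiff(1:4, s[site]), 1)
      }
    }
    seqs[[child]] <- s
  }
  mat <- do.call(rbind, lapply(seq_len(ntip), function(i) {
    c("A", "C", "G", "T")[seqs[[i]]]
  }))
  rownames(mat) <- tree$tip.label
  locus_aln(locus_id, mat)
}

#' Simulate a full synthetic community with known truth
#'
#' Runs the MSC simulator over all nuclear loci and the mtDNA locus,
#' evolves Jukes-Cantor sequences, applies per-locus missingness by
#' dropping whole individuals (both alleles) with probability
#' `missing_rate`, and injects any configured F1 hybrids. The returned
#' bundle records the complete truth (true genealogies, introgression
#' events, hybrid identities) so downstream inferences can be scored.
#'
#' Each locus uses a seed derived from `config$seed` and the locus index,
#' so the bundle is bit-for-bit reproducible and individual loci can be
#' re-simulated in isolation with [simulate_gene_tree()].
#'
#' @param config A [sim_config()].
#' @return An object of class `hyb_bundle`: list with `alignments` (named
#'   list of [locus_aln()]), `mtdna` (one haploid `locus_aln`), `map`
#'   (species-map tibble), `true_gene_trees` (list of `phylo`), `truth`
#'   (list: `individuals` tibble with `is_hybrid`/parents, `events`),
#'   and `config`.
#' @export
simulate_community <- function(config) {
  sp <- config$species
  inds <- individual_names(sp)
  map <- species_map(
    individual = inds,
    species = rep(sp$name, sp$n_individuals),
    host = rep(sp$host, sp$n_individuals),
    foundress = rep(sp$foundress, sp$n_individuals))

  alignments <- vector("list", config$n_loci)
  trees <- vector("list", config$n_loci)
  for (k in seq_len(config$n_loci)) {
    set.seed(child_seed(config$seed, k))
    tr <- msc_draw(config, "nuclear")
    locus_id <- sprintf("uce-%04d", k)
    aln <- evolve_sequences(tr, config$locus_length, config$mu, locus_id)
    if (config$missing_rate > 0) {
      drop <- map$individual[runif(nrow(map)) < config$missing_rate]
      keep <- !(strip_allele(aln_labels(aln)) %in% drop)
      if (sum(keep) >= 2) {
        aln <- locus_aln(locus_id, aln$mat[keep, , drop = FALSE])
      }
    }
    alignments[[k]] <- aln
    trees[[k]] <- tr
  }
  names(alignments) <- vapply(alignments, `[[`, character(1), "locus_id")

  set.seed(child_seed(config$seed, 0))
  mt_tree <- msc_draw(config, "mtdna")
  mtdna <- evolve_sequences(mt_tree, config$mtdna_length, config$mu, "mtdna")

  truth <- list(
    individuals = tibble(individual = map$individual, species = map$species,
                         is_hybrid = FALSE, parentA = NA_character_,
                         parentB = NA_character_),
    events = config$events)
  bundle <- structure(list(alignments = alignments, mtdna = mtdna, map = map,
                           true_gene_trees = trees, truth = truth,
                           config = config),
                      class = "hyb_bundle")
  if (!is.null(config$f1_injections)) {
    fi <- config$f1_injections
    for (i in seq_len(nrow(fi))) {
      bundle <- inject_f1(bundle, fi$parentA[i], fi$parentB[i], fi$count[i],
                          seed = child_seed(config$seed, 1e6 + i))
    }
  }
  bundle
}

#' @export
print.hyb_bundle <- function(x, ...) {
  cat(sprintf("<hyb_bundle> %d individuals (%d species), %d nuclear loci + mtDNA\n",
              nrow(x$map), length(unique(x$truth$individuals$species[!x$truth$individuals$is_hybrid])),
              length(x$alignments)))
  nh <- sum(x$truth$individuals$is_hybrid)
  if (nh > 0) cat(sprintf("  %d injected F1 hybrid(s)\n", nh))
  invisible(x)
}

#' Inject first-generation hybrids into a simulated bundle
#'
#' Each injected F1 receives, locus by locus, allele 1 copied from a
#' random present individual of `parentA` (a random one of its two
#' alleles) and allele 2 likewise from `parentB`; its mtDNA is copied
#' from a random `parentA` individual (maternal inheritance). At loci
#' where a parental panel is entirely missing the hybrid is missing too.
#' Injected individuals are recorded as hybrids in the bundle truth and
#' appear in the species map under the species label
#' `"<parentA>x<parentB>"`.
#'
#' @param bundle A `hyb_bundle` from [simulate_community()].
#' @param parentA,parentB Species labels present in the bundle.
#' @param count Number of F1 individuals to add (0 returns the bundle
#'   unchanged).
#' @param seed Optional seed for the parental draws.
#' @return The augmented `hyb_bundle`.
#' @export
inject_f1 <- function(bundle, parentA, parentB, count, seed = NULL) {
  if (count == 0) return(bundle)
  if (!is.null(seed)) set.seed(seed)
  map <- bundle$map
  for (p in c(parentA, parentB)) {
    if (!p %in% map$species) abort(sprintf("unknown parent species '%s'", p))
  }
  existing <- sum(bundle$truth$individuals$is_hybrid)
  hyb_species <- paste0(parentA, "x", parentB)
  for (j in seq_len(count)) {
    ind <- sprintf("%s_f1_%02d", hyb_species, existing + j)
    for (k in seq_along(bundle$alignments)) {
      aln <- bundle$alignments[[k]]
      pick <- function(parent) {
        pres <- intersect(aln_individuals(aln),
                          map$individual[map$species == parent])
        if (length(pres) == 0) return(NULL)
        donor <- pres[sample.int(length(pres), 1)]
        allele <- paste0(donor, c("_a1", "_a2"))[sample.int(2, 1)]
        aln$mat[allele, ]
      }
      a1 <- pick(parentA); a2 <- pick(parentB)
      if (is.null(a1) || is.null(a2)) next
      mat <- rbind(aln$mat, a1, a2)
      rownames(mat) <- c(rownames(aln$mat), paste0(ind, "_a1"), paste0(ind, "_a2"))
      bundle$alignments[[k]] <- locus_aln(aln$locus_id, mat)
    }
    mt <- bundle$mtdna
    mothers <- intersect(rownames(mt$mat), map$individual[map$species == parentA])
    if (length(mothers) > 0) {
      mother <- mothers[sample.int(length(mothers), 1)]
      mat <- rbind(mt$mat, mt$mat[mother, ])
      rownames(mat) <- c(rownames(mt$mat), ind)
      bundle$mtdna <- locus_aln(mt$locus_id, mat)
    }
    bundle$map <- dplyr::bind_rows(bundle$map, tibble(
      individual = ind, species = hyb_species,
      host = NA_character_, foundress = NA_real_))
    bundle$truth$individuals <- dplyr::bind_rows(bundle$truth$individuals, tibble(
      individual = ind, species = hyb_species, is_hybrid = TRUE,
      parentA = parentA, parentB = parentB))
  }
  bundle
}

#' Write a simulated bundle to disk as plain-text files
#'
#' One FASTA per nuclear locus plus `mtdna.fasta`, a TSV species map,
#' the true gene trees as one Newick per line and the truth record as
#' JSON.
#'
#' @param bundle A `hyb_bundle`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_locus_fasta_dir(bundle$alignments, file.path(dir, "loci"))
  write_locus_fasta_dir(list(bundle$mtdna), dir)
  write_species_map(bundle$map, file.path(dir, "species_map.tsv"))
  ape::write.tree(do.call(c, lapply(bundle$true_gene_trees, list)) |>
                    (\(x) { class(x) <- "multiPhylo"; x })(),
                  file.path(dir, "true_gene_trees.nwk"))
  truth <- list(individuals = bundle$truth$individuals,
                events = bundle$truth$events)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       dataframe = "rows", na = "null", auto_unbox = TRUE)
  invisible(dir)
}
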