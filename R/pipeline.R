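#' Run the full hybridization screen end to end
#'
#' Orchestrates simulate -> completeness filter -> diversity statistics
#' -> gene trees -> monophyly proportions and threshold summary ->
#' foundress correlations -> mtDNA barcode gap -> per-pair admixture
#' screens -> comparison against the simulation truth. The run is a
#' pure function of the configuration (including its seed): repeating
#' it reproduces the report exactly.
#'
#' @param config A [sim_config()].
#' @param screen_pairs Two-column matrix/data frame of species pairs to
#'   screen for hybrids. Default: the parent pairs of any configured F1
#'   injections, plus pairs of species sharing a host.
#' @param thresholds Monophyly thresholds for the summary.
#' @param gene_trees `"true"` (the simulated genealogies) or `"nj"`
#'   (neighbor-joining re-estimates from the filtered alignments).
#' @param completeness Locus completeness threshold (default 0.70).
#' @return Object of class `hyb_run` with elements `manifest` (config,
#'   seed, per-stage seeds, stage tallies, timestamp), `report` (list
#'   of tibbles: `diversity`, `monophyly`, `threshold_summary`,
#'   `correlations`, `barcode`, `hybrid_calls`, `confusion`) and
#'   `bundle` (the simulated data with truth).
#' @examples
#' \donttest{
#' cfg <- sim_config("((A:10000,B:10000):10000,C:20000);",
#'                   tibble::tibble(name = c("A", "B", "C"),
#'                                  n_individuals = 4, Ne = 1000),
#'                   n_loci = 20, locus_length = 200, mu = 2e-6, seed = 7)
#' run <- run_pipeline(cfg)
#' run$report$monophyly
#' }
#' @export
run_pipeline <- function(config, screen_pairs = NULL,
                         thresholds = c(0.90, 0.95),
                         gene_trees = c("true", "nj"), completeness = 0.70) {
  gene_trees <- match.arg(gene_trees)
  t_start <- Sys.time()
  stage_seeds <- c(simulate = config$seed,
                   snp = child_seed(config$seed, 2e6),
                   screen = child_seed(config$seed, 3e6))

  bundle <- simulate_community(config)
  map <- bundle$map
  pure_map <- map[!map$individual %in%
                    bundle$truth$individuals$individual[bundle$truth$individuals$is_hybrid], ]

  filtered <- filter_by_completeness(bundle$alignments, map, completeness,
                                     quiet = TRUE)
  diversity <- species_diversity(filtered, pure_map)

  trees <- if (gene_trees == "true") bundle$true_gene_trees else
    estimate_gene_trees(filtered)
  mono <- monophyly_proportions(trees, pure_map)
  thr <- threshold_summary(mono, thresholds)

  stats_tbl <- dplyr::left_join(diversity,
                                mono[, c("species", "proportion")],
                                by = "species")
  n_found <- sum(!is.na(dplyr::distinct(pure_map, .data$species,
                                        .data$foundress)$foundress))
  correlations <- if (n_found >= 3) {
    foundress_correlations(stats_tbl, pure_map)
  } else tibble(statistic = character(), rho = numeric(),
                p_value = numeric(), n = integer(), method = character())

  # species-level barcode statistics: injected hybrids are screened below,
  # not treated as species of their own
  mt_d <- suppressWarnings(jc_distance_matrix(bundle$mtdna))
  mt_keep <- rownames(mt_d) %in% pure_map$individual
  barcode <- barcode_gap(mt_d[mt_keep, mt_keep, drop = FALSE], pure_map)

  if (is.null(screen_pairs)) {
    pairs <- list()
    if (!is.null(config$f1_injections)) {
      pairs <- c(pairs, lapply(seq_len(nrow(config$f1_injections)), function(i) {
        c(config$f1_injections$parentA[i], config$f1_injections$parentB[i])
      }))
    }
    sp <- config$species
    shared <- split(sp$name, sp$host)
    for (g in shared[lengths(shared) > 1]) {
      pairs <- c(pairs, utils::combn(g, 2, simplify = FALSE))
    }
    pairs <- unique(lapply(pairs, sort))
  } else {
    sp_mat <- as.matrix(screen_pairs)
    pairs <- lapply(seq_len(nrow(sp_mat)), function(i) sp_mat[i, ])
  }

  screens <- list()
  calls <- tibble()
  for (i in seq_along(pairs)) {
    pa <- pairs[[i]][1]; pb <- pairs[[i]][2]
    hyb_inds <- map$individual[map$species %in%
                                 c(paste0(pa, "x", pb), paste0(pb, "x", pa))]
    scr <- screen_pair(bundle$alignments, map, pa, pb,
                       extra_individuals = hyb_inds,
                       threshold = completeness,
                       seed = child_seed(stage_seeds[["screen"]], i))
    screens[[paste(pa, pb, sep = "-")]] <- scr
    calls <- dplyr::bind_rows(calls, scr$calls)
  }

  confusion <- if (nrow(calls) > 0) {
    truth <- bundle$truth$individuals
    joined <- dplyr::left_join(calls, truth[, c("individual", "is_hybrid")],
                               by = "individual")
    joined$called_hybrid <- joined$klass %in% c("F1-like", "backcross-like")
    dplyr::count(joined, .data$is_hybrid, .data$called_hybrid, .data$klass)
  } else tibble()

  manifest <- list(config = config, seed = config$seed,
                   stage_seeds = stage_seeds,
                   n_loci_simulated = length(bundle$alignments),
                   filter_counts = attr(filtered, "filter_counts"),
                   gene_trees = gene_trees,
                   n_pairs_screened = length(pairs),
                   started = t_start, finished = Sys.time())
  structure(list(manifest = manifest,
                 report = list(diversity = diversity, monophyly = mono,
                               threshold_summary = thr,
                               correlations = correlations,
                               barcode = barcode, hybrid_calls = calls,
                               confusion = confusion),
                 screens = screens, bundle = bundle),
            class = "hyb_run")
}

#' @export
print.hyb_run <- function(x, ...) {
  cat(sprintf("<hyb_run> seed %d: %d loci kept of %d simulated\n",
              x$manifest$seed, x$manifest$filter_counts[["kept"]],
              x$manifest$n_loci_simulated))
  cat(sprintf("  monophyly: min %.2f; barcode gap %s\n",
              min(x$report$monophyly$proportion, na.rm = TRUE),
              if (isTRUE(x$report$barcode$gap)) "present" else "absent"))
  if (nrow(x$report$hybrid_calls) > 0) {
    hy <- sum(x$report$hybrid_calls$klass %in% c("F1-like", "backcross-like"))
    cat(sprintf("  screen: %d hybrid call(s) over %d pair(s)\n",
                hy, x$manifest$n_pairs_screened))
  }
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' TSV per table plus one JSON summary.
#'
#' @param run A `hyb_run`.
#' @param dir Output directory.
#' @export
write_report <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rep <- run$report
  readr::write_tsv(rep$diversity, file.path(dir, "diversity.tsv"))
  readr::write_tsv(rep$monophyly, file.path(dir, "monophyly.tsv"))
  readr::write_tsv(rep$threshold_summary$summary, file.path(dir, "monophyly_thresholds.tsv"))
  readr::write_tsv(rep$correlations, file.path(dir, "correlations.tsv"))
  if (nrow(rep$hybrid_calls) > 0) {
    readr::write_tsv(rep$hybrid_calls, file.path(dir, "hybrid_calls.tsv"))
  }
  summary <- list(
    seed = run$manifest$seed,
    loci_kept = unname(run$manifest$filter_counts[["kept"]]),
    monophyly_min = min(rep$monophyly$proportion, na.rm = TRUE),
    barcode = list(intra_pct = rep$barcode$intra_pct,
                   inter_pct = rep$barcode$inter_pct, gap = rep$barcode$gap),
    hybrid_calls = if (nrow(rep$hybrid_calls) > 0)
      sum(rep$hybrid_calls$klass %in% c("F1-like", "backcross-like")) else 0)
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' A small default demonstration configuration
#'
#' Three deeply diverged species (divergences of 10 and 20 times Ne
#' generations), four diploid individuals each, with an injected F1
#' between the two closer species -- enough to exercise every pipeline
#' stage in seconds.
#'
#' @param seed Seed for the run.
#' @param n_loci Number of nuclear loci (default 60).
#' @return A [sim_config()].
#' @export
demo_config <- function(seed = 1L, n_loci = 60L) {
  sim_config(
    species_tree = "((A:10000,B:10000):10000,C:20000);",
    species = tibble(name = c("A", "B", "C"), n_individuals = 4L,
                     Ne = 1000, foundress = c(1.2, 2.5, 1.0)),
    n_loci = n_loci, locus_length = 300, mu = 5e-6,
    f1_injections = tibble(parentA = "A", parentB = "B", count = 1L),
    missing_rate = 0.05, seed = seed)
}
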