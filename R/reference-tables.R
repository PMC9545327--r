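#' Published sampling table for the Panamanian fig-wasp community
#'
#' Sampling summary for the 19 in-group *Pegoscapus* pollinator species
#' of the Barro Colorado Island strangler-fig community: host fig(s),
#' number of wasps sequenced and mean foundress number per syconium of
#' the host (averaged across hosts for shared pollinators; NA where no
#' foundress survey exists). Bundled so the community-level rank
#' correlations and power calculations can be reproduced from printed
#' values without any sequence download.
#'
#' @return Tibble with `species`, `host`, `n_sequenced`, `foundress`.
#' @seealso [wasp_diversity_table()], [foundress_correlations()]
#' @export
wasp_sampling_table <- function() {
  tibble::tribble(
    ~species,                  ~host,                              ~n_sequenced, ~foundress,
    "P. gemellus",             "F. bullenei and F. popenoei",      21L, 1.980,
    "P. sp. 1",                "F. bullenei",                       7L, 1.410,
    "P. sp. 2",                "F. popenoei",                      11L, 2.550,
    "P. sp. 3",                "F. americana and F. colubrinae",   16L, 1.005,
    "P. insularis",            "F. americana",                      2L, 1.000,
    "P. orozcoi",              "F. colubrinae",                     8L, 1.010,
    "P. hoffmeyeri sp. A",     "F. obtusifolia",                    4L, 1.050,
    "P. hoffmeyeri sp. B",     "F. obtusifolia",                   10L, 1.050,
    "P. baschierii",           "F. turbinata",                      8L, NA,
    "P. estherae",             "F. costaricana",                    5L, NA,
    "P. grandii",              "F. crocata",                       17L, 4.530,
    "P. herrei",               "F. paraensis",                     12L, 1.050,
    "P. longiceps",            "F. dugandii",                       6L, 2.160,
    "P. lopesi",               "F. aff. crocata",                  10L, 2.570,
    "P. piceipes",             "F. nymphaeifolia",                  6L, 2.640,
    "P. silvestrii",           "F. pertusa",                        7L, NA,
    "P. tonduzi",              "F. citrifolia",                     6L, 1.210,
    "P. sp. 4",                "F. aurea",                          8L, NA,
    "P. sp. 5",                "F. sp. 1",                          8L, NA)
}

#' Published per-species diversity and monophyly table
#'
#' Per-species nuclear summary statistics for the same community:
#' mean nucleotide diversity (`pi`), mean segregating sites per locus
#' (`ss`), mean Watterson's theta per site (`theta_w`), and the
#' proportion of gene trees in which the species is monophyletic
#' (`monophyly`, with the number of testable trees `n_trees`). Means
#' are over ~1500 ultraconserved-element loci.
#'
#' @return Tibble with `species`, `pi`, `ss`, `theta_w`, `monophyly`,
#'   `n_trees`.
#' @export
wasp_diversity_table <- function() {
  tibble::tribble(
    ~species,              ~pi,    ~ss,    ~theta_w, ~monophyly, ~n_trees,
    "P. gemellus",         0.0005, 2.0410, 0.0012,   0.82, 1502L,
    "P. sp. 1",            0.0005, 0.5179, 0.0005,   0.92, 1482L,
    "P. sp. 2",            0.0013, 2.4979, 0.0016,   0.89, 1496L,
    "P. sp. 3",            0.0004, 0.8855, 0.0007,   0.91, 1499L,
    "P. insularis",        0.0003, 0.1600, 0.0003,   0.98, 1337L,
    "P. orozcoi",          0.0024, 2.3022, 0.0021,   0.94, 1484L,
    "P. hoffmeyeri sp. A", 0.0004, 0.3750, 0.0004,   0.93, 1479L,
    "P. hoffmeyeri sp. B", 0.0004, 0.6432, 0.0005,   0.87, 1493L,
    "P. baschierii",       0.0005, 0.6733, 0.0006,   0.95, 1484L,
    "P. estherae",         0.0007, 0.8545, 0.0008,   0.99, 1467L,
    "P. grandii",          0.0029, 8.1135, 0.0047,   0.96, 1501L,
    "P. herrei",           0.0008, 1.4675, 0.0011,   0.91, 1499L,
    "P. longiceps",        0.0009, 1.0470, 0.0009,   1.00, 1472L,
    "P. lopesi",           0.0013, 2.1351, 0.0015,   0.99, 1484L,
    "P. piceipes",         0.0015, 1.8930, 0.0015,   0.99, 1476L,
    "P. silvestrii",       0.0004, 0.4931, 0.0004,   0.97, 1488L,
    "P. tonduzi",          0.0006, 0.7403, 0.0006,   0.99, 1467L,
    "P. sp. 4",            0.0005, 0.7237, 0.0006,   0.99, 1490L,
    "P. sp. 5",            0.0003, 0.4135, 0.0004,   0.96, 1491L)
}
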