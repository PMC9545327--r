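Package: hybscreen
Title: Community-Wide Screening for Hybridization and Introgression in
    Fig-Pollinator Wasps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for screening multilocus, phased
    sequence data from communities of fig-pollinating wasps (or any set of
    closely sampled species) for evidence of hybridization and
    introgression. Implements per-locus nucleotide diversity, segregating
    sites and Watterson's theta with Spearman rank correlations against
    foundress number; a gene-tree monophyly-proportion statistic with
    threshold summaries; mtDNA barcode-gap analysis under Jukes-Cantor or
    pairwise maximum-likelihood GTR distances; unlinked-SNP extraction,
    principal components with species-mean imputation, and a
    diagnostic-locus hybrid-index classifier for F1 and backcross
    detection; and closed-form hybrid-detection power and island-model
    FST calculations. A built-in multispecies-coalescent simulator with
    introgression pulses and F1 injection provides synthetic communities
    with known truth so the whole screen is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
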