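---
title: "Screening a wasp community for hybridization and introgression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening a wasp community for hybridization and introgression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybscreen)
```

## Motivation and model

Fig-pollinating wasps mate inside the syconium their mother pollinated.
Hybridization between pollinator species therefore requires that
foundresses of two species oviposit in the same syconium, that their
offspring mate, and that the resulting diploid F1 daughters survive to
reproduce (haploid males carry only their mother's genome, so only
daughters can be hybrid). `hybscreen` packages the statistics used to
screen multilocus, phased sequence data from such a community for any
trace of this process, together with a simulator that generates
communities where the truth is known.

The package assumes tabular, tidy-style interfaces: species maps,
diversity tables, monophyly reports, SNP genotypes and hybrid calls are
all tibbles; alignments live in a light matrix container read and
written as FASTA, and gene trees are `ape` `phylo` objects.

## The synthetic community generator

The simulator draws gene trees under the multispecies coalescent: within
a population of effective size Ne, each pair of lineages coalesces at
rate 1/(2Ne) per generation (so the expected pairwise TMRCA is 2Ne);
populations merge at the species-tree nodes; all times are in
generations, which avoids any unit ambiguity between mutation rates and
branch lengths. The haploid, maternally inherited mtDNA locus uses an
effective size of `mtdna_scale * Ne` (default 0.5). Ancestral
populations take a configurable size, by default the mean of the tip
sizes.

An introgression event is modelled as a pulse: at its time, every
lineage currently in the recipient population is independently rerouted
into the donor population with the event's probability. A
zero-proportion pulse is dropped from the schedule entirely, so it
cannot perturb the random-number stream — a seed-matched run with
proportion 0 is bit-for-bit identical to a run without the event.

Sequences evolve by finite-sites Jukes–Cantor: a uniform random root
sequence, a Poisson(μ · branch length · L) number of substitution
events per branch, each hitting a uniform site and switching it to one
of the three other bases. Repeat hits can revert, which yields the
exact JC saturation curve p = 3/4·(1 − e^(−4d/3)); the tests verify
this against the closed form.

F1 injection copies, locus by locus, one random allele from a random
individual of each parental species, and the mtDNA from the maternal
(first-named) parent. Missingness drops whole individuals per locus —
both alleles — with the configured probability, matching the semantics
of the standard "70% of individuals" locus filter applied downstream.

The defaults were chosen once for statistical clarity rather than to
mimic any particular empirical system, whose generation times, mutation
rates and divergence depths are not known: tip Ne = 1000–10000 with μ
set so that within-species diversity is θ = 4·Ne·μ ≈ 0.004–0.02, and
species divergences of at least 10·Ne generations, deep enough that the
coalescent predicts near-complete lineage sorting (monophyly proportion
≥ 0.95). An optional monotone map Ne = base · foundress can tie
effective size to foundress number; it is off by default.

What the simulator deliberately omits: recombination within loci,
selection, demographic change, and haploid males (all sampled
individuals are diploid females, as in sequenced pollinator offspring).
Passing tests on these simulations therefore validate the statistical
machinery, not the realism of any particular parameter choice for real
communities.

## Diversity statistics

Per locus and allele subset, `locus_pi()` averages pairwise differences
over pairwise comparable sites (both bases unambiguous — pairwise
deletion), `locus_segregating_sites()` counts columns with two or more
distinct unambiguous bases, and `locus_watterson()` computes
S/(a_{n−1}·L_eff) with L_eff the number of columns where at least two
alleles carry a base. These missing-data conventions maximise data use
and are fully specified, which makes every value reproducible by brute
force; the tests do exactly that. Per-species summaries average over
loci unweighted by length, and the across-locus SD is reported with the
population (divisor n) convention.

`spearman_cor()` uses mid-ranks (so ties are handled deterministically)
and reports rho as the Pearson correlation of rank vectors. The p-value
is exact by full permutation enumeration for n ≤ 9 and a t
approximation otherwise; since printed p-values in the literature
depend on the approximation used, rho is the quantity of record here
and p is informational.

## Gene trees and monophyly

Per-locus trees at desk scale come from neighbor joining on
Jukes–Cantor distances (`ape::nj`); saturated pairs (p ≥ 0.75) are
capped at a configurable distance (default 5 substitutions/site) and
negative NJ branches are clamped to zero. Full likelihood tree search
is out of scope — the monophyly statistic, not the tree method, is the
analysis — and precomputed Newick trees (for example the simulator's
true genealogies) are accepted wherever trees are consumed.

`is_monophyletic()` tests splits: a tip set is monophyletic when some
edge's removal bipartitions the tips into exactly that set and its
complement. This unrooted semantics coincides with rooted clade
monophyly whenever the outgroup is outside the subset, and is invariant
to re-rooting. Allele tips are collapsed to individuals before testing,
and a tree counts as tested for a species only when at least two of its
individuals appear — both-alleles presence is not required, since
sampling is of individuals. Threshold summaries report the percentage
of species at or above each threshold, rounded half-up to whole
percent.

## Barcode gap

`corrected_distances()` offers JC and a pairwise-ML GTR: base
frequencies are taken empirically from the whole alignment, the six
exchangeabilities are estimated once by maximising the two-sequence
likelihood of the pooled site-pattern counts (BFGS on log parameters,
GT fixed to 1), and each pair's distance is then a bounded
one-dimensional likelihood maximisation under the fitted rate matrix.
No gamma rate variation is used. With equal exchangeabilities and
uniform frequencies the model collapses to JC, which the tests verify
to 1e-6; if the global fit fails to converge the function falls back to
JC with a warning. `barcode_gap()` averages distances within species
(≥ 2 sequences required; singletons are NA and excluded) and between
species pairs, both unweighted, and flags a gap when the smallest pair
mean exceeds the largest within-species mean. Reproducing empirical
community values would require the original read data; the module's
validation is therefore property-based plus toy arithmetic oracles.

## SNP extraction and the admixture screen

`extract_unlinked_snps()` takes one SNP per locus: candidate columns
have exactly two distinct unambiguous bases (triallelic and invariant
columns are excluded), the candidate with the highest sample coverage
wins, and coverage ties break uniformly at random under the given seed.
Coverage is counted in allele copies by default — the finer-grained
choice — with a switch to individual-based counting
(`coverage_unit = "individuals"`). Genotypes count copies of the minor
allele (global frequency, alphabetical tie-break, so the coding is
deterministic), and are missing whenever either allele of an individual
is missing at the chosen column. Alignment columns are 0-based
internally and 1-based in reports.

`snp_pca()` imputes missing genotypes with the within-species mean for
that SNP (the standard practice for population-structure PCA; a global
mean is the fallback for a species with no data at a SNP), centres
columns without scaling, and decomposes by SVD.

The hybrid classifier replaces model-based clustering (Structure's
MCMC, TreeMix's graph likelihood), which is deliberately not
reimplemented: at fixed inter-parental differences, genotypes alone
separate the hypotheses. For diagnostic loci (`diagnostic_loci()`,
frequency difference ≥ 1 by default), an individual's hybrid index is
the fraction of its allele copies carrying the parent-B allele and het
the fraction of heterozygous diagnostic loci. An F1 must sit at
(0.5, 1); a first-generation backcross to A has expectation
(0.25, 0.5). `classify_hybrids()` applies fixed windows — F1-like for
index in [0.4, 0.6] with het ≥ 0.9, pure at index ≤ 0.05 or ≥ 0.95 —
and refuses to call anything from fewer than 20 informative loci
(`ambiguous`). On simulated communities at default settings this screen
has specificity and sensitivity 1, which the acceptance tests measure
over replicate simulations.

## Power and gene-flow arithmetic

`detect_prob(f, n) = 1 − (1 − f)^n` is the binomial chance of catching
at least one hybrid; `required_n()` inverts it. `island_fst()` uses
Wright's infinite-island equilibrium F_ST = 1/(1 + 4·Ne·m) — the
standard closed form for turning a hypothetical migration rate into an
expected differentiation. Percentages are reported to one decimal.

## Pipeline and reproducibility

`run_pipeline()` chains simulate → filter → diversity → trees →
monophyly → correlations → barcode → per-pair screens → truth
comparison. One user seed fans out deterministically to per-locus and
per-stage child seeds (`seed · 48271 + k mod 2³¹−1`), so any locus or
stage can be re-run in isolation and the whole run is a pure function
of its configuration; the tests assert bit-for-bit identity of repeated
runs. Screens process each species pair on the pair's own data subset
(subset, re-filter, re-extract SNPs), mirroring per-system processing
of host-sharing communities.

Problem sizes used in the validation suite are chosen for statistical
resolution at desk scale: 2000 coalescent replicates for the TMRCA
check (Monte-Carlo error ≈ 2%), 500 loci for the θ recovery check
(≈ 4% error against a 10% band), 100–150 loci and 20 replicates for
the monotonicity and specificity/sensitivity properties.

## Known limitations

- NJ+JC gene trees underperform likelihood methods on saturated or
  rate-heterogeneous data; for empirical work, import externally
  estimated trees instead.
- The GTR fit pools site patterns across all pairs; for very divergent
  sequence sets a per-pair fit could differ.
- The hybrid classifier assumes the parental panels are correctly
  assigned and nearly fixed at diagnostic loci; pervasive ongoing gene
  flow would erode fixed differences and with them the diagnostic set.
- The simulator's clean JC sequences lack alignment error, indels and
  base-composition bias, all present in real capture data — results on
  simulations bound what the statistics can do, not what any given
  dataset will support.

## A complete run

```{r, eval = FALSE}
run <- run_pipeline(demo_config(seed = 11, n_loci = 80))
run$report$threshold_summary$summary
run$report$barcode
autoplot(run$screens[[1]]$pca)
autoplot(run$screens[[1]])
```
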