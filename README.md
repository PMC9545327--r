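# hybscreen

Community-wide screening for hybridization and introgression in
fig-pollinator wasps.

## The problem

Fig-pollinating wasps (*Pegoscapus*, Agaonidae) reproduce inside the
syconia of their host figs. When two or more foundress wasps of
different species oviposit in the same syconium, their offspring can
mate, so communities in which pollinator species share hosts present
clear opportunities for hybridization — yet whether hybrids and
introgression actually occur must be read out of multilocus sequence
data. `hybscreen` implements the complete desk-scale analysis chain for
that question, for anyone working with phased multilocus alignments
from a community of closely sampled species:

- **Diversity statistics** per species and locus: nucleotide diversity
  (π), segregating sites (S) and Watterson's theta
  (θ_w = S / (a_{n−1} · L)), with Spearman rank correlations (mid-rank
  ties, exact permutation p for n ≤ 9) against foundress number.
- **Gene-tree monophyly proportions**: the fraction of per-locus gene
  trees in which each species is monophyletic (split semantics, allele
  tips collapsed to individuals, ≥ 2 individuals required), with
  threshold summaries.
- **mtDNA barcode gap**: intraspecific vs interspecific corrected
  distances under Jukes–Cantor or pairwise maximum-likelihood GTR.
- **Admixture screen**: unlinked-SNP extraction (one highest-coverage
  biallelic SNP per locus), PCA with within-species mean imputation,
  and a diagnostic-locus classifier scoring each individual's hybrid
  index h (fraction of parent-B alleles at fixed differences) and
  interspecific heterozygosity — an F1 sits at (h, het) = (0.5, 1).
- **Power calculations**: P(detect) = 1 − (1 − f)^n for hybrid
  frequency f and sample size n, the minimal n reaching a target, and
  Wright's island-model F_ST = 1 / (1 + 4·Ne·m).
- **A multispecies-coalescent simulator** with introgression pulses and
  F1 injection, so every stage can be validated against known truth
  without any sequence download.

## Worked example

Simulate a three-species community (divergences of 10·Ne and 20·Ne
generations, four diploid individuals each, one injected F1 between A
and B), and run the whole screen:

```r
library(hybscreen)
run <- run_pipeline(demo_config(seed = 11, n_loci = 80))
run
#> <hyb_run> seed 11: 80 loci kept of 80 simulated
#>   monophyly: min 1.00; barcode gap present
#>   screen: 1 hybrid call(s) over 1 pair(s)

run$report$diversity
#> # A tibble: 3 x 8
#>   species n_loci mean_pi  sd_pi mean_ss sd_ss mean_theta_w sd_theta_w
#> 1 A           80  0.0185 0.0112    14.0  7.50       0.0184    0.00968
#> 2 B           80  0.0208 0.0133    15.1  8.35       0.0200    0.0110
#> 3 C           80  0.0206 0.0121    15.8  7.94       0.0206    0.0105
```

Mean π per species lands on the neutral expectation 4·Ne·μ = 0.02 for
the simulated Ne = 1000, μ = 5×10⁻⁶. Every species is monophyletic in
all 80 gene trees (complete lineage sorting at this divergence), and
the mtDNA barcode gap is wide open (0.49% intraspecific vs 17.90%
interspecific). The screen scores every individual at fixed A/B
differences:

```r
dplyr::select(run$report$hybrid_calls, individual, hybrid_index, het, klass)
#>   individual hybrid_index   het klass
#> 1 A_01                0       0  pure-A
#> ...
#> 9 AxB_f1_01           0.5     1  F1-like
```

The injected F1 is recovered exactly at hybrid index 0.5 with full
heterozygosity; all pure individuals are called pure. Community-level
power arithmetic:

```r
detect_prob(0.009, 14)   # 0.119 -> an 11.9% chance of catching a hybrid
required_n(0.009, 0.5)   # 77 wasps for a 50% chance
island_fst(1000, 0.009)  # Nm = 9, Fst = 1/37 ~ 0.027
```

With an F1 frequency of 0.009 (4 hybrid broods in 457), a sample of 14
wasps detects a hybrid with only 11.9% probability, and were that rate
effective migration it would hold F_ST below 0.03 — so strong observed
differentiation implies F1s are not a bridge to gene flow.

The bundled `wasp_sampling_table()` / `wasp_diversity_table()` give the
published 19-species community summaries; `foundress_correlations()`
on them reproduces the reported rank correlations (ρ = .687 for π,
.611 for S, .604 for θ_w, .280 for monophyly).

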