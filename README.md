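# allelicER

Quantitative proteomics of endoplasmic-reticulum (ER) remodelling across
an ER-phagy receptor allelic series.

ER-phagy receptors (FAM134A/B/C, TEX264, CCPG1, ...) target ER membranes
and content for lysosomal degradation. Their combinatorial contributions
can be dissected with an *allelic series* — genotypes built by sequential
deletion (WT → DKO → TKO → QKO → PKO) and profiled together in one
tandem-mass-tag (TMT) plex. `allelicER` implements the analysis chain for
such experiments, for proteomics analysts and cell biologists working on
selective autophagy:

- **TMT quantification**: PSM filtering on summed signal-to-noise (> 200)
  and isolation purity (> 0.5), channel sum-normalization to the median
  channel total, and protein rollup by summation
  (`filter_psms()`, `normalize_channels()`, `rollup_proteins()`).
- **Differential abundance**: wild-type-centred log2 matrices, per-protein
  two-sided Student's t-tests (pooled variance; Welch optional) and
  Benjamini–Hochberg correction (`center_log2()`, `diff_test()`,
  `bh_adjust()`).
- **The allelic-series linear model**: for protein *p*,

  y_ps = Σₖ β_pk · x_k(s) + ε_ps,

  where x_k(s) is the cumulative indicator that sample *s*'s genotype
  contains the *k*-th sequential deletion (staircase rows 0000, 1000,
  1100, 1110, 1111). Each β_pk is the mean log2 fold change between
  adjacent genotypes — β₃ is "the average change from the triple to the
  quadruple knockout" (`build_design()`, `fit_allelic()`, with
  broom-style `tidy()` / `glance()` and `autoplot()` methods,
  `summarize_beta()`, `rank_top()`).
- **Compartment statistics**: ER annotation parsing (TM-segment counts
  encoded as `_1`, `_2`, ... name suffixes), a randomized-selection
  Kolmogorov–Smirnov null (group vs. 100 random same-size selections),
  one-sided Wilcoxon tests of β against zero with Bonferroni correction,
  and paired two-sided Wilcoxon tests between genotypes
  (`parse_annotations()`, `randomized_null_ks()`,
  `wilcoxon_beta_vs_zero()`, `paired_wilcoxon_genotypes()`).
- **Keima flux**: acidic (561 nm) / neutral (445 nm) excitation ratios
  from gated flow-cytometry event tables as ratios of channel means,
  normalized to bafilomycin-A1 (BAFA) controls (`keima_ratio()`,
  `normalize_to_bafa()`).
- **Synthetic data with ground truth**: an 18-plex-style allelic-series
  simulator (sparse per-step effects, receptor-deletion signatures,
  lognormal peptide shares, Gaussian log2 noise, configurable QC-failure
  fractions) so every stage is testable end to end (`sim_config()`,
  `generate_truth()`, `simulate_protein_matrix()`, `simulate_psm_table()`,
  `simulate_flow_events()`).

All user-facing functions take a data frame first and return tibbles, so
steps chain with the pipe.

## Worked example

```r
library(allelicER)
library(dplyr)

cfg    <- sim_config(n_proteins = 1000, n_er = 200, seed = 42)
design <- plex_design(cfg)
truth  <- generate_truth(cfg)

quant <- simulate_psm_table(simulate_protein_matrix(truth, cfg), cfg) |>
  filter_psms(min_snr = 200, min_purity = 0.5) |>
  normalize_channels() |>
  rollup_proteins()

fit <- quant |>
  center_log2(design, reference = "WT") |>
  fit_allelic(design)
fit
#> <allelic_fit> 980 proteins, series WT -> DKO -> TKO -> QKO -> PKO
#>   significant (adjusted p < 0.05) per step:
#>  WT->DKO DKO->TKO TKO->QKO QKO->PKO
#>       46       32       28       22

tidy(fit) |> filter(protein_id == "FAM134A") |> select(-flag)
#> # A tibble: 4 × 8
#>   protein_id step     estimate std.error statistic p.value p.adjusted significant
#>   <chr>      <ord>       <dbl>     <dbl>     <dbl>   <dbl>      <dbl> <lgl>
#> 1 FAM134A    WT->DKO   -2.66       0.207   -12.8   1.58e-7  0.0000772 TRUE
#> 2 FAM134A    DKO->TKO   0.106      0.207     0.513 6.19e-1  0.928     FALSE
#> 3 FAM134A    TKO->QKO   0.0713     0.207     0.344 7.38e-1  0.948     FALSE
#> 4 FAM134A    QKO->PKO  -0.172      0.207    -0.830 4.26e-1  0.855     FALSE
```

FAM134A is deleted at the first step of the series: its WT→DKO
coefficient is strongly negative (here −2.66, simulated true effect
−2.5) and significant, while the coefficients of all later deletions are
near zero and non-significant — the protein stays deleted, so its
abundance does not change again. The per-step significant counts reflect
the simulated ER remodelling signature plus sparse background regulation.

Flux, from simulated gated events:

```r
events <- bind_rows(
  simulate_flow_events(0.25, 1e5, bafa = TRUE, seed = 1),
  simulate_flow_events(1.0,  1e5, condition = "day12", seed = 2)
)
events |> keima_ratio() |> normalize_to_bafa()
#> # A tibble: 2 × 4
#>   condition raw_ratio n_events normalized_ratio
#>   <chr>         <dbl>    <int>            <dbl>
#> 1 BAFA          0.250   100000             1
#> 2 day12         1.00    100000             4.00
```

The BAFA control normalizes to exactly 1 by construction; the `day12`
condition carries four-fold higher ER-phagic flux than the
lysosome-inhibited baseline.

Plots: `autoplot(fit)` (per-step volcano panels), `plot_beta_ecdf()`
(compartment ECDFs against the quantified background),
`plot_rank_top(rank_top(fit))` (top accumulated / bottom depleted
waterfall), `autoplot()` on a `randomized_null_ks()` result, and
`plot_flux()`.

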