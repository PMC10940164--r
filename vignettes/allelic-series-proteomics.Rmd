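---
title: "Quantifying ER proteome remodelling across an ER-phagy receptor allelic series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying ER proteome remodelling across an ER-phagy receptor allelic series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allelicER)
library(dplyr)
```

## The scientific problem

ER-phagy receptors (FAM134A/B/C, TEX264, CCPG1, ...) link endoplasmic
reticulum membranes to the autophagy machinery and thereby control which
parts of the ER proteome are delivered to lysosomes. A powerful way to
dissect their combinatorial contributions is an *allelic series*: an ordered
set of genotypes built by sequential deletion — wild type (WT), a double
knockout (DKO), then triple (TKO), quadruple (QKO) and quintuple (PKO) —
profiled by multiplexed tandem-mass-tag (TMT) proteomics in one plex.
`allelicER` implements the full quantitative chain for such experiments:

1. **PSM-level quality control and quantification** (`filter_psms()`,
   `normalize_channels()`, `rollup_proteins()`),
2. **reference-centred differential abundance** (`center_log2()`,
   `diff_test()`, `bh_adjust()`),
3. **the sequential-knockout linear model** (`build_design()`,
   `fit_allelic()`, `summarize_beta()`, `rank_top()`),
4. **compartment-level distribution statistics**
   (`parse_annotations()`, `randomized_null_ks()`,
   `wilcoxon_beta_vs_zero()`, `paired_wilcoxon_genotypes()`),
5. **ratiometric Keima flux quantification** from flow cytometry
   (`keima_ratio()`, `normalize_to_bafa()`), and
6. **a synthetic-data generator with known ground truth**
   (`sim_config()`, `generate_truth()`, `simulate_protein_matrix()`,
   `simulate_psm_table()`, `simulate_flow_events()`), so every stage can be
   validated end to end without access to instrument data.

## The model

For protein $p$, let $y_{ps}$ be its reference-centred log2 intensity in
sample $s$. Each deletion step $k$ of the series gets a cumulative
indicator $x_k(s) \in \{0, 1\}$ that is 1 when sample $s$'s genotype
contains the $k$-th deletion, so genotype rows form a staircase
($\mathrm{WT} = 0000$, $\mathrm{DKO} = 1000$, ..., $\mathrm{PKO} = 1111$):

$$ y_{ps} = \sum_{k=1}^{4} \beta_{pk} \, x_k(s) + \varepsilon_{ps},
   \qquad \varepsilon_{ps} \sim N(0, \sigma_p^2). $$

Because the indicators are cumulative, $\beta_{pk}$ is the mean log2 fold
change between the adjacent genotypes of step $k$; for example
$\beta_{p3}$ is the average change from the triple to the quadruple
knockout. A receptor that is itself deleted at step $k$ shows a strongly
negative $\beta_{pk}$ and near-zero coefficients at every later step,
because it stays deleted for the rest of the series.

```{r staircase}
cfg <- sim_config(n_proteins = 400, n_er = 80, seed = 1)
design <- plex_design(cfg)
unique(build_design(design, cfg$genotypes)$X)
```

### Inference: why the fit keeps a nuisance intercept

Centring uses the *estimated* mean of the wild-type replicates, and the
centred wild-type sample mean is exactly zero. A no-intercept fit on such
values treats the reference mean as known: the first-step coefficient
$\hat\beta_1 = \bar y_{\mathrm{DKO}}$ gets a modelled variance of
$\sigma^2 / n_{\mathrm{DKO}}$, while its true sampling variance is
$\sigma^2 (1/n_{\mathrm{DKO}} + 1/n_{\mathrm{WT}})$ — two-fold larger at
equal replication — and the residual degrees of freedom are overstated by
one. Under a simulated global null this makes step-1 p-values visibly
anti-conservative (the test suite measures a step-1 type-I error roughly
double the nominal $\alpha = 0.05$ for the pinned fit, and nominal for
the default fit).

`fit_allelic()` therefore keeps an intercept *nuisance term* by default.
On centred data its estimate is numerically zero, so every coefficient is
unchanged, but the reference-mean uncertainty propagates into the standard
errors ($\mathrm{df} = n - 5$ for a five-genotype series) and the
coefficient p-values are calibrated (type-I error within Monte-Carlo error
of nominal in the test suite). `intercept = "none"` reproduces the
pinned-reference fit (`lm(y ~ X - 1)`, $\mathrm{df} = n - 4$) exactly for
users who want that convention; both modes are cross-checked against `lm()`
in the tests. Steps 2–4 are differences of mutant genotype means, in which
the reference mean cancels, so they are identical in both modes.

Degenerate inputs are flagged rather than dropped: zero-residual fits
(`"zero_residual"`, e.g. noise-free data — coefficients exact, p-values
degenerate), proteins missing a genotype entirely (`"rank_deficient"`),
and fits without residual degrees of freedom (`"no_inference"`).

## The quantification chain

PSMs are retained when their summed reporter signal-to-noise across the
plex is strictly greater than 200 and their precursor isolation purity is
strictly greater than 0.5 — both strict inequalities, applied before
normalization, since both are acquisition properties. Channel totals are
then sum-normalized to the median channel total (midpoint convention for
even plex sizes), and protein intensities are the sums of their
constituent PSM intensities, which weights peptides by abundance. Zero
intensities within retained PSMs are kept as zeros; nothing is imputed.

Two properties of this chain are worth stating precisely:

* **Conservation.** The simulator splits protein intensities across PSMs
  with lognormal shares that are identical across channels, so with no QC
  failures rollup reproduces the protein matrix exactly, and
  filter–normalize–rollup reproduces `normalize_channels()` applied to the
  protein matrix (normalization and summation commute). The test suite
  asserts both to a relative tolerance of 1e-9.
* **Compositionality.** Sum-normalization assumes the total proteome is
  constant across channels. Any genuine net drift — including the slight
  upward drift that mean-zero log2 effects produce on the linear scale
  (Jensen's inequality) and a strong accumulation signature concentrated
  in one compartment — is subtracted from every protein. In the synthetic
  study this attenuates the recovered ER-proteome mean step-1 coefficient
  by roughly 0.02–0.04 log2 units relative to the generating truth; the
  same caveat applies to real sum-normalized TMT data.

## The synthetic study

The generator's defaults describe the emulated experiment, chosen once:

| parameter | default | why |
|---|---|---|
| genotype series | WT, DKO, TKO, QKO, PKO | sequential receptor deletions |
| replicates | 3 per genotype | one 15-channel slice of an 18-plex design |
| proteins | 8,000, of which 359 ER | deep TMT proteome; ER annotation set size; keeps the ER share of total signal realistically small so sum-normalization behaves as it does on real data |
| receptor deletions | FAM134A+FAM134C at step 1, FAM134B at 2, TEX264 at 3, CCPG1 at 4, effect −2.5 log2 | deletion signature magnitude of the modelled study |
| ER signature | mean step-1 effect 0.21 log2 over the ER proteome, ER-membrane enriched 2:1 over lumen/associated; lumen-specific step-4 mean 0.2 | ER remodelling structure of the modelled study |
| noise | $\sigma = 0.25$ log2, Gaussian per cell | conventional TMT replicate variability; the study itself does not report one |
| background effects | 20 % sparsity, $N(0, 0.5)$ per protein and step | proteome-wide regulation unrelated to ER-phagy |
| peptides per protein | $1 + \mathrm{Pois}(2)$, lognormal shares | so rollup is exact and filtering consequential |
| QC failures | 5 % each for SNR and purity, failing PSMs perturbed ×U(0.1, 10) per channel | makes filtered and unfiltered pipelines measurably differ |

`sim_config_null()` zeroes every true effect (background sparsity, ER
signature and receptors) and is the configuration used for all
calibration claims.

What the generator does *not* emulate: co-isolation interference
mechanisms, missing values beyond QC filtering, multi-plex batch
structure (single plex by default), non-Gaussian heavy-tailed replicate
noise, and correlated regulation across proteins. Passing tests therefore
demonstrate the correctness and calibration of the *procedures*, not that
real TMT data meet their assumptions.

```{r pipeline}
truth <- generate_truth(cfg)
pq <- simulate_protein_matrix(truth, cfg)
psms <- simulate_psm_table(pq, cfg)

quant <- psms |>
  filter_psms(min_snr = 200, min_purity = 0.5) |>
  normalize_channels() |>
  rollup_proteins()

fit <- quant |>
  center_log2(design, reference = "WT") |>
  fit_allelic(design)
fit
tidy(fit) |> filter(protein_id == "FAM134A")
```

FAM134A is deleted at the first step: its WT→DKO coefficient is strongly
negative and significant, and its later coefficients are near zero — it
stays deleted, so its abundance does not change again.

## Distribution-level statistics

`randomized_null_ks()` compares a compartment's coefficient distribution
against randomized selections of the same number of proteins from the
quantified background (100 selections by default), each scored with a
two-sided two-sample Kolmogorov–Smirnov test. Three choices deserve
explanation:

* **Aggregation.** How 100 iteration-level p-values become one headline
  number is genuinely open; the object returns all of them, their median
  (used by `print()`), the fraction below $\alpha$, and a single pooled
  test of the group against all draws concatenated, so users can report
  whichever summary their figure needs.
* **Sampling.** Draws are uniform without replacement from the full
  background; group members are *not* excluded, so a draw can share
  members with the group. Shared members produce ties, for which the
  asymptotic p-value is used (the tie warning is suppressed internally).
* **Calibration.** The KS statistic is discrete, so rejection at exactly
  $\alpha = 0.05$ is somewhat conservative for small samples. The suite's
  calibration check uses groups of 150 from a background of 8,000 — sizes
  at which the nominal level is meaningful — and averages over 100
  independent groups because iterations that share one group are
  dependent.

`wilcoxon_beta_vs_zero()` tests a compartment's coefficients against zero
(one-sided greater by default, Bonferroni-multiplied by the number of
panel comparisons); `paired_wilcoxon_genotypes()` compares two genotypes
paired by protein (two-sided). Both drop zero differences (signed-rank
convention), use the exact distribution for $n \le 25$ without ties and
the normal approximation with continuity correction otherwise, and flag
the all-zero degenerate case with p = 1. Exactness for $n \le 12$ is
verified in the tests against brute-force enumeration of all $2^n$ sign
assignments.

## Keima flux

The acidic-to-neutral ratio is the mean of the 561-nm-excited intensities
divided by the mean of the 445-nm-excited intensities over a condition's
gated events — the ratio of channel means, *not* the mean of per-event
ratios (the two differ; the tests pin the implemented convention).
Arithmetic means are the literal reading; a geometric-mean option exists
because some cytometry workflows report geometric statistics. Ratios are
normalized to a matched bafilomycin-A1 (BAFA) control, so the control
itself is exactly 1 and common detector gains cancel.

```{r flux}
events <- bind_rows(
  simulate_flow_events(0.25, 2e4, bafa = TRUE, seed = 1),
  simulate_flow_events(1.0, 2e4, condition = "established", seed = 2)
)
events |> keima_ratio() |> normalize_to_bafa()
```

## Numerical choices and limitations

* Filtering thresholds are strict (`> 200`, `> 0.5`); a PSM at the
  boundary is removed. The median over an even number of channel totals is
  the midpoint of the two central values.
* Rank-ties in `rank_top()` break by accession lexicographic order, so
  output is deterministic.
* Zero-residual detection uses a relative tolerance of 1e-12 on the
  residual sum of squares; coefficients below 1e-10 in such fits count as
  exactly zero when assigning the degenerate p of 1.
* Benjamini–Hochberg adjustment is applied per coefficient (per deletion
  step) across proteins, with a pooled option; the per-comparison
  convention for `diff_test()` is within one mutant-vs-reference contrast.
* Proteins with no finite reference quantification are excluded from
  centring with a message and listed in the `"excluded"` attribute;
  proteins missing a genotype are flagged, never silently dropped.
* Test and calibration problem sizes (e.g. 1,000–8,000 proteins, 20 null
  seeds, 2,000 KS iterations, $10^5$ flow events) were chosen so the whole
  suite completes in well under a minute of simulation time per claim
  while leaving Monte-Carlo error comfortably inside each asserted band.
* The pipeline starts from identified, quantified PSMs and gated flow
  events: database search, FDR filtering, isotope-impurity correction,
  protein inference, compensation and gating are upstream of this
  package's scope, as are multi-plex bridging and moderated-variance
  (empirical-Bayes) testing.
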