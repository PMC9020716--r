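---
title: "Methods: proximity-interactor calling and FRAP recovery fitting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: proximity-interactor calling and FRAP recovery fitting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proxitome)
```

## The analysis problem

In a proximity-labeling experiment a promiscuous biotin ligase
(TurboID/BioID) is fused or targeted to a bait protein; proteins near
the bait in vivo are biotinylated, captured on streptavidin and
quantified by LC-MS/MS label-free quantification (LFQ). Experimental
samples (ligase at the bait) are compared against expression-matched
controls (ligase alone), typically three replicates per group.

Two features make the downstream statistics non-standard:

* **Left-censoring.** An LFQ intensity of 0 does not mean absence; it
  means the protein fell below what the run could quantify. True
  proximity interactors of a spatially restricted bait are often
  low-abundance proteins, so they tend to be quantified in experimental
  samples but *missing in most or all controls* —
  missing-not-at-random structure that ordinary imputation handles
  badly.
* **Abundant shared background.** Endogenously biotinylated proteins
  (most prominently the biotin-dependent carboxylases) are captured at
  high levels in both groups. They dominate the raw lists but carry no
  enrichment signal, so the sample-vs-control comparison is the filter
  that removes them.

## Filtering

`apply_filters()` removes, in a fixed reporting order: reverse
(decoy-database) identifications, potential contaminants, groups
identified only by a modified peptide, groups with fewer than
`min_group_values = 2` quantified values in the required group(s), and
groups with fewer than `min_razor = 2` razor + unique peptides. Each
record is counted under the first rule that removes it; the retained set
is the conjunction of all rules and therefore independent of the order.

The quantification-count rule is ambiguous in common usage ("fewer than
two values in one group"): *which* group? `proxitome` exposes this as
`group_value_mode`:

* `any_group` (default): keep a protein if *either* group has ≥ 2
  values. Chosen as default because interactors absent from all
  controls — exactly the expected signature of a true hit — would be
  deleted by any stricter reading.
* `experimental_group`: require the values in the experimental group.
* `both_groups`: the strict reading, useful for treatment-vs-treatment
  comparisons where both conditions should quantify the protein.

The bait is never special-cased: it passes or fails filters like any
record and, being strongly enriched, normally tops its own significant
list.

## Imputation

Both schemes operate on the log2 matrix produced by `log_transform()`
(zeros become missing cells) and never alter an observed value. Each
cell's provenance (observed vs imputed) is carried in masks and
propagated to the per-protein `n_imputed_exp` / `n_imputed_ctrl` columns
of the results.

**LOD (lowest of detection), `impute_lod()`** — deterministic: each
missing cell takes the minimum observed log2 value of its own sample
column. One sample column corresponds to one MS run, so the column
minimum is that run's empirical detection floor. The minimum is taken
over the *retained* (post-filter) proteins, since imputation runs after
filtering.

**ND (down-shifted normal), `impute_nd()`** — stochastic: with `m` and
`s` the mean and SD of **all** observed log2 values in the matrix,
missing cells are drawn i.i.d. from `N(m − shift·s, (width·s)²)`,
defaults `shift = 1.8`, `width = 0.3`. The whole-matrix statistics are
the default (a per-column variant is a common alternative elsewhere but
is not what this pipeline models); draws come from a dedicated seeded
stream (`nd_params(seed = ...)`) that leaves the caller's RNG state
untouched, so a run is reproducible from its config alone.

**Why two schemes, and when they disagree.** ND assumes censored values
scatter just below the global detection region. For proteins far above
the floor this is fine. But a genuine interactor observed *at* the
detection floor in experimental samples and censored in controls gets
its control values imputed at `m − 1.8s` — often *above* the floor — so
its fold change shrinks and can even invert sign, while LOD imputes the
controls at the floor and preserves the enrichment direction. The
package's property tests construct exactly this geometry and verify that
the mean log2 fold change of such planted interactors is strictly larger
under LOD than under ND. `run_enrichment()` can produce both routes in
one run plus a per-protein comparison table with an `inverted` flag.

## Enrichment statistics

For each protein, `compute_enrichment()` reports:

* `log2_fc` — difference of group means of log2 values (not the log of
  the ratio of linear means; consistent with imputation acting in log
  space).
* `p_value` — two-sided unpaired t-test. The default is the classical
  pooled-variance (Student) test, the conventional choice for small
  balanced designs; `var_equal = FALSE` switches to Welch. The
  statistic is computed in closed form (vectorized); the test suite
  checks it against `stats::t.test()` to 1e-10.
* `significant` — `log2_fc > 1` **and** `p < 0.05`, both strict. No
  multiple-testing correction enters the call (the threshold is on raw
  p); a Benjamini–Hochberg column `p_adj_bh` is emitted for information
  only.

Degenerate case: if all values of a protein are identical the t statistic
is 0/0; the package defines p = 1 (no evidence of difference). Zero
pooled variance with distinct means gives p = 0.

`significant_set()` orders hits by descending fold change, ties broken
by ascending p then by id, so output is fully deterministic.
`volcano_table()` and `ma_table()` are pure projections onto the
(−log10 p, log2 FC) and (mean log2 sample intensity, log2 FC) axes; the
MA view is the one that visually separates low-abundance interactors
from the abundant carboxylase band.

## FRAP quantification

`integrated_intensity()` implements the concentric-region measurement:
(mean intensity in the inner box − mean intensity in the ring between
inner and outer boxes) × inner area, i.e. local-background-corrected
integrated signal. `normalize_trace()` divides by the mean of the
pre-bleach frames (all of them by default; `n_prebleach` restricts to
the frames immediately before the bleach), so 1.0 is the unbleached
steady state.

`fit_recovery()` fits `Y = A(1 − e^{−kX}) + B` by
Levenberg–Marquardt nonlinear least squares (`minpack.lm`) to the
post-bleach points only, with:

* `X = 0` at the **first post-bleach frame** — `B` is defined as the
  background left right after the bleach, so the time origin must sit
  there; fits are then invariant to uniform time translation.
* Data-derived starting values: `B₀` = first post-bleach value, `A₀` =
  post-bleach span, `k₀` = ln 2 / (time to half of the apparent
  plateau); up to 5 jittered restarts if the first attempt fails.
* A reflected start (`−A₀`, `−k₀`): the positive-`k` basin contains a
  near-linear local optimum (`k → 0⁺`, large `A`) that can shadow a
  better negative-`k` optimum when a trace grows instead of recovering.
  The lower-deviance optimum wins; a final `k ≤ 0` raises "no recovery
  detected" rather than reporting a half-time.
* `t½ = ln 2 / k` (the identity `t½·k = ln 2` holds exactly for every
  returned fit), and `R² = 1 − SS_res/SS_tot` over the fitted points —
  the usual goodness-of-fit reading of a "correlation coefficient" for
  a nonlinear model.

At least 4 post-bleach points are required (3 parameters); pre-bleach
points serve normalization only and never enter the fit or `R²`.

## Synthetic data: what it emulates, and what it does not

`generate_proteome()` draws each protein's base abundance on the log2
scale (log-normal intensities), adds i.i.d. replicate noise, applies the
interactor enrichment effect to experimental samples only, and censors
every value below a hard detection threshold to "not quantified". The
defaults define the simulated experiment:

| parameter | default | rationale |
|---|---|---|
| replicates per group | 3 | the standard 3-vs-3 pulldown design |
| interactors | 12 at log2 = 20.5 ± 0.5 | low-abundance class just under the detection limit, so controls are censored (MNAR) |
| interactor effect | +4 log2 units (bait +6) | strong proximity enrichment; baits top their lists |
| carboxylase-like | 4 at log2 = 31 ± 1 | the handful of very abundant endogenously biotinylated carboxylases, present in both groups |
| background | 300 at log2 = 25 ± 2 | ordinary shared proteome |
| decoys | 30, cycling reverse / contaminant / site-only / razor = 1 | every filter rule is exercised |
| detection limit | log2 = 21 | censoring threshold; hard cut, so censoring is exactly invertible for test oracles |
| replicate noise | 0.4 log2 units SD | typical LFQ replicate scatter |

The carboxylase abundance offset is a synthetic choice for clear class
separation, not an estimate from any measured dataset. Hard-threshold
censoring is deliberately simple: it reproduces "absent in one or all
control samples" and lets tests verify censoring cell-by-cell against
the generator's pre-censoring draws. Real LFQ data differ in ways the
generator does not model: probabilistic (intensity-dependent) dropout
rather than a sharp threshold, between-run normalization artifacts,
correlated noise across proteins, ragged peptide evidence, and shared
peptides between groups. Passing the end-to-end tests therefore
demonstrates that the pipeline recovers planted structure under the
stated statistical assumptions — not that any particular biological
dataset will behave as cleanly.

`generate_frap_trace()` inverts the recovery model (pre-bleach points at
exactly 1.0, seeded additive noise after the bleach);
`generate_frap_stack()` renders a trace as a Gaussian spot of matching
integrated amplitude on a flat background, with a region pair sized so
`extract_trace()` recovers the input series.

## Problem sizes and tolerances in the validation suite

The test suite runs entirely on generated data, sized for seconds-scale
runs: 347-protein proteomes (20 seeds for the end-to-end
sensitivity/specificity checks: sensitivity ≥ 0.8 on planted
interactors, ≤ 10% of background classes called), ~10⁴ imputed cells for
the ND moment and Kolmogorov–Smirnov checks (3-standard-error bands),
100 seeded traces for FRAP parameter recovery (median |relative error|
of A and t½ ≤ 5% at noise SD 0.05, 1 s sampling over 60 s — a window
long enough to pin the plateau of a 5 s half-time recovery), and a
16-trace ensemble at mobile fraction 0.9, t½ = 5 s for the headline
FRAP check (ensemble means within 5%). The post-bleach floor for that
ensemble is set to B = 0.1, the complement of the 0.9 mobile fraction,
so the noiseless plateau recovers to A + B ≈ 1 (full recovery with
essentially no immobile population). Exactness tolerances: noiseless
fit identity to 1e-6; t-test p-values against an independent
implementation to 1e-10.

## Known limitations

* The pipeline consumes MaxQuant-style `proteinGroups` tables; it does
  not parse spectra, `evidence.txt`, or perform LFQ normalization —
  those are upstream steps.
* Exactly two groups (experimental vs control); multi-condition designs
  are out of scope.
* The FRAP model is the single-exponential reaction-dominant limit;
  diffusion-coupled recovery and acquisition photobleaching correction
  are not modeled.
* No curation of significant hits into "interactor" vs "contaminant" —
  that judgment is biological, not statistical.
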