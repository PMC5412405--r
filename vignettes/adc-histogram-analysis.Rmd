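---
title: "Whole-lesion ADC histogram analysis: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-lesion ADC histogram analysis: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adchist)
```

## The analysis this package implements

Diffusion-weighted MRI estimates, per voxel, the apparent diffusion
coefficient (ADC) of water — a quantity that falls as tissue cellularity
rises. In oncologic imaging the conventional readout is a single
two-dimensional region of interest on one slice; whole-lesion histogram
analysis instead pools **every** voxel of the tumor across all slices and
summarizes the resulting intensity distribution. The shape of that
distribution (skewness, kurtosis, entropy), not just its location, carries
information about tissue heterogeneity, and in thyroid carcinoma cohorts it
has been used to separate nodal-negative from nodal-positive disease and to
track proliferation markers.

The pipeline has four stages, each usable on its own:

1. **Image IO** (`read_adc_map()`, `read_mask()`, `read_cohort_table()`):
   NIfTI volumes for maps and masks, CSV for the clinical table. The
   canonical ADC unit throughout is 1e-5 mm²/s; files stored in the common
   1e-3 convention are rescaled on read (`units_hint = "e-3"`). Published
   correlation tables occasionally print a 1e-3 header next to values that
   are plainly on the 1e-5 scale; we treat that as a typesetting
   inconsistency and never propagate it.
2. **Feature extraction** (`extract_voi_values()`, `compute_features()`):
   the first-order feature vector per lesion.
3. **Cohort statistics** (`correlate_markers()`, `compare_groups()`):
   Spearman correlations against immunohistopathology and Levene-gated
   two-group comparisons.
4. **Synthetic cohorts** (`synthetic_config()`, `simulate_cohort()`): seeded
   generation of maps, masks, optional DWI stacks and marker tables with the
   statistical structure the analysis assumes, so the full pipeline is
   testable without patient data.

## Feature definitions and conventions

`compute_features()` returns: mean, minimum, maximum, median, mode, the
10th/25th/75th/90th percentiles (all 1e-5 mm²/s), skewness, non-excess
kurtosis, Shannon entropy (bits), VOI volume (cm³ = voxel count × voxel
volume / 1000), and the binning metadata.

Several of these have more than one common convention; the choices here are:

* **Percentiles.** Order statistics positioned at `(i − 0.5)/n` with linear
  interpolation and clamping at the extremes — the convention of the
  numerical environment in which these analyses have historically been run.
  The widely used "type 7" convention is available via
  `percentiles = "type7"`; at cohort sizes of 10–20 voxels the two differ
  noticeably, at lesion sizes (10³–10⁵ voxels) they are practically
  indistinguishable.
* **Skewness and kurtosis.** Biased (population) central-moment estimators,
  `m₃/m₂^{3/2}` and `m₄/m₂²`, kurtosis **non-excess** (3 for a normal
  distribution). Published cohort values clustering around 3 identify this
  convention.
* **Entropy and mode.** Neither is well-defined without a binning rule, and
  published reports rarely state one. We use `bin_count` (default 64)
  equal-width bins spanning `[min, max]` of the sample; entropy is
  `−Σ pᵢ log₂ pᵢ` with empty bins contributing zero, the mode is the center
  of the most populated bin with ties resolving to the lowest center. The
  bin count is recorded in every output row. Entropy is therefore bounded by
  `log₂(bin_count)` (6 bits at the default), and values around 3–4 bits for
  real lesions are typical.
* **Degenerate samples.** A constant sample has zero variance: skewness and
  kurtosis are reported as `NaN` with an explicit warning (never silently),
  entropy is 0 and the mode is the constant itself.

The feature engine is checked against an independent brute-force oracle
(direct formula evaluation with explicit loops) to 1e-10 relative error, and
property tests assert the invariant chain `min ≤ p10 ≤ p25 ≤ median ≤ p75 ≤
p90 ≤ max`, `entropy ∈ [0, log₂ B]` and the moment inequality
`kurtosis ≥ skewness² + 1` on 1000 random samples.

## ADC fitting

`adc_fit()` and `adc_fit_map()` fit the mono-exponential decay
`S(b) = S₀ · exp(−b · ADC)` by ordinary least squares of `log S` on `b`,
which is exact on noiseless input and is the standard scanner-side method.
The unit bridge is `S(b) = S₀ · exp(−b · ADC · 1e-5)` with `b` in s/mm² and
ADC in 1e-5 mm²/s; the default b-values are 0, 400 and 800 s/mm².
Non-positive signals (possible under noise after subtraction, or from
masking) are excluded per voxel; a voxel with fewer than two usable signals
at distinct b-values gets ADC 0 and is counted in an `n_flagged` attribute
rather than failing the whole map.

## Statistical workflow

* **Spearman correlation** (`spearman_cor()`): midranks for ties, `rho` as
  the Pearson correlation of ranks, and the two-sided p-value from the
  t-approximation `t = rho·√((n−2)/(1−rho²))` with `n − 2` degrees of
  freedom, which is what mainstream statistics software reports at n ≈ 15.
  `rho = ±1` reports `p = 0`. An exact permutation p-value is available for
  `n ≤ 10` (`exact = TRUE`).
* **Levene gate** (`levene_test()`, `compare_groups()`): classic one-way
  ANOVA on absolute deviations from the group **mean** (the default of the
  statistics package conventionally used for such cohorts; median centering
  is available). The gate follows the standard rule: Levene `p > gate_alpha`
  → pooled-variance t-test, otherwise Mann–Whitney U. Published reports of
  this workflow are not always internally consistent about which side of the
  gate a feature fell on; `test_override` lets the caller force a specific
  test per feature to replicate a published assignment exactly, and the
  output records both the Levene p-value and whether the gate was overridden.
* **Mann–Whitney U** (`mann_whitney_u()`): exact null distribution when
  `n₁ + n₂ ≤ 20` without ties, else the normal approximation with tie and
  continuity corrections; `U` is reported for the first group. The exact
  branch is validated against full enumeration of all group assignments.
* **Significance** is flagged at `p ≤ 0.05` two-sided with **no**
  multiple-testing correction, matching how such exploratory cohorts are
  reported; `p_adjust = "holm"` is available but off by default.
* Group definitions: nodal status is N0 (`n_stage = 0`) versus N1/2
  (`n_stage ≥ 1`); infiltration is restricted (sites within thyroid
  gland/trachea) versus advanced (esophagus or internal jugular vein
  involved).

## The synthetic cohort generator

No public voxel-level dataset accompanies the cohort this package is
modelled on, so the generator is a first-class, tested component rather than
a fixture. It emulates the *statistical* structure the analysis consumes:

* **Voxel distributions.** In-mask ADC values are generated by the Fleishman
  power method: a cubic transform `a + bZ + cZ² + dZ³` of a standard normal,
  with coefficients solved (`solve_fleishman()`) so the transform has
  exactly the target skewness and kurtosis. The Fleishman family was chosen
  because the published group structure *is* a pair of (skewness, kurtosis)
  levels — the generator hits the two reported shape moments directly
  without asserting anything else about the unobservable distribution family.
  The solver is verified analytically against the closed-form moment
  equations, not by sampling. Targets must satisfy `kurtosis ≥ skewness² + 1`
  (a moment-space law) and lie inside the Fleishman-attainable region
  (approximately `kurtosis ≥ 1.774 + 1.641·skewness²`); both violations
  raise typed errors.
* **Group conditions.** Defaults are the published group-level moments for a
  15-patient cohort split 5 nodal-negative / 10 nodal-positive: lesion-mean
  ADC 125.25 ± 34.1 vs 111.41 ± 25.0 (1e-5 mm²/s), skewness −0.12 ± 0.64 vs
  0.41 ± 0.21, kurtosis 3.23 ± 0.29 vs 3.81 ± 0.57. Per-patient targets are
  drawn around the group means with the group SDs; a drawn kurtosis below
  the Fleishman boundary for its drawn skewness is clamped to the boundary
  plus 0.2 (without the clamp, roughly the most extreme skewness draws would
  request unattainable shape pairs).
* **Within-lesion spread.** The within-lesion voxel SD is not reported at
  group level; the default of 35 (1e-5 mm²/s) was fixed once so that (a) the
  percentile spread of a generated lesion is comparable to published
  single-lesion examples and (b) clipping at zero (ADC is non-negative)
  affects well under 0.1% of voxels, keeping the realized shape moments at
  their targets. The clipped-voxel count is attached to every generated map.
* **Geometry.** The lesion is a discretized ellipsoid (default semi-axes
  8 × 7 × 5 voxels on a 48 × 48 × 24 grid at 1 × 1 × 4 mm), about 1,200
  voxels ≈ 4.7 cm³ spanning 9 slices — a plausible size for these tumors and
  comfortably multi-slice, which the whole-lesion measure requires.
  Background voxels are fluid-like (300 ± 5), far from lesion statistics, so
  mask misalignment corrupts features conspicuously rather than subtly.
* **Marker dependence.** Only rank correlations between imaging summaries
  and markers are published, so dependence is realized by a Gaussian copula
  on ranks: the observed lesion summaries' midrank normal scores act as
  latent coordinates, marker latents are drawn from the conditional
  multivariate normal implied by the configured Spearman matrix (converted
  to the latent Pearson scale via `r = 2·sin(π·ρ/6)`), and marker values
  come from fixed marginal quantile functions spanning plausible clinical
  ranges (Ki-67 and p53 as scaled Betas in [0, 100]%, cell count and nuclear
  areas as log-normals). The default cross block holds the published
  feature–marker point estimates. The within-block entries (summary–summary
  and marker–marker correlations) are not identifiable from published
  summaries; they were chosen once, by minimal adjustment from plausible
  values, subject to the joint latent matrix and the conditional covariance
  being positive definite with margin ≥ 0.08 — a feasibility constraint, not
  a tuning knob. A user-supplied matrix that is asymmetric, has a non-unit
  diagonal, or is not PSD on the latent scale raises a typed error.
* **DWI simulation.** `generate_dwi()` applies the mono-exponential decay
  plus Rician noise (`√((S + σε₁)² + (σε₂)²)`) — the magnitude-MRI
  convention; `σ = 0` gives the exact decay for deterministic round-trip
  tests. At σ = 10 with S₀ = 1000 the refit ADC is biased by well under 2
  units at ADC = 100 (the Rician floor matters only at much lower SNR).

### What the generator does and does not emulate

It reproduces: the group-level moment structure, the rank-dependence between
lesion summaries and markers, the staging/demographic schema, and the
map/mask/DWI file layout. It does **not** attempt anatomically realistic
thyroid geometry, spatial texture or autocorrelation within the lesion,
partial-volume effects at the lesion rim, or scanner artifacts. Passing
tests therefore demonstrate that the *pipeline* is correct and that the
statistical machinery behaves as designed at the stated effect sizes — not
that the features would behave identically on clinical data with spatially
structured heterogeneity.

### Power under the default conditions

With the default group moments, the separation in skewness (−0.12 ± 0.64 vs
0.41 ± 0.21) is detectable by the Levene-gated comparison with high
probability at moderate cohort sizes. `simulate_group_power()` measures
this: at 30 vs 60 patients and 1,000 voxels per lesion, the detection rate
over 200 seeded replicates is about 0.95–0.99, safely above the 0.80 the
test suite asserts. The per-lesion estimator noise (SE of sample skewness
≈ √(6/V) ≈ 0.08 at V = 1000) is small against the between-patient SDs, so
the result is insensitive to the exact lesion size.

## Numerical choices and edge cases

* Fleishman solving: `pracma::fsolve` (Gauss–Newton) over a small ladder of
  starting points; a solution is accepted only if the analytic moment
  residual is below `tol` (1e-8). The normal case (0, 3) short-circuits to
  the exact identity transform.
* Grids must match between map and mask exactly in shape and to 1e-3 mm in
  spacing; mismatches are errors, never resampled.
* The pipeline excludes a patient whose map/mask fails any validation,
  records the reason, and aborts if more than half the cohort is excluded.
* All randomness flows through explicit seeds (`withr::with_seed`);
  identical config + seed gives byte-identical output bundles, asserted in
  the tests, and the seed is recorded in the run manifest.
* Problem sizes in the test suite (10⁵-voxel moment recovery, n = 2000
  copula recovery, 200-replicate power runs, 10⁶-draw moment grids) were
  chosen so each stochastic tolerance sits at ≥ 3 Monte-Carlo standard
  errors from its target.

## Known limitations

* The generator reproduces group-level structure only; it cannot (and does
  not try to) recreate any specific patient cohort, so per-patient published
  values serve only as plausibility ranges.
* Entropy and mode depend on the binning rule; cross-study comparison of
  these two features requires the same `bin_count` convention.
* DICOM series ingestion is deliberately out of scope; NIfTI is the exchange
  format. Registration, resampling and bias-field correction are assumed
  done upstream.
* At n = 15 the Spearman t-approximation and the Levene gate both have
  limited power; the package reports exact alternatives where feasible but
  the scientific limitation is inherent to the cohort size.
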