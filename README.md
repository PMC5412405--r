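# adchist

Whole-lesion ADC histogram analysis for small oncologic imaging cohorts.

## The problem

In diffusion-weighted MRI, the apparent diffusion coefficient (ADC) of water
falls as tissue cellularity rises, which makes ADC maps a non-invasive probe
of tumor biology. The conventional readout — one 2D region of interest on a
single slice — ignores intratumoral heterogeneity. Whole-lesion histogram
analysis instead pools every voxel of the tumor across all slices and
summarizes the distribution of ADC values: location (mean, median, mode,
percentiles), spread, and shape (skewness, kurtosis, entropy). In thyroid
carcinoma, the shape features of the whole-lesion ADC histogram separate
nodal-negative from nodal-positive disease and track proliferation markers
(Ki-67, p53) and cellularity.

`adchist` is for imaging researchers who want that analysis as a tested,
scriptable pipeline rather than a one-off spreadsheet: NIfTI maps and masks
in, per-lesion feature tables, Spearman feature–marker correlation tables and
Levene-gated two-group comparisons out.

## What it computes

For each lesion with voxel values `x₁ … x_V` (canonical unit 1e-5 mm²/s):

- location: mean, min, max, median, mode, P10/P25/P75/P90 (percentiles by
  the `(i − 0.5)/n` linear-interpolation convention; "type 7" optional);
- shape: skewness `m₃/m₂^{3/2}` and non-excess kurtosis `m₄/m₂²` from biased
  central moments; Shannon entropy `−Σ pᵢ log₂ pᵢ` (bits) over 64 equal-width
  bins spanning `[min, max]`;
- volume: voxel count × voxel volume, in cm³;
- ADC itself, when raw DWI stacks are the input: per-voxel OLS of `log S`
  on `b` for the mono-exponential decay `S(b) = S₀ e^{−b·ADC}`.

Cohort statistics: Spearman rank correlations (midranks, t-approximation
p-values) between features and immunohistopathology markers, and two-group
comparisons (nodal status N0 vs N1/2, or restricted vs advanced infiltration)
gated per feature by Levene's test — pooled-variance t-test under
homoscedasticity, Mann–Whitney U otherwise, two-sided, significance at
p ≤ 0.05 with no multiplicity correction (a Holm option exists).

A seeded synthetic-cohort generator (Fleishman cubic transforms for the voxel
distributions, a Gaussian copula for feature–marker rank dependence, Rician
noise for DWI) makes the whole pipeline testable without patient data; see
the methods vignette (`vignettes/adc-histogram-analysis.Rmd`) for its design
and limits.

## Worked example

```r
library(adchist)

# a 15-patient synthetic cohort with the default group structure
cfg <- synthetic_config(seed = 42)
sim <- simulate_cohort(cfg)
sim
#> <synthetic_cohort> 15 patients (seed 42): N0 n=5, N1/2 n=10

dplyr::select(sim$features, patient_id, adc_mean, skewness, kurtosis,
              entropy, volume_cm3)
#> # A tibble: 15 × 6
#>   patient_id adc_mean skewness kurtosis entropy volume_cm3
#>   <chr>         <dbl>    <dbl>    <dbl>   <dbl>      <dbl>
#> 1 P001           138.   0.793      3.17    5.42       4.74
#> 2 P002           145.   0.0582     3.43    5.12       4.74
#> 3 P003           122.   0.295      3.72    5.07       4.74
#> # … 12 more rows
```

Each row is one lesion: `adc_mean` 138 means the average water diffusivity
in that tumor is 138 × 1e-5 mm²/s; positive `skewness` means a tail of
high-ADC voxels; `entropy` 5.4 bits (of at most 6 at 64 bins) means the
voxel values spread across most of the histogram; all lesions here share the
default 4.74 cm³ ellipsoid geometry.

```r
res <- run_pipeline(run_config(mode = "synthetic", synthetic = cfg, seed = 42))
dplyr::select(tidy(res$table4), feature, mean1, sd1, mean2, sd2,
              levene_p, test_used, p_value) |>
  dplyr::filter(feature %in% c("skewness", "kurtosis"))
#> # A tibble: 2 × 8
#>   feature  mean1   sd1 mean2   sd2 levene_p test_used      p_value
#>   <chr>    <dbl> <dbl> <dbl> <dbl>    <dbl> <chr>            <dbl>
#> 1 kurtosis 3.48  0.356 3.93  0.568   0.258  pooled_t         0.128
#> 2 skewness 0.172 0.660 0.509 0.221   0.0447 mann_whitney_u   0.310
```

Group 1 is N0, group 2 is N1/2. For skewness, Levene's p = 0.045 ≤ 0.05
flags unequal variances, so the gate picked Mann–Whitney U; for kurtosis the
variances pass (p = 0.26) and a pooled t-test is used. At n = 15 a single
synthetic cohort often misses significance — the power analysis
(`simulate_group_power()`) shows the skewness difference is detected in
~95–99% of replicates at 30 vs 60 patients.

Real data works the same way, reading from disk:

```r
cfg <- run_config(mode = "real",
                  maps_dir = "maps/", masks_dir = "masks/",
                  cohort_csv = "cohort.csv", out_dir = "results/")
res <- run_pipeline(cfg)   # writes table1–table4 CSVs + manifest + log
```

The bundled 15-case clinical table reproduces the published demographics:

```r
co <- read_cohort_table(system.file("extdata", "cohort_table5.csv",
                                    package = "adchist"))
summarize_demographics(co)
#> # A tibble: 1 × 7
#>       n mean_age sd_age n_female n_male n_nodal_negative n_nodal_positive
#>   <int>    <dbl>  <dbl>    <int>  <int>            <int>            <int>
#> 1    15     67.1   12.9       14      1                5               10
```

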