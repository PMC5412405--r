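Package: adchist
Title: Whole-Lesion ADC Histogram Analysis for Tumor Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: First-order histogram analysis of apparent diffusion coefficient
    (ADC) maps over whole-lesion volumes of interest, with the downstream
    cohort statistics used in small-sample oncologic imaging studies:
    per-lesion histogram features (mean, percentiles, mode, skewness,
    kurtosis, entropy, volume), mono-exponential ADC fitting from multi-b
    diffusion-weighted stacks, Spearman correlation of features against
    immunohistopathology markers, and Levene-gated two-group comparisons
    (pooled t versus Mann-Whitney U). Includes a seeded synthetic-cohort
    generator (Fleishman voxel distributions, Gaussian-copula marker
    dependence, Rician DWI noise) so the full pipeline is testable without
    patient data.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    car,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
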