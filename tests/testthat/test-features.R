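test_that("VOI extraction returns exactly the in-mask values", {
  vals <- array(seq_len(18), dim = c(3, 3, 2))
  map <- adc_map(vals, spacing = c(1, 1, 4))
  marr <- array(0L, dim = c(3, 3, 2))
  marr[c(1, 5, 10, 18)] <- 1L
  mask <- lesion_mask(marr, spacing = c(1, 1, 4))
  v <- extract_voi_values(map, mask)
  expect_setequal(v$values, c(1, 5, 10, 18))
  expect_equal(v$voxel_count, 4)
  expect_equal(v$voxel_volume, 4)

  full <- lesion_mask(array(1L, dim = c(3, 3, 2)), spacing = c(1, 1, 4))
  expect_length(extract_voi_values(map, full)$values, 18)
  zero <- lesion_mask(array(0L, dim = c(3, 3, 2)), spacing = c(1, 1, 4))
  expect_error(extract_voi_values(map, zero), class = "adchist_empty_mask")
  small <- lesion_mask(array(1L, dim = c(3, 3, 1)), spacing = c(1, 1, 4))
  expect_error(extract_voi_values(map, small), class = "adchist_grid_mismatch")
})

test_that("feature values match hand-computed references", {
  f <- compute_features(c(1, 2, 2, 3, 10))
  expect_equal(f$adc_mean, 3.6)
  expect_equal(f$adc_median, 2)
  expect_equal(f$skewness, 1.361, tolerance = 1e-3)
  expect_equal(f$kurtosis, 3.068, tolerance = 1e-3)
  # MATLAB-convention percentile on {1,2,3,4}
  expect_equal(quantile_matlab(c(1, 2, 3, 4), 0.25), 1.5)
  expect_equal(compute_features(c(1, 2, 3, 4))$p25, 1.5)
  # type-7 convention differs
  expect_equal(compute_features(c(1, 2, 3, 4), percentiles = "type7")$p25, 1.75)
})

test_that("constant samples have defined degenerate behavior", {
  expect_warning(f <- compute_features(rep(100, 50)), "undefined")
  expect_equal(f$adc_mean, 100)
  expect_equal(f$adc_median, 100)
  expect_equal(f$adc_mode, 100)
  expect_equal(f$adc_min, 100)
  expect_equal(f$adc_max, 100)
  expect_equal(f$entropy, 0)
  expect_true(is.nan(f$skewness))
  expect_true(is.nan(f$kurtosis))
  expect_error(compute_features(numeric(0)), class = "adchist_empty_sample")
  expect_error(compute_features(1:5, bin_count = 1),
               class = "adchist_bad_argument")
})

test_that("the feature engine agrees with the brute-force oracle", {
  withr::with_seed(14, {
    for (i in 1:50) {
      x <- random_voxel_sample()
      bins <- sample(c(16, 64, 128), 1)
      got <- suppressWarnings(compute_features(x, bin_count = bins))
      want <- suppressWarnings(oracle_features(x, bin_count = bins))
      for (nm in names(want)) {
        if (is.nan(want[[nm]])) {
          expect_true(is.nan(got[[nm]]))
        } else {
          expect_equal(got[[nm]], want[[nm]], tolerance = 1e-10,
                       label = sprintf("%s (iter %d)", nm, i))
        }
      }
    }
  })
})

test_that("feature invariants hold on random samples", {
  withr::with_seed(15, {
    for (i in 1:1000) {
      x <- random_voxel_sample()
      f <- suppressWarnings(compute_features(x, bin_count = 64))
      expect_true(f$adc_min <= f$p10 + 1e-12)
      expect_true(f$p10 <= f$p25 + 1e-12)
      expect_true(f$p25 <= f$adc_median + 1e-12)
      expect_true(f$adc_median <= f$p75 + 1e-12)
      expect_true(f$p75 <= f$p90 + 1e-12)
      expect_true(f$p90 <= f$adc_max + 1e-12)
      expect_true(f$adc_mode >= f$adc_min - 1e-12 &&
                    f$adc_mode <= f$adc_max + 1e-12)
      expect_true(f$entropy >= 0 && f$entropy <= log2(64) + 1e-12)
      if (!is.nan(f$kurtosis)) {
        expect_gte(f$kurtosis, f$skewness^2 + 1 - 1e-12)
      }
    }
  })
})

test_that("features are permutation-invariant and affine-equivariant", {
  withr::with_seed(16, {
    x <- rlnorm(500, log(100), 0.4)
    f1 <- compute_features(x)
    f2 <- compute_features(sample(x))
    expect_equal(f1, f2)
    c0 <- 2.5; k0 <- 30
    f3 <- compute_features(c0 * x + k0)
    loc <- c("adc_mean", "adc_min", "adc_max", "adc_median", "adc_mode",
             "p10", "p25", "p75", "p90")
    for (nm in loc) expect_equal(f3[[nm]], c0 * f1[[nm]] + k0, tolerance = 1e-9)
    expect_equal(f3$skewness, f1$skewness, tolerance = 1e-9)
    expect_equal(f3$kurtosis, f1$kurtosis, tolerance = 1e-9)
    expect_equal(f3$entropy, f1$entropy, tolerance = 1e-9)
  })
})

test_that("large normal samples have normal shape moments", {
  withr::with_seed(17, {
    x <- rnorm(1e6)
    f <- compute_features(x)
    expect_lt(abs(f$skewness), 0.01)
    expect_lt(abs(f$kurtosis - 3), 0.02)
  })
})

test_that("ADC fitting inverts the mono-exponential decay", {
  expect_equal(as.numeric(adc_fit(c(1000, 670.32, 449.33), c(0, 400, 800))),
               100, tolerance = 1e-5)
  expect_equal(as.numeric(adc_fit(c(500, 500, 500), c(0, 400, 800))), 0)
  expect_error(adc_fit(c(-1, 0, -3), c(0, 400, 800)),
               class = "adchist_bad_signal")
  expect_error(adc_fit(c(100, -1, -1), c(0, 400, 800)),
               class = "adchist_bad_signal")
  # non-positive signals excluded, fit uses the rest
  got <- adc_fit(c(1000, -5, 449.33), c(0, 400, 800))
  expect_equal(as.numeric(got), 100, tolerance = 1e-4)
  expect_equal(attr(got, "n_used"), 2)
})

test_that("cohort summaries report median, range, min, max", {
  s <- summarize_cohort(c(73, 120, 163))
  expect_equal(s$range, 90)
  expect_equal(s$min, 73)
  expect_equal(s$max, 163)
  expect_equal(summarize_cohort(c(2.89, 3.6, 4.79))$range, 1.90)
  single <- summarize_cohort(5)
  expect_equal(unlist(single[c("median", "range", "min", "max")]),
               c(median = 5, range = 0, min = 5, max = 5))
  expect_error(summarize_cohort(numeric(0)), class = "adchist_empty_sample")
})

test_that("volume in cm^3 follows voxel count and spacing", {
  vals <- array(100, dim = c(10, 10, 4))
  map <- adc_map(vals, spacing = c(1, 1, 4))
  mask <- lesion_mask(array(1L, dim = c(10, 10, 4)), spacing = c(1, 1, 4))
  f <- suppressWarnings(compute_features(extract_voi_values(map, mask)))
  expect_equal(f$volume_cm3, 400 * 4 / 1000)
})
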