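test_that("Spearman correlation handles monotone, tied and degenerate input", {
  expect_equal(spearman_cor(c(1, 2, 3), c(2, 4, 6))$rho, 1)
  expect_equal(spearman_cor(c(1, 2, 3), c(2, 4, 6))$p_value, 0)
  # midranks: equals Pearson on ranks computed directly
  x <- c(1, 2, 2, 3); y <- c(4, 3, 3, 1)
  expect_equal(spearman_cor(x, y)$rho, cor(rank(x), rank(y)))
  # matches the standard implementation's t-approximation p-value
  withr::with_seed(19, {
    for (i in 1:20) {
      a <- rnorm(15); b <- 0.5 * a + rnorm(15)
      got <- spearman_cor(a, b)
      ref <- suppressWarnings(cor.test(a, b, method = "spearman", exact = FALSE))
      expect_equal(got$rho, unname(ref$estimate), tolerance = 1e-12)
      expect_equal(got$p_value, ref$p.value, tolerance = 1e-9)
    }
  })
  res <- suppressWarnings(spearman_cor(rep(1, 5), c(1, 2, 3, 4, 5)))
  expect_true(is.na(res$rho))
  expect_error(spearman_cor(1:2, 1:2), class = "adchist_bad_argument")
})

test_that("Spearman p-values are near-uniform under the null", {
  withr::with_seed(20, {
    p <- replicate(1000, {
      x <- rnorm(15)
      spearman_cor(x, sample(x))$p_value
    })
    expect_lt(abs(mean(p <= 0.05) - 0.05), 0.02)
  })
})

test_that("Spearman is invariant under strictly monotone transforms", {
  withr::with_seed(22, {
    x <- rlnorm(20); y <- rnorm(20)
    base <- spearman_cor(x, y)$rho
    expect_equal(spearman_cor(log(x), y)$rho, base)
    expect_equal(spearman_cor(x, exp(y))$rho, base)
    expect_equal(spearman_cor(x^3, qlogis(pnorm(y)))$rho, base)
  })
})

test_that("exact permutation Spearman p is available for tiny n", {
  withr::with_seed(23, {
    x <- rnorm(6); y <- rnorm(6)
    res <- spearman_cor(x, y, exact = TRUE)
    expect_equal(res$method, "exact permutation")
    expect_gte(res$p_value, 1 / factorial(6))
    expect_lte(res$p_value, 1)
  })
})

test_that("Levene's test matches the brute-force ANOVA on deviations", {
  v <- c(1, 2, 3, 4, 10, 20, 30, 40)
  g <- rep(c("a", "b"), each = 4)
  got <- levene_test(v, g)
  want <- oracle_levene(v, g)
  expect_equal(got$statistic, want$statistic, tolerance = 1e-12)
  expect_equal(got$p_value, want$p, tolerance = 1e-12)
  # agrees with the standard implementation (mean centering)
  ref <- car::leveneTest(v ~ factor(g), center = mean)
  expect_equal(got$statistic, ref[1, "F value"], tolerance = 1e-10)
  expect_equal(got$p_value, ref[1, "Pr(>F)"], tolerance = 1e-10)
  # identical groups: no evidence against homogeneity
  same <- levene_test(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_error(levene_test(c(1, 2, 3), c("a", "a", "b")),
               class = "adchist_bad_argument")
})

test_that("Levene's test holds its type-I error on equal-variance groups", {
  withr::with_seed(24, {
    rej <- replicate(1000, {
      levene_test(c(rnorm(8), rnorm(12)),
                  rep(c("a", "b"), c(8, 12)))$p_value <= 0.05
    })
    expect_lt(abs(mean(rej) - 0.05), 0.02)
  })
})

test_that("pooled t from summaries equals t.test on matching raw data", {
  expect_equal(pooled_t_from_summary(5, 1, 10, 5, 2, 8)$t, 0)
  expect_equal(pooled_t_from_summary(5, 1, 10, 5, 2, 8)$p_value, 1)
  expect_message(z <- pooled_t_from_summary(3, 0, 5, 3, 0, 5), "convention")
  expect_equal(z$p_value, 1)
  withr::with_seed(25, {
    for (i in 1:10) {
      x <- rnorm(7, 1); y <- rnorm(12)
      got <- pooled_t_from_summary(mean(x), sd(x), 7, mean(y), sd(y), 12)
      ref <- t.test(x, y, var.equal = TRUE)
      expect_equal(got$t, unname(ref$statistic), tolerance = 1e-10)
      expect_equal(got$df, unname(ref$parameter))
      expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
    }
  })
})

test_that("Mann-Whitney U matches enumeration and satisfies U-sum identity", {
  res <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(res$u, 0)
  expect_equal(res$p_value, 1 / 3, tolerance = 1e-12)
  expect_equal(res$mode_used, "exact")
  # identical multisets -> p = 1 under either mode
  expect_equal(mann_whitney_u(c(1, 2, 3), c(1, 2, 3), mode = "auto")$p_value, 1)
  expect_equal(suppressWarnings(
    mann_whitney_u(c(1, 2, 3), c(1, 2, 3), mode = "normal_approx"))$p_value, 1)
  withr::with_seed(26, {
    for (i in 1:20) {
      x <- rnorm(5); y <- rnorm(10)
      got <- mann_whitney_u(x, y)
      expect_equal(got$mode_used, "exact")
      expect_equal(got$u, oracle_u(x, y))
      expect_equal(got$p_value, oracle_mwu_exact_p(x, y), tolerance = 1e-12)
      # U(x,y) + U(y,x) = n1 * n2
      expect_equal(got$u + mann_whitney_u(y, x)$u, 50)
    }
  })
})

test_that("group classification reproduces the fixture's published split", {
  co <- read_cohort_table(fixture_path("cohort_table5.csv"))
  nodal <- classify_groups(co, "nodal_status")
  expect_equal(as.vector(table(nodal)), c(5, 10))
  inf <- classify_groups(co, "infiltration")
  expect_equal(unname(inf[4]), factor("advanced",
                                      levels = c("restricted", "advanced")))
  expect_equal(unname(inf[8]), factor("restricted",
                                      levels = c("restricted", "advanced")))
  expect_equal(as.vector(table(inf)), c(11, 4))
})

test_that("the Levene gate selects the comparison test per feature", {
  withr::with_seed(27, {
    ids <- sprintf("P%02d", 1:20)
    cohort <- tibble::tibble(patient_id = ids,
                             n_stage = rep(c(0L, 1L), each = 10),
                             infiltration_sites = replicate(20, "trachea",
                                                            simplify = FALSE))
    features <- tibble::tibble(
      patient_id = ids,
      # grossly unequal variances -> Mann-Whitney
      adc_mean = c(rnorm(10, 100, 1), rnorm(10, 100, 60)),
      # equal variances, shifted -> pooled t
      skewness = c(rnorm(10, -0.1, 0.3), rnorm(10, 0.9, 0.3))
    )
    cmp <- compare_groups(features, cohort, grouping = "nodal_status",
                          feature_cols = c("adc_mean", "skewness"))
    expect_equal(cmp$test_used[cmp$feature == "adc_mean"], "mann_whitney_u")
    expect_equal(cmp$test_used[cmp$feature == "skewness"], "pooled_t")
    expect_true(all(cmp$p_value >= 0 & cmp$p_value <= 1))
    # override forces the published test assignment regardless of the gate
    forced <- compare_groups(features, cohort, grouping = "nodal_status",
                             feature_cols = c("adc_mean", "skewness"),
                             test_override = c(adc_mean = "pooled_t"))
    expect_equal(forced$test_used[forced$feature == "adc_mean"], "pooled_t")
    expect_true(forced$gate_overridden[forced$feature == "adc_mean"])
    # swapping group membership flips t's sign, leaves p unchanged
    cohort_swapped <- cohort
    cohort_swapped$n_stage <- 1L - cohort$n_stage
    cmp2 <- compare_groups(features, cohort_swapped, grouping = "nodal_status",
                           feature_cols = "skewness")
    expect_equal(cmp2$statistic[1], -cmp$statistic[cmp$feature == "skewness"],
                 tolerance = 1e-12)
    expect_equal(cmp2$p_value[1], cmp$p_value[cmp$feature == "skewness"],
                 tolerance = 1e-12)
  })
})

test_that("identical groups produce no significant comparisons", {
  ids <- sprintf("P%02d", 1:10)
  base <- c(1.2, 3.4, 2.2, 5.1, 0.7)
  features <- tibble::tibble(patient_id = ids,
                             adc_mean = rep(base, 2),
                             skewness = rep(base / 10, 2))
  cohort <- tibble::tibble(patient_id = ids,
                           n_stage = rep(c(0L, 1L), each = 5))
  cmp <- compare_groups(features, cohort, grouping = "nodal_status",
                        feature_cols = c("adc_mean", "skewness"))
  expect_false(any(cmp$significant))
})

test_that("marker correlations mirror per-pair Spearman results", {
  withr::with_seed(28, {
    ids <- sprintf("P%02d", 1:15)
    features <- tibble::tibble(patient_id = ids,
                               adc_mean = rnorm(15, 120, 30),
                               kurtosis = rnorm(15, 3.6, 0.5))
    cohort <- tibble::tibble(patient_id = ids,
                             ki67_pct = runif(15, 0, 100),
                             p53_pct = runif(15, 0, 100))
    tab <- correlate_markers(features, cohort)
    expect_equal(nrow(tab), 4)
    one <- tab[tab$feature == "adc_mean" & tab$marker == "ki67_pct", ]
    ref <- spearman_cor(features$adc_mean, cohort$ki67_pct)
    expect_equal(one$rho, ref$rho)
    expect_equal(one$p_value, ref$p_value)
    expect_s3_class(tidy(tab), "tbl_df")
  })
})
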