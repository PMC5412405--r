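#' Spearman rank correlation with t-approximation p-value
#'
#' Midranks for ties; rho is the Pearson correlation of the ranks. The
#' two-sided p-value comes from `t = rho * sqrt((n-2) / (1-rho^2))` on `n - 2`
#' degrees of freedom (the usual behavior of mainstream statistics packages at
#' these sample sizes); `rho = +-1` reports `p = 0`. An exact permutation
#' p-value is available for small samples.
#'
#' @param x,y Numeric vectors of equal length `n >= 3`.
#' @param exact If `TRUE` and `n <= 10`, compute the p-value by full
#'   enumeration of the `n!` rank permutations instead.
#' @return A one-row tibble: `rho`, `p_value`, `n`, `method`.
#' @export
spearman_cor <- function(x, y, exact = FALSE) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3 || length(y) != n) {
    abort("spearman_cor needs equal-length inputs with n >= 3",
          class = "adchist_bad_argument")
  }
  rx <- rank(x); ry <- rank(y)
  if (var(rx) == 0 || var(ry) == 0) {
    warn("zero-variance input: Spearman correlation undefined")
    return(tibble(rho = NA_real_, p_value = NA_real_, n = n,
                  method = "undefined (zero variance)"))
  }
  rho <- cor(rx, ry)
  if (exact && n <= 10) {
    perms <- all_permutations(n)
    rhos <- apply(perms, 1, function(p) cor(rx, ry[p]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    return(tibble(rho = rho, p_value = p, n = n, method = "exact permutation"))
  }
  if (abs(rho) >= 1 - 1e-12) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
  }
  tibble(rho = rho, p_value = p, n = n, method = "t approximation")
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (k in seq_len(n)) {
    block <- cbind(k, ifelse(sub >= k, sub + 1L, sub))
    out[r + seq_len(nrow(sub)), ] <- block
    r <- r + nrow(sub)
  }
  out
}

#' Levene's test for homogeneity of variance
#'
#' Classic one-way ANOVA on the absolute deviations from each group's center.
#' The default center is the group mean, matching the default of the
#' statistics package conventionally used for these cohort analyses; the
#' Brown-Forsythe variant (median centering) is available.
#'
#' @param values Numeric vector of observations.
#' @param groups Group labels, same length as `values`.
#' @param center `"mean"` (default) or `"median"`.
#' @return A one-row tibble: `statistic`, `df1`, `df2`, `p_value`, `center`.
#' @export
levene_test <- function(values, groups, center = c("mean", "median")) {
  center <- match.arg(center)
  keep <- is.finite(values) & !is.na(groups)
  values <- values[keep]
  groups <- factor(groups[keep])
  if (nlevels(groups) < 2) {
    abort("levene_test needs at least 2 groups", class = "adchist_bad_argument")
  }
  if (any(table(groups) < 2)) {
    abort("every group needs at least 2 observations",
          class = "adchist_bad_argument")
  }
  centers <- tapply(values, groups, if (center == "mean") mean else median)
  dev <- abs(values - centers[as.character(groups)])
  if (all(dev == dev[1])) {
    # identical spread in every group: no evidence against homogeneity
    k <- nlevels(groups)
    return(tibble(statistic = 0, df1 = k - 1, df2 = length(values) - k,
                  p_value = 1, center = center))
  }
  a <- anova(lm(dev ~ groups))
  tibble(statistic = a[["F value"]][1], df1 = a$Df[1], df2 = a$Df[2],
         p_value = a[["Pr(>F)"]][1], center = center)
}

#' Pooled-variance two-sided t-test from group summary statistics
#'
#' Equal-variance unpaired t-test computed from `(mean, sd, n)` per group,
#' with `df = n1 + n2 - 2`. Given raw samples with exactly these summaries it
#' reproduces `t.test(var.equal = TRUE)`. When both SDs are zero and the means
#' are equal, `t = 0` and `p = 1` by convention.
#'
#' @param mean1,sd1,n1 Summary statistics of the first group.
#' @param mean2,sd2,n2 Summary statistics of the second group.
#' @return A one-row tibble: `t`, `df`, `p_value`.
#' @examples
#' pooled_t_from_summary(-0.12, 0.64, 5, 0.41, 0.21, 10)
#' @export
pooled_t_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  if (sp2 == 0) {
    if (mean1 == mean2) {
      inform("both groups have zero variance and equal means: t = 0, p = 1 by convention")
      return(tibble(t = 0, df = df, p_value = 1))
    }
    return(tibble(t = sign(mean1 - mean2) * Inf, df = df, p_value = 0))
  }
  tstat <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  tibble(t = tstat, df = df, p_value = 2 * pt(-abs(tstat), df))
}

#' Mann-Whitney U test
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test. `U` is reported for the
#' first group (number of `(x, y)` pairs with `x > y`, ties counting 1/2). In
#' `auto` mode the exact null distribution is used when `n1 + n2 <= 20` and
#' there are no ties; otherwise the normal approximation with tie and
#' continuity corrections.
#'
#' @param x,y Numeric vectors (both nonempty).
#' @param mode `"auto"` (default), `"exact"` or `"normal_approx"`.
#' @return A one-row tibble: `u`, `p_value`, `n1`, `n2`, `mode_used`.
#' @export
mann_whitney_u <- function(x, y, mode = c("auto", "exact", "normal_approx")) {
  mode <- match.arg(mode)
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) == 0 || length(y) == 0) {
    abort("both groups must be nonempty", class = "adchist_bad_argument")
  }
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- switch(mode,
    exact = TRUE,
    normal_approx = FALSE,
    auto = (length(x) + length(y)) <= 20 && !ties
  )
  if (use_exact && ties) {
    warn("ties present: falling back to the normal approximation")
    use_exact <- FALSE
  }
  wt <- suppressWarnings(
    wilcox.test(x, y, exact = use_exact, correct = TRUE, alternative = "two.sided")
  )
  tibble(
    u = unname(wt$statistic),
    p_value = wt$p.value,
    n1 = length(x), n2 = length(y),
    mode_used = if (use_exact) "exact" else "normal_approx"
  )
}

#' Correlate histogram features with histopathology markers
#'
#' Spearman correlation of every feature column against every marker column,
#' joined per patient. Mirrors the feature-by-marker correlation table of a
#' cohort report.
#'
#' @param features Feature tibble from [cohort_features()] (needs
#'   `patient_id`).
#' @param cohort Cohort tibble from [read_cohort_table()] with marker columns.
#' @param feature_cols,marker_cols Column selections (defaults: the standard
#'   feature set; all marker columns present).
#' @param sig_alpha Significance threshold for the `significant` flag.
#' @return A tibble of class `adc_correlations`: `feature`, `marker`, `rho`,
#'   `p_value`, `n`, `significant`.
#' @export
correlate_markers <- function(features, cohort,
                              feature_cols = NULL, marker_cols = NULL,
                              sig_alpha = 0.05) {
  feature_cols <- feature_cols %||%
    intersect(c("adc_mean", "adc_min", "adc_max", "p10", "p25", "p75", "p90",
                "adc_median", "adc_mode", "kurtosis", "skewness", "entropy"),
              names(features))
  marker_cols <- marker_cols %||% intersect(marker_names, names(cohort))
  if (length(marker_cols) == 0) {
    abort("cohort table has no marker columns to correlate",
          class = "adchist_bad_argument")
  }
  joined <- dplyr::inner_join(
    features[c("patient_id", feature_cols)],
    cohort[c("patient_id", marker_cols)],
    by = "patient_id"
  )
  grid <- tidyr::expand_grid(feature = feature_cols, marker = marker_cols)
  out <- purrr::pmap(grid, function(feature, marker) {
    res <- spearman_cor(joined[[feature]], joined[[marker]])
    tibble(feature = feature, marker = marker,
           rho = res$rho, p_value = res$p_value, n = res$n)
  }) |>
    purrr::list_rbind() |>
    dplyr::mutate(significant = .data$p_value <= sig_alpha)
  class(out) <- c("adc_correlations", class(out))
  out
}

#' Classify patients into the two comparison groups
#'
#' `nodal_status`: N0 (`n_stage == 0`) versus N1/2 (`n_stage >= 1`).
#' `infiltration`: restricted (sites within thyroid gland / trachea) versus
#' advanced (esophagus or internal jugular vein involved).
#'
#' @param cohort Cohort tibble.
#' @param grouping `"nodal_status"` or `"infiltration"`.
#' @return Factor of group labels, one per row of `cohort`.
#' @export
classify_groups <- function(cohort, grouping = c("nodal_status", "infiltration")) {
  grouping <- match.arg(grouping)
  if (grouping == "nodal_status") {
    factor(ifelse(cohort$n_stage == 0, "N0", "N1/2"), levels = c("N0", "N1/2"))
  } else {
    adv <- vapply(cohort$infiltration_sites, function(s) {
      length(intersect(s, c("esophagus", "internal jugular vein"))) > 0
    }, logical(1))
    factor(ifelse(adv, "advanced", "restricted"),
           levels = c("restricted", "advanced"))
  }
}

#' Levene-gated two-group comparison of histogram features
#'
#' For each feature: Levene's test on the two groups decides the comparison
#' test — pooled-variance t-test if `levene_p > gate_alpha` (homoscedastic),
#' Mann-Whitney U otherwise. A per-feature `test_override` map can force a
#' specific test regardless of the gate (useful to replicate a published test
#' assignment). Significance is flagged at `p <= sig_alpha` with no
#' multiple-testing correction by default (a Holm adjustment is available).
#'
#' @param features Feature tibble with `patient_id` and feature columns.
#' @param cohort Cohort tibble with `patient_id` and staging columns.
#' @param grouping `"nodal_status"` or `"infiltration"`.
#' @param gate_alpha Significance level of the Levene gate (default 0.05).
#' @param feature_cols Features to compare (default: the standard set).
#' @param test_override Named character vector / list mapping feature name to
#'   `"pooled_t"` or `"mann_whitney_u"`, bypassing the gate for those features.
#' @param sig_alpha Threshold for the `significant` flag (default 0.05).
#' @param p_adjust `"none"` (default) or `"holm"`.
#' @return A tibble of class `adc_group_comparison`: one row per feature with
#'   per-group `n`, `mean`, `sd`, the Levene p, `test_used`, `statistic`,
#'   `p_value` and `significant`.
#' @export
compare_groups <- function(features, cohort,
                           grouping = c("nodal_status", "infiltration"),
                           gate_alpha = 0.05, feature_cols = NULL,
                           test_override = NULL, sig_alpha = 0.05,
                           p_adjust = c("none", "holm")) {
  grouping <- match.arg(grouping)
  p_adjust <- match.arg(p_adjust)
  feature_cols <- feature_cols %||%
    intersect(c("adc_mean", "adc_min", "adc_max", "p10", "p25", "p75", "p90",
                "adc_median", "adc_mode", "kurtosis", "skewness", "entropy"),
              names(features))
  cohort <- dplyr::mutate(cohort, .group = classify_groups(cohort, grouping))
  joined <- dplyr::inner_join(features, cohort[c("patient_id", ".group")],
                              by = "patient_id")
  sizes <- table(joined$.group)
  if (length(sizes) < 2 || any(sizes == 0)) {
    abort(sprintf("grouping '%s' leaves an empty group (sizes: %s)",
                  grouping, paste(sizes, collapse = ", ")),
          class = "adchist_bad_grouping")
  }
  labs <- levels(joined$.group)
  rows <- purrr::map(feature_cols, function(f) {
    v <- joined[[f]]
    g <- joined$.group
    keep <- is.finite(v)
    v <- v[keep]; g <- g[keep]
    x <- v[g == labs[1]]; y <- v[g == labs[2]]
    lev <- levene_test(v, g)
    forced <- if (!is.null(test_override) && f %in% names(test_override)) {
      as.character(test_override[[f]])
    } else NULL
    test <- forced %||%
      (if (lev$p_value > gate_alpha) "pooled_t" else "mann_whitney_u")
    if (test == "pooled_t") {
      res <- pooled_t_from_summary(mean(x), sd(x), length(x),
                                   mean(y), sd(y), length(y))
      stat <- res$t; p <- res$p_value
    } else if (test == "mann_whitney_u") {
      res <- mann_whitney_u(x, y)
      stat <- res$u; p <- res$p_value
    } else {
      abort(sprintf("unknown test '%s' in test_override for feature '%s'",
                    test, f), class = "adchist_bad_argument")
    }
    tibble(
      feature = f, group1 = labs[1], group2 = labs[2],
      n1 = length(x), mean1 = mean(x), sd1 = sd(x),
      n2 = length(y), mean2 = mean(y), sd2 = sd(y),
      levene_p = lev$p_value,
      test_used = test, gate_overridden = !is.null(forced),
      statistic = stat, p_value = p
    )
  })
  out <- purrr::list_rbind(rows)
  if (p_adjust == "holm") {
    out$p_adjusted <- stats::p.adjust(out$p_value, method = "holm")
    out$significant <- out$p_adjusted <= sig_alpha
  } else {
    out$significant <- out$p_value <= sig_alpha
  }
  attr(out, "grouping") <- grouping
  attr(out, "gate_alpha") <- gate_alpha
  class(out) <- c("adc_group_comparison", class(out))
  out
}

#' @export
tidy.adc_group_comparison <- function(x, ...) {
  as_tibble(x)
}

#' @export
glance.adc_group_comparison <- function(x, ...) {
  tibble(
    grouping = attr(x, "grouping"),
    gate_alpha = attr(x, "gate_alpha"),
    n_features = nrow(x),
    n_significant = sum(x$significant),
    n_mann_whitney = sum(x$test_used == "mann_whitney_u"),
    n_pooled_t = sum(x$test_used == "pooled_t")
  )
}

#' @export
tidy.adc_correlations <- function(x, ...) {
  as_tibble(x)
}
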