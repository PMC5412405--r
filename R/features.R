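#' Extract the whole-lesion voxel sample from an ADC map and mask
#'
#' Collects every ADC value inside the volume of interest across all slices
#' (the whole-lesion measure). Downstream features are order-independent.
#'
#' @param map An [adc_map()].
#' @param mask A [lesion_mask()] on the same grid.
#' @return An object of class `voxel_sample`: list with `values` (numeric
#'   vector, 1e-5 mm^2/s), `voxel_count` and `voxel_volume` (mm^3).
#' @export
extract_voi_values <- function(map, mask) {
  stopifnot(inherits(map, "adc_map"), inherits(mask, "lesion_mask"))
  if (!identical(dim(map$values), dim(mask$values))) {
    abort(sprintf("mask grid %s does not match map grid %s",
                  paste(dim(mask$values), collapse = "x"),
                  paste(dim(map$values), collapse = "x")),
          class = "adchist_grid_mismatch")
  }
  if (max(abs(map$spacing - mask$spacing)) > 1e-3) {
    abort("mask voxel spacing does not match map spacing",
          class = "adchist_grid_mismatch")
  }
  idx <- mask$values != 0
  if (!any(idx)) {
    abort("empty mask: no voxels in the VOI", class = "adchist_empty_mask")
  }
  structure(
    list(values = as.numeric(map$values[idx]),
         voxel_count = sum(idx),
         voxel_volume = voxel_volume_mm3(map)),
    class = "voxel_sample"
  )
}

#' @export
print.voxel_sample <- function(x, ...) {
  cat(sprintf("<voxel_sample> %d voxels (%.2f cm^3), ADC range [%.1f, %.1f]\n",
              x$voxel_count, x$voxel_count * x$voxel_volume / 1000,
              min(x$values), max(x$values)))
  invisible(x)
}

#' Percentiles by the MATLAB prctile convention
#'
#' Order statistics are placed at probabilities `(i - 0.5) / n` and linearly
#' interpolated between; probabilities beyond the extreme positions clamp to
#' the sample minimum / maximum. This mirrors the convention of the toolchain
#' historically used for ADC histogram reports; `quantile(type = 7)` is the
#' alternative convention offered by [compute_features()].
#'
#' @param x Numeric vector.
#' @param probs Probabilities in `[0, 1]`.
#' @return Numeric vector of percentile values.
#' @export
quantile_matlab <- function(x, probs) {
  stopifnot(length(x) >= 1, all(probs >= 0 & probs <= 1))
  s <- sort(x)
  n <- length(s)
  pos <- (seq_len(n) - 0.5) / n
  vapply(probs, function(p) {
    if (p <= pos[1]) return(s[1])
    if (p >= pos[n]) return(s[n])
    stats::approx(pos, s, xout = p)$y
  }, numeric(1))
}

# Biased (population) central-moment skewness and non-excess kurtosis; the
# estimators behind the reported histogram shape parameters. Constant samples
# have undefined shape (NaN).
sample_skewness <- function(x) {
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) return(NaN)
  mean((x - m)^3) / m2^1.5
}

sample_kurtosis <- function(x) {
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) return(NaN)
  mean((x - m)^4) / m2^2
}

# Equal-width histogram over [min, max] shared by the mode and entropy
# features. Values at the right edge fall in the last bin.
voi_histogram <- function(values, bin_count) {
  lo <- min(values); hi <- max(values)
  if (lo == hi) {
    return(list(counts = length(values), centers = lo,
                edges = c(lo, hi), degenerate = TRUE))
  }
  width <- (hi - lo) / bin_count
  idx <- pmin(floor((values - lo) / width) + 1L, bin_count)
  counts <- tabulate(idx, nbins = bin_count)
  centers <- lo + (seq_len(bin_count) - 0.5) * width
  list(counts = counts, centers = centers,
       edges = lo + (0:bin_count) * width, degenerate = FALSE)
}

#' First-order histogram features of a whole-lesion ADC sample
#'
#' Computes the per-lesion feature vector used in ADC histogram analysis:
#' mean, minimum, maximum, median, mode, the 10th/25th/75th/90th percentiles
#' (all in 1e-5 mm^2/s), skewness and non-excess kurtosis from biased central
#' moments, Shannon entropy in bits of the binned value distribution, and the
#' VOI volume in cm^3.
#'
#' Mode is the center of the most populated of `bin_count` equal-width bins
#' spanning `[min, max]` (ties resolve to the lowest center); entropy uses the
#' same bins, with empty bins contributing zero. A constant sample has
#' undefined skewness/kurtosis (`NaN`, with a warning), entropy 0, and mode
#' equal to the constant.
#'
#' @param sample A [extract_voi_values()] result, or a bare numeric vector.
#' @param bin_count Number of histogram bins for mode and entropy (default 64).
#' @param percentiles Convention for percentile estimation: `"matlab"`
#'   (order statistics at `(i-0.5)/n`, the default) or `"type7"`.
#' @return A one-row tibble with the feature columns plus `voxel_count`,
#'   `volume_cm3`, `bin_count` and `bin_width`.
#' @examples
#' compute_features(c(1, 2, 2, 3, 10), bin_count = 4)
#' @export
compute_features <- function(sample, bin_count = 64,
                             percentiles = c("matlab", "type7")) {
  percentiles <- match.arg(percentiles)
  if (inherits(sample, "voxel_sample")) {
    values <- sample$values
    voxel_count <- sample$voxel_count
    voxel_volume <- sample$voxel_volume
  } else {
    values <- as.numeric(sample)
    voxel_count <- length(values)
    voxel_volume <- NA_real_
  }
  if (length(values) == 0) {
    abort("empty voxel sample", class = "adchist_empty_sample")
  }
  if (!is.numeric(bin_count) || bin_count < 2) {
    abort("bin_count must be >= 2", class = "adchist_bad_argument")
  }
  bin_count <- as.integer(bin_count)
  probs <- c(0.10, 0.25, 0.75, 0.90)
  q <- switch(percentiles,
    matlab = quantile_matlab(values, probs),
    type7 = unname(quantile(values, probs, type = 7))
  )
  h <- voi_histogram(values, bin_count)
  p <- h$counts / sum(h$counts)
  entropy <- -sum(ifelse(p > 0, p * log2(p), 0))
  skew <- sample_skewness(values)
  kurt <- sample_kurtosis(values)
  if (is.nan(skew)) {
    warn("constant voxel sample: skewness and kurtosis are undefined (zero variance)")
  }
  tibble(
    adc_mean = mean(values),
    adc_min = min(values),
    adc_max = max(values),
    adc_median = median(values),
    adc_mode = h$centers[which.max(h$counts)],
    p10 = q[1], p25 = q[2], p75 = q[3], p90 = q[4],
    skewness = skew,
    kurtosis = kurt,
    entropy = entropy,
    voxel_count = voxel_count,
    volume_cm3 = voxel_count * voxel_volume / 1000,
    bin_count = bin_count,
    bin_width = if (h$degenerate) 0 else diff(h$edges[1:2])
  )
}

#' Fit the apparent diffusion coefficient from multi-b signals
#'
#' Ordinary least squares of `log(S)` against the b-value for one voxel's
#' signals; the ADC is minus the slope, rescaled to 1e-5 mm^2/s. Non-positive
#' signals are excluded (flagged in the result); noiseless mono-exponential
#' input is recovered exactly.
#'
#' @param signals Numeric vector of signal intensities, one per b-value.
#' @param b_values b-values in s/mm^2 (at least two distinct).
#' @return The fitted ADC in 1e-5 mm^2/s, with attribute `n_used`.
#' @examples
#' adc_fit(c(1000, 670.32, 449.33), c(0, 400, 800)) # ~100
#' @export
adc_fit <- function(signals, b_values) {
  stopifnot(length(signals) == length(b_values))
  ok <- is.finite(signals) & signals > 0
  if (sum(ok) == 0) {
    abort("all signals are non-positive; ADC undefined",
          class = "adchist_bad_signal")
  }
  b <- b_values[ok]
  if (length(unique(b)) < 2) {
    abort("fewer than 2 usable distinct b-values", class = "adchist_bad_signal")
  }
  y <- log(signals[ok])
  slope <- sum((b - mean(b)) * (y - mean(y))) / sum((b - mean(b))^2)
  structure(-slope * 1e5, n_used = sum(ok))
}

#' Fit an ADC map from a 4D DWI stack
#'
#' Voxel-wise version of [adc_fit()] over a `x * y * z * b` signal array.
#' Voxels without at least two usable (positive) signals at distinct b-values
#' get ADC 0 and are counted in the `n_flagged` attribute.
#'
#' @param dwi 4D numeric array, last dimension indexing b-values.
#' @param b_values b-values in s/mm^2, matching the 4th dimension.
#' @param spacing Voxel spacing in mm for the output map.
#' @return An [adc_map()] (1e-5 mm^2/s) with attribute `n_flagged`.
#' @export
adc_fit_map <- function(dwi, b_values, spacing = c(1, 1, 1)) {
  d <- dim(dwi)
  if (length(d) != 4 || d[4] != length(b_values)) {
    abort("dwi must be a 4D array with one volume per b-value",
          class = "adchist_bad_volume")
  }
  nb <- length(b_values)
  sig <- matrix(dwi, ncol = nb)
  pos <- is.finite(sig) & sig > 0
  all_ok <- rowSums(pos) == nb
  adc <- numeric(nrow(sig))
  # vectorized OLS for fully usable voxels
  if (any(all_ok)) {
    b <- b_values
    bc <- b - mean(b)
    y <- log(sig[all_ok, , drop = FALSE])
    slope <- (y %*% bc) / sum(bc^2)
    adc[all_ok] <- -slope * 1e5
  }
  flagged <- 0L
  for (i in which(!all_ok)) {
    ok <- pos[i, ]
    if (sum(ok) >= 2 && length(unique(b_values[ok])) >= 2) {
      adc[i] <- unclass(adc_fit(sig[i, ], b_values))
      flagged <- flagged + 1L
    } else {
      adc[i] <- 0
      flagged <- flagged + 1L
    }
  }
  out <- adc_map(array(adc, dim = d[1:3]), spacing = spacing)
  attr(out, "n_flagged") <- flagged
  out
}

#' Cohort-level summary of one feature: median, range, min, max
#'
#' The descriptive summary used for cohort tables of DWI histogram parameters
#' (median, range = max - min, minimum-maximum).
#'
#' @param values Numeric vector of per-patient feature values.
#' @return A one-row tibble with `median`, `range`, `min`, `max`, `n`.
#' @export
summarize_cohort <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) == 0) {
    abort("no finite values to summarize", class = "adchist_empty_sample")
  }
  tibble(
    median = median(values),
    range = max(values) - min(values),
    min = min(values),
    max = max(values),
    n = length(values)
  )
}

#' Histogram features for every patient in a cohort
#'
#' @param maps Named list of [adc_map()]s (names are patient ids).
#' @param masks Named list of [lesion_mask()]s with matching names.
#' @param ... Passed to [compute_features()].
#' @return A tibble with one row per patient (`patient_id` first).
#' @export
cohort_features <- function(maps, masks, ...) {
  stopifnot(length(maps) == length(masks))
  ids <- names(maps) %||% as.character(seq_along(maps))
  purrr::map2(maps, masks, function(m, k) {
    compute_features(extract_voi_values(m, k), ...)
  }) |>
    purrr::list_rbind() |>
    dplyr::mutate(patient_id = ids, .before = 1)
}
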