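#' Convert a Spearman rank correlation to the latent Gaussian correlation
#'
#' For a Gaussian copula, a latent Pearson correlation `r` induces a Spearman
#' correlation `(6/pi) * asin(r/2)` between the transformed margins; this is
#' the inverse map, `r = 2 * sin(pi * rho / 6)`.
#'
#' @param rho Spearman correlation(s) in `[-1, 1]`.
#' @return Latent Pearson correlation(s).
#' @export
spearman_to_pearson <- function(rho) 2 * sin(pi * rho / 6)

#' @rdname spearman_to_pearson
#' @param r Latent Pearson correlation(s).
#' @export
pearson_to_spearman <- function(r) (6 / pi) * asin(r / 2)

adc_summary_names <- c("adc_mean", "adc_max", "kurtosis")
marker_names <- c("cell_count", "ki67_pct", "p53_pct",
                  "total_nuclear_area", "average_nuclear_area")

#' Default rank-correlation matrix linking ADC summaries and markers
#'
#' Joint Spearman correlation matrix over the three lesion-level ADC summaries
#' (`adc_mean`, `adc_max`, `kurtosis`) and the five immunohistopathology
#' markers (cell count, Ki-67 %, p53 %, total and average nuclear area). The
#' cross block holds the reported feature-marker rank correlations for
#' follicular-cell derived thyroid carcinoma; the within-block entries are not
#' identifiable from group-level summaries and are set to plausible values
#' chosen so that the implied latent Gaussian matrix is positive definite.
#'
#' @return A symmetric 8x8 named matrix with unit diagonal.
#' @export
default_copula_matrix <- function() {
  nm <- c(adc_summary_names, marker_names)
  S <- diag(8)
  dimnames(S) <- list(nm, nm)
  set <- function(i, j, v) {
    S[i, j] <<- v; S[j, i] <<- v
  }
  # ADC summary block (unreported; chosen, see vignette)
  set("adc_mean", "adc_max", 0.67)
  set("adc_mean", "kurtosis", -0.18)
  set("adc_max", "kurtosis", -0.05)
  # cross block: reported Spearman point estimates
  set("adc_mean", "cell_count", 0.429)
  set("adc_max", "cell_count", 0.372)
  set("kurtosis", "cell_count", -0.571)
  set("adc_mean", "ki67_pct", -0.325)
  set("adc_max", "ki67_pct", -0.646)
  set("kurtosis", "ki67_pct", -0.314)
  set("adc_mean", "p53_pct", 0.548)
  set("adc_max", "p53_pct", 0.645)
  set("kurtosis", "p53_pct", -0.262)
  set("adc_mean", "total_nuclear_area", 0.389)
  set("adc_max", "total_nuclear_area", 0.461)
  set("kurtosis", "total_nuclear_area", -0.411)
  set("adc_mean", "average_nuclear_area", 0.034)
  set("adc_max", "average_nuclear_area", 0.155)
  set("kurtosis", "average_nuclear_area", -0.182)
  # marker block (unreported; chosen, see vignette)
  set("cell_count", "ki67_pct", 0.22)
  set("cell_count", "p53_pct", 0.31)
  set("cell_count", "total_nuclear_area", 0.59)
  set("cell_count", "average_nuclear_area", 0.11)
  set("ki67_pct", "p53_pct", -0.35)
  set("ki67_pct", "total_nuclear_area", -0.05)
  set("ki67_pct", "average_nuclear_area", 0.11)
  set("p53_pct", "total_nuclear_area", 0.33)
  set("p53_pct", "average_nuclear_area", 0.13)
  set("total_nuclear_area", "average_nuclear_area", 0.46)
  S
}

validate_copula_matrix <- function(S, tol = 1e-8) {
  if (!is.matrix(S) || nrow(S) != ncol(S)) {
    abort("copula matrix must be square", class = "adchist_bad_copula")
  }
  if (max(abs(S - t(S))) > tol) {
    abort("copula matrix must be symmetric", class = "adchist_bad_copula")
  }
  if (max(abs(diag(S) - 1)) > tol) {
    abort("copula matrix must have unit diagonal", class = "adchist_bad_copula")
  }
  ev <- eigen(spearman_to_pearson(S) + diag(1 - spearman_to_pearson(1), nrow(S)),
              symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol) {
    abort(sprintf(
      "copula matrix is not positive semi-definite on the latent scale (min eigenvalue %.3g)",
      min(ev)
    ), class = "adchist_copula_not_psd")
  }
  invisible(S)
}

# Marginal quantile functions for the synthetic marker table; ranges chosen to
# span the cohort-level medians/ranges reported for these markers.
marker_quantile_funs <- function() {
  list(
    cell_count = function(p) pmax(100L, as.integer(round(qlnorm(p, log(1300), 0.45)))),
    ki67_pct = function(p) 100 * qbeta(p, 1.1, 1.7),
    p53_pct = function(p) 100 * qbeta(p, 0.55, 2.6),
    total_nuclear_area = function(p) qlnorm(p, log(68000), 0.75),
    average_nuclear_area = function(p) qlnorm(p, log(54), 0.25)
  )
}
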