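#' Moments implied by Fleishman polynomial coefficients
#'
#' For `Y = a + b*Z + c*Z^2 + d*Z^3` with `Z` standard normal and `a = -c`,
#' returns the mean, variance, skewness and (non-excess) kurtosis of `Y` in
#' closed form. These are the classic power-method moment equations; they are
#' used both by the solver and as its independent verification.
#'
#' @param coef Named numeric vector or list with elements `a`, `b`, `c`, `d`.
#' @return A tibble with columns `mean`, `variance`, `skewness`, `kurtosis`.
#' @export
fleishman_moments <- function(coef) {
  a <- coef[["a"]]; b <- coef[["b"]]; cc <- coef[["c"]]; d <- coef[["d"]]
  mean <- a + cc
  v <- b^2 + 6 * b * d + 2 * cc^2 + 15 * d^2
  skew <- 2 * cc * (b^2 + 24 * b * d + 105 * d^2 + 2)
  exkurt <- 24 * (b * d + cc^2 * (1 + b^2 + 28 * b * d) +
    d^2 * (12 + 48 * b * d + 141 * cc^2 + 225 * d^2))
  tibble(
    mean = mean,
    variance = v,
    skewness = skew / v^1.5,
    kurtosis = exkurt / v^2 + 3
  )
}

# Empirical lower boundary of the Fleishman-attainable region, in terms of
# non-excess kurtosis as a function of skewness.
fleishman_min_kurtosis <- function(skewness) {
  1.7735511 + 1.6410373 * skewness^2
}

#' Solve for Fleishman coefficients matching target skewness and kurtosis
#'
#' Finds coefficients of the cubic transform `Y = a + b*Z + c*Z^2 + d*Z^3` of a
#' standard normal `Z` such that `Y` has mean 0, variance 1 and the requested
#' third and fourth standardized moments. The solution is verified analytically
#' against the closed-form moment equations (not by sampling).
#'
#' @param skewness Target skewness of the transformed variable.
#' @param kurtosis Target non-excess kurtosis (3 for a normal distribution).
#' @param tol Maximum allowed absolute residual of the moment equations.
#' @return A one-row tibble of class `fleishman_coef` with columns `a`, `b`,
#'   `c`, `d`, `skewness`, `kurtosis`, `residual`.
#' @examples
#' solve_fleishman(0, 3)        # identity transform
#' solve_fleishman(0.41, 3.81)
#' @export
solve_fleishman <- function(skewness, kurtosis, tol = 1e-8) {
  stopifnot(is.numeric(skewness), is.numeric(kurtosis), length(skewness) == 1,
            length(kurtosis) == 1)
  if (kurtosis < skewness^2 + 1) {
    abort(sprintf(
      "(skewness = %g, kurtosis = %g) violates the moment inequality kurtosis >= skewness^2 + 1",
      skewness, kurtosis
    ), class = "adchist_infeasible_moments")
  }
  if (kurtosis < fleishman_min_kurtosis(skewness) - 1e-9) {
    abort(sprintf(
      "(skewness = %g, kurtosis = %g) is outside the Fleishman region (needs kurtosis >= %.4f)",
      skewness, kurtosis, fleishman_min_kurtosis(skewness)
    ), class = "adchist_outside_fleishman")
  }
  if (abs(skewness) < 1e-12 && abs(kurtosis - 3) < 1e-12) {
    out <- tibble(a = 0, b = 1, c = 0, d = 0,
                  skewness = skewness, kurtosis = kurtosis, residual = 0)
    class(out) <- c("fleishman_coef", class(out))
    return(out)
  }
  target <- c(1, skewness, kurtosis - 3)
  eqs <- function(p) {
    b <- p[1]; cc <- p[2]; d <- p[3]
    c(
      b^2 + 6 * b * d + 2 * cc^2 + 15 * d^2,
      2 * cc * (b^2 + 24 * b * d + 105 * d^2 + 2),
      24 * (b * d + cc^2 * (1 + b^2 + 28 * b * d) +
        d^2 * (12 + 48 * b * d + 141 * cc^2 + 225 * d^2))
    ) - target
  }
  sgn <- if (skewness >= 0) 1 else -1
  starts <- list(
    c(1 - 0.1 * abs(kurtosis - 3), skewness / 6, (kurtosis - 3) / 50),
    c(0.95, sgn * 0.1, 0.02),
    c(0.9, sgn * 0.25, -0.05),
    c(0.8, sgn * 0.3, 0.05),
    c(1.05, skewness / 8, (kurtosis - 3) / 20),
    c(0.7, sgn * 0.35, -0.08),
    c(1.1, sgn * 0.05, -0.03)
  )
  sol <- NULL
  for (s0 in starts) {
    cand <- tryCatch(
      suppressWarnings(pracma::fsolve(eqs, s0, tol = .Machine$double.eps^0.7)),
      error = function(e) NULL
    )
    if (!is.null(cand) && max(abs(eqs(cand$x))) <= tol) {
      sol <- cand
      break
    }
  }
  if (is.null(sol) || max(abs(eqs(sol$x))) > tol) {
    abort(sprintf(
      "no Fleishman coefficients found for (skewness = %g, kurtosis = %g): outside Fleishman region or solver failure",
      skewness, kurtosis
    ), class = "adchist_outside_fleishman")
  }
  p <- sol$x
  out <- tibble(a = -p[2], b = p[1], c = p[2], d = p[3],
                skewness = skewness, kurtosis = kurtosis,
                residual = max(abs(eqs(p))))
  class(out) <- c("fleishman_coef", class(out))
  out
}

#' Apply a Fleishman transform to standard-normal draws
#'
#' @param z Numeric vector of standard-normal draws.
#' @param coef Coefficients as returned by [solve_fleishman()].
#' @return Numeric vector with mean 0, variance 1 and the coefficients'
#'   implied skewness/kurtosis (in distribution).
#' @export
fleishman_transform <- function(z, coef) {
  coef[["a"]] + coef[["b"]] * z + coef[["c"]] * z^2 + coef[["d"]] * z^3
}
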