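# Independent brute-force oracles, kept deliberately naive and separate from
# the package implementations they check.

fixture_path <- function(name) {
  system.file("extdata", name, package = "adchist", mustWork = TRUE)
}

# Direct-formula feature oracle: loops and explicit sums only.
oracle_features <- function(x, bin_count = 64) {
  n <- length(x)
  mu <- sum(x) / n
  m2 <- sum((x - mu)^2) / n
  m3 <- sum((x - mu)^3) / n
  m4 <- sum((x - mu)^4) / n
  s <- sort(x)
  pct <- function(p) {
    pos <- (seq_len(n) - 0.5) / n
    if (p <= pos[1]) return(s[1])
    if (p >= pos[n]) return(s[n])
    i <- max(which(pos <= p))
    s[i] + (p - pos[i]) / (pos[i + 1] - pos[i]) * (s[i + 1] - s[i])
  }
  med <- if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
  lo <- s[1]; hi <- s[n]
  if (lo == hi) {
    mode <- lo; entropy <- 0
  } else {
    w <- (hi - lo) / bin_count
    counts <- integer(bin_count)
    for (v in x) {
      k <- min(floor((v - lo) / w) + 1, bin_count)
      counts[k] <- counts[k] + 1L
    }
    mode <- lo + (which.max(counts) - 0.5) * w
    entropy <- 0
    for (cnt in counts[counts > 0]) {
      p <- cnt / n
      entropy <- entropy - p * log2(p)
    }
  }
  list(
    adc_mean = mu, adc_min = lo, adc_max = hi, adc_median = med,
    adc_mode = mode,
    p10 = pct(0.10), p25 = pct(0.25), p75 = pct(0.75), p90 = pct(0.90),
    skewness = if (m2 == 0) NaN else m3 / m2^1.5,
    kurtosis = if (m2 == 0) NaN else m4 / m2^2,
    entropy = entropy
  )
}

# Mann-Whitney U of the first group, ties counted 1/2.
oracle_u <- function(x, y) {
  u <- 0
  for (xi in x) for (yj in y) {
    u <- u + (xi > yj) + 0.5 * (xi == yj)
  }
  u
}

# Exact two-sided Mann-Whitney p by full enumeration of group assignments.
oracle_mwu_exact_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  idx <- utils::combn(length(pooled), n1)
  u_obs <- oracle_u(x, y)
  mid <- n1 * length(y) / 2
  us <- apply(idx, 2, function(ii) oracle_u(pooled[ii], pooled[-ii]))
  mean(abs(us - mid) >= abs(u_obs - mid) - 1e-9)
}

# Classic Levene statistic by explicit one-way ANOVA on |deviations|.
oracle_levene <- function(values, groups, center = "mean") {
  groups <- factor(groups)
  cen <- tapply(values, groups, if (center == "mean") mean else median)
  z <- abs(values - cen[as.character(groups)])
  k <- nlevels(groups); n <- length(z)
  zbar <- mean(z)
  zg <- tapply(z, groups, mean)
  ng <- tabulate(groups)
  ssb <- sum(ng * (zg - zbar)^2)
  ssw <- sum((z - zg[as.character(groups)])^2)
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  list(statistic = f, p = pf(f, k - 1, n - k, lower.tail = FALSE))
}

random_voxel_sample <- function(n = NULL) {
  n <- n %||% sample(3:100, 1)
  gen <- sample(1:4, 1)
  switch(gen,
    rnorm(n, 120, 40),
    rlnorm(n, log(100), 0.5),
    runif(n, 10, 300),
    round(rnorm(n, 120, 40)) # heavy ties
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
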