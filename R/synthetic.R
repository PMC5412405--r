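#' Configuration for the synthetic cohort generator
#'
#' Bundles the study conditions the generator emulates: cohort size and nodal
#' group split, per-group voxel-distribution targets (mean and SD in 1e-5
#' mm^2/s, skewness, non-excess kurtosis, plus the between-patient spread of
#' each), lesion geometry, background tissue level, the rank-correlation
#' matrix coupling lesion ADC summaries to histopathology markers, and the
#' DWI signal model. Defaults reproduce the group-level structure reported
#' for a 15-patient thyroid-carcinoma cohort (5 nodal-negative, 10
#' nodal-positive).
#'
#' @param n_patients Number of patients.
#' @param group_fractions Named fractions for the `N0` and `N1/2` groups
#'   (must sum to 1).
#' @param group_targets Tibble with one row per group: `group`, `adc_mean`,
#'   `adc_mean_sd` (between-patient SD of the lesion mean), `voxel_sd`
#'   (within-lesion SD), `skewness`, `skewness_sd`, `kurtosis`, `kurtosis_sd`.
#' @param grid_dim Map grid dimensions (voxels).
#' @param spacing Voxel spacing `(dx, dy, dz)` in mm.
#' @param semi_axes Ellipsoid lesion semi-axes in voxels.
#' @param background ADC level and SD of non-lesion voxels (1e-5 mm^2/s);
#'   fluid-like by default so mask errors are conspicuous.
#' @param copula_rank_corr Joint Spearman matrix over ADC summaries and
#'   markers; see [default_copula_matrix()].
#' @param dwi List with `S0`, `b_values` (s/mm^2, must contain 0) and
#'   `noise_sigma` (Rician scale; 0 = deterministic).
#' @param seed Integer seed recorded in outputs and used by
#'   [simulate_cohort()].
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_patients = 15,
                             group_fractions = c("N0" = 1 / 3, "N1/2" = 2 / 3),
                             group_targets = NULL,
                             grid_dim = c(48, 48, 24),
                             spacing = c(1, 1, 4),
                             semi_axes = c(8, 7, 5),
                             background = list(adc = 300, sd = 5),
                             copula_rank_corr = default_copula_matrix(),
                             dwi = list(S0 = 1000, b_values = c(0, 400, 800),
                                        noise_sigma = 0),
                             seed = 1L) {
  group_targets <- group_targets %||% tibble(
    group = c("N0", "N1/2"),
    adc_mean = c(125.25, 111.41),
    adc_mean_sd = c(34.1, 25.0),
    voxel_sd = c(35, 35),
    skewness = c(-0.12, 0.41),
    skewness_sd = c(0.64, 0.21),
    kurtosis = c(3.23, 3.81),
    kurtosis_sd = c(0.29, 0.57)
  )
  if (abs(sum(group_fractions) - 1) > 1e-8) {
    abort("group_fractions must sum to 1", class = "adchist_bad_config")
  }
  if (!setequal(names(group_fractions), group_targets$group)) {
    abort("group_fractions names must match group_targets$group",
          class = "adchist_bad_config")
  }
  infeasible <- group_targets$kurtosis < group_targets$skewness^2 + 1
  if (any(infeasible)) {
    abort(sprintf("group target(s) %s violate kurtosis >= skewness^2 + 1",
                  paste(group_targets$group[infeasible], collapse = ", ")),
          class = "adchist_infeasible_moments")
  }
  validate_copula_matrix(copula_rank_corr)
  if (!0 %in% dwi$b_values) {
    abort("dwi b_values must contain 0", class = "adchist_bad_config")
  }
  if (any(2 * semi_axes + 1 > grid_dim)) {
    abort("lesion ellipsoid does not fit inside the map grid",
          class = "adchist_bad_config")
  }
  structure(list(
    n_patients = as.integer(n_patients),
    group_fractions = group_fractions,
    group_targets = group_targets,
    grid_dim = as.integer(grid_dim),
    spacing = as.numeric(spacing),
    semi_axes = as.numeric(semi_axes),
    background = background,
    copula_rank_corr = copula_rank_corr,
    dwi = dwi,
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

#' Draw a voxel-value sample with prescribed first four moments
#'
#' Samples standard normals, applies the Fleishman cubic transform matching
#' the target skewness and kurtosis, scales to `(mean, sd)`, and clips at zero
#' (ADC values are non-negative). The number of clipped voxels is attached as
#' attribute `n_clipped`.
#'
#' @param n Number of voxels.
#' @param mean,sd Target location and scale (1e-5 mm^2/s). `sd = 0` gives a
#'   constant sample.
#' @param skewness,kurtosis Target shape moments (kurtosis non-excess).
#' @return Numeric vector of length `n`, draws from the caller's RNG stream.
#' @export
generate_voxel_sample <- function(n, mean, sd, skewness = 0, kurtosis = 3) {
  if (sd == 0) {
    return(structure(rep(mean, n), n_clipped = 0L))
  }
  coef <- solve_fleishman(skewness, kurtosis)
  y <- fleishman_transform(rnorm(n), coef)
  v <- mean + sd * y
  n_clipped <- sum(v < 0)
  v[v < 0] <- 0
  structure(v, n_clipped = n_clipped)
}

ellipsoid_mask_array <- function(grid_dim, semi_axes,
                                 center = (grid_dim + 1) / 2) {
  cx <- (seq_len(grid_dim[1]) - center[1]) / semi_axes[1]
  cy <- (seq_len(grid_dim[2]) - center[2]) / semi_axes[2]
  cz <- (seq_len(grid_dim[3]) - center[3]) / semi_axes[3]
  r2 <- outer(outer(cx^2, cy^2, `+`), cz^2, `+`)
  array(as.integer(r2 <= 1), dim = grid_dim)
}

#' Generate one synthetic lesion: ADC map plus mask
#'
#' The mask is a discretized ellipsoid centered in the grid; in-mask voxels
#' follow the group's target voxel distribution (via the Fleishman transform),
#' out-of-mask voxels hold a distinct fluid-like background. Explicit
#' per-patient `targets` (named list/row with `adc_mean`, `voxel_sd`,
#' `skewness`, `kurtosis`) override the group's means, which is how
#' between-patient variability enters in [simulate_cohort()].
#'
#' @param cfg A [synthetic_config()].
#' @param group Group label present in `cfg$group_targets$group`.
#' @param targets Optional per-patient moment targets.
#' @return List with `map` ([adc_map()]) and `mask` ([lesion_mask()]); the
#'   map carries attribute `n_clipped`. Uses the caller's RNG stream.
#' @export
generate_lesion <- function(cfg, group, targets = NULL) {
  stopifnot(inherits(cfg, "synthetic_config"))
  gt <- cfg$group_targets[cfg$group_targets$group == group, ]
  if (nrow(gt) != 1) {
    abort(sprintf("unknown group '%s'", group), class = "adchist_bad_argument")
  }
  tg <- list(
    adc_mean = targets$adc_mean %||% gt$adc_mean,
    voxel_sd = targets$voxel_sd %||% gt$voxel_sd,
    skewness = targets$skewness %||% gt$skewness,
    kurtosis = targets$kurtosis %||% gt$kurtosis
  )
  mask_arr <- ellipsoid_mask_array(cfg$grid_dim, cfg$semi_axes)
  n_in <- sum(mask_arr)
  if (n_in == 0) {
    abort("lesion mask is empty after discretization",
          class = "adchist_empty_mask")
  }
  n_slices <- sum(apply(mask_arr, 3, sum) > 0)
  if (n_slices < 2) {
    abort("lesion must span at least 2 slices", class = "adchist_bad_config")
  }
  vals <- array(rnorm(prod(cfg$grid_dim), cfg$background$adc, cfg$background$sd),
                dim = cfg$grid_dim)
  vals[vals < 0] <- 0
  lesion <- generate_voxel_sample(n_in, tg$adc_mean, tg$voxel_sd,
                                  tg$skewness, tg$kurtosis)
  vals[mask_arr == 1] <- lesion
  map <- adc_map(vals, spacing = cfg$spacing)
  attr(map, "n_clipped") <- attr(lesion, "n_clipped")
  list(map = map, mask = lesion_mask(mask_arr, spacing = cfg$spacing))
}

#' Generate rank-correlated histopathology markers for a cohort
#'
#' Gaussian-copula draw of the marker block (cell count, Ki-67 %, p53 %,
#' total/average nuclear area) conditional on the observed lesion ADC
#' summaries: the summaries' midrank normal scores act as the latent Gaussian
#' coordinates, the marker latents are drawn from the conditional multivariate
#' normal implied by `cfg$copula_rank_corr` (Spearman targets converted to the
#' latent Pearson scale), and marker values come from fixed marginal quantile
#' functions spanning plausible clinical ranges. Empirical Spearman
#' correlations between markers and summaries converge to the configured
#' matrix as the cohort grows.
#'
#' @param cfg A [synthetic_config()].
#' @param lesion_summaries Tibble with the ADC summary columns named in the
#'   copula matrix (default `adc_mean`, `adc_max`, `kurtosis`), one row per
#'   patient.
#' @return Tibble of marker columns, one row per patient. Uses the caller's
#'   RNG stream.
#' @export
generate_histopath <- function(cfg, lesion_summaries) {
  stopifnot(inherits(cfg, "synthetic_config"))
  S <- cfg$copula_rank_corr
  validate_copula_matrix(S)
  snames <- intersect(rownames(S), names(lesion_summaries))
  mnames <- setdiff(rownames(S), snames)
  if (length(snames) == 0 || length(mnames) == 0) {
    abort("copula matrix names must split into summary columns present in lesion_summaries and marker names",
          class = "adchist_bad_config")
  }
  n <- nrow(lesion_summaries)
  P <- spearman_to_pearson(S)
  diag(P) <- 1
  PA <- P[snames, snames, drop = FALSE]
  B <- P[mnames, snames, drop = FALSE]
  PM <- P[mnames, mnames, drop = FALSE]
  zA <- vapply(snames, function(s) {
    qnorm((rank(lesion_summaries[[s]]) - 0.5) / n)
  }, numeric(n))
  zA <- matrix(zA, nrow = n)
  coefs <- B %*% solve(PA)
  cond_cov <- PM - coefs %*% t(B)
  ev <- eigen((cond_cov + t(cond_cov)) / 2, symmetric = TRUE)
  if (min(ev$values) < -1e-8) {
    abort("conditional marker covariance is not positive semi-definite; copula targets are jointly infeasible",
          class = "adchist_copula_not_psd")
  }
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), length(ev$values))
  eps <- matrix(rnorm(n * length(mnames)), nrow = length(mnames))
  zM <- zA %*% t(coefs) + t(L %*% eps)
  # conditional latents have the marginal variances of PM's diagonal (1)
  u <- pnorm(zM)
  qf <- marker_quantile_funs()
  out <- purrr::imap(setNames(seq_along(mnames), mnames), function(j, nm) {
    if (!nm %in% names(qf)) {
      abort(sprintf("no marginal defined for marker '%s'", nm),
            class = "adchist_bad_config")
    }
    qf[[nm]](u[, j])
  })
  as_tibble(out)
}

#' Simulate a diffusion-weighted signal stack from an ADC map
#'
#' Per-voxel mono-exponential decay `S(b) = S0 * exp(-b * ADC * 1e-5)` (the
#' unit bridge between b in s/mm^2 and ADC in 1e-5 mm^2/s), plus Rician noise
#' of scale `noise_sigma` — the magnitude-MRI noise model,
#' `sqrt((S + sigma*e1)^2 + (sigma*e2)^2)` with independent standard normal
#' `e1`, `e2`. `noise_sigma = 0` gives the exact decay.
#'
#' @param map An [adc_map()] (values in 1e-5 mm^2/s).
#' @param S0 Signal at `b = 0` (must be positive).
#' @param b_values b-values in s/mm^2.
#' @param noise_sigma Rician noise scale (>= 0).
#' @return 4D array `dim(map) x length(b_values)`. Uses the caller's RNG
#'   stream when `noise_sigma > 0`.
#' @export
generate_dwi <- function(map, S0 = 1000, b_values = c(0, 400, 800),
                         noise_sigma = 0) {
  stopifnot(inherits(map, "adc_map"))
  if (S0 <= 0) abort("S0 must be positive", class = "adchist_bad_argument")
  if (noise_sigma < 0) abort("noise_sigma must be >= 0",
                             class = "adchist_bad_argument")
  d <- dim(map$values)
  out <- array(0, dim = c(d, length(b_values)))
  nv <- prod(d)
  for (k in seq_along(b_values)) {
    s <- S0 * exp(-b_values[k] * map$values * 1e-5)
    if (noise_sigma > 0) {
      s <- sqrt((s + noise_sigma * rnorm(nv))^2 + (noise_sigma * rnorm(nv))^2)
    }
    out[, , , k] <- s
  }
  out
}

draw_patient_targets <- function(gt) {
  skew <- rnorm(1, gt$skewness, gt$skewness_sd)
  kurt <- rnorm(1, gt$kurtosis, gt$kurtosis_sd)
  kmin <- max(fleishman_min_kurtosis(skew), skew^2 + 1) + 0.2
  list(
    adc_mean = max(rnorm(1, gt$adc_mean, gt$adc_mean_sd), 3 * gt$voxel_sd / 10),
    voxel_sd = gt$voxel_sd,
    skewness = skew,
    kurtosis = max(kurt, kmin)
  )
}

#' Simulate a complete synthetic cohort
#'
#' Seeded end-to-end generation: assigns patients to nodal groups by the
#' configured fractions, draws per-patient distribution targets around the
#' group-level moments, builds one ADC map + lesion mask per patient, extracts
#' whole-lesion histogram features, draws rank-correlated histopathology
#' markers conditional on the lesion summaries, and fills in demographics.
#' Identical config + seed gives an identical cohort.
#'
#' @param cfg A [synthetic_config()].
#' @param seed Seed (defaults to `cfg$seed`).
#' @param keep_images Keep the per-patient maps/masks in the result (set
#'   `FALSE` to save memory when only the tables matter).
#' @param dwi Also simulate a DWI stack per patient using `cfg$dwi`.
#' @return List of class `synthetic_cohort`: `cohort` (patient table incl.
#'   markers), `features` (per-patient histogram features), `maps`, `masks`,
#'   optionally `dwi`, plus `config` and `seed`.
#' @export
simulate_cohort <- function(cfg = synthetic_config(), seed = cfg$seed,
                            keep_images = TRUE, dwi = FALSE) {
  stopifnot(inherits(cfg, "synthetic_config"))
  withr::with_seed(as.integer(seed), {
    n <- cfg$n_patients
    counts <- round(cfg$group_fractions * n)
    counts[length(counts)] <- n - sum(counts[-length(counts)])
    groups <- rep(names(counts), counts)
    ids <- sprintf("P%03d", seq_len(n))
    maps <- vector("list", n)
    masks <- vector("list", n)
    dwis <- if (dwi) vector("list", n) else NULL
    feats <- vector("list", n)
    demo <- vector("list", n)
    for (i in seq_len(n)) {
      gt <- cfg$group_targets[cfg$group_targets$group == groups[i], ]
      tg <- draw_patient_targets(gt)
      les <- generate_lesion(cfg, groups[i], targets = tg)
      feats[[i]] <- compute_features(extract_voi_values(les$map, les$mask))
      if (dwi) {
        dwis[[i]] <- generate_dwi(les$map, S0 = cfg$dwi$S0,
                                  b_values = cfg$dwi$b_values,
                                  noise_sigma = cfg$dwi$noise_sigma)
      }
      maps[[i]] <- les$map
      masks[[i]] <- les$mask
      n_stage <- if (groups[i] == "N0") 0L else sample(c(1L, 2L), 1, prob = c(0.9, 0.1))
      advanced <- runif(1) < 0.25
      sites <- if (runif(1) < 0.9) "trachea" else character(0)
      if (advanced) {
        sites <- union(sites, sample(c("esophagus", "internal jugular vein"),
                                     sample(1:2, 1)))
      }
      demo[[i]] <- tibble(
        patient_id = ids[i],
        age = pmin(pmax(round(rnorm(1, 67, 12.9)), 18), 95),
        sex = if (runif(1) < 14 / 15) "female" else "male",
        subtype = sample(valid_subtypes, 1, prob = c(5, 3, 7)),
        infiltration_sites = list(sites),
        m_stage = rbinom(1, 1, 1 / 15),
        n_stage = n_stage,
        group = groups[i]
      )
    }
    features <- purrr::list_rbind(feats)
    features$patient_id <- ids
    features <- dplyr::relocate(features, "patient_id")
    markers <- generate_histopath(cfg, features)
    cohort <- dplyr::bind_cols(purrr::list_rbind(demo), markers)
    out <- list(
      cohort = cohort,
      features = features,
      maps = if (keep_images) setNames(maps, ids) else NULL,
      masks = if (keep_images) setNames(masks, ids) else NULL,
      dwi = if (dwi) setNames(dwis, ids) else NULL,
      config = cfg,
      seed = as.integer(seed)
    )
    class(out) <- "synthetic_cohort"
    out
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d patients (seed %d): %s\n",
              nrow(x$cohort), x$seed,
              paste(sprintf("%s n=%d", names(table(x$cohort$group)),
                            table(x$cohort$group)), collapse = ", ")))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' One NIfTI ADC map and mask per patient (optionally the 4D DWI stack), the
#' cohort CSV, and a JSON manifest recording the seed.
#'
#' @param x A [simulate_cohort()] result with images kept.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_cohort <- function(x, dir) {
  stopifnot(inherits(x, "synthetic_cohort"))
  if (is.null(x$maps)) {
    abort("cohort was simulated with keep_images = FALSE; nothing to write",
          class = "adchist_bad_argument")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(x$maps)) {
    write_nifti_volume(x$maps[[id]], file.path(dir, paste0(id, "_adc.nii.gz")))
    write_nifti_volume(x$masks[[id]], file.path(dir, paste0(id, "_mask.nii.gz")))
    if (!is.null(x$dwi)) {
      write_nifti_volume(x$dwi[[id]], file.path(dir, paste0(id, "_dwi.nii.gz")),
                         spacing = x$config$spacing)
    }
  }
  write_cohort_table(x$cohort, file.path(dir, "cohort.csv"))
  jsonlite::write_json(
    list(seed = x$seed, n_patients = x$config$n_patients,
         package_version = as.character(utils::packageVersion("adchist"))),
    file.path(dir, "manifest.json"), auto_unbox = TRUE
  )
  invisible(dir)
}
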