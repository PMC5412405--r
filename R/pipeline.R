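#' Demographic summary of a cohort table
#'
#' @param cohort Cohort tibble from [read_cohort_table()] or
#'   [simulate_cohort()].
#' @return One-row tibble: `n`, `mean_age`, `sd_age`, `n_female`, `n_male`,
#'   `n_nodal_negative`, `n_nodal_positive`.
#' @export
summarize_demographics <- function(cohort) {
  tibble(
    n = nrow(cohort),
    mean_age = mean(cohort$age),
    sd_age = sd(cohort$age),
    n_female = sum(cohort$sex == "female"),
    n_male = sum(cohort$sex == "male"),
    n_nodal_negative = sum(cohort$n_stage == 0),
    n_nodal_positive = sum(cohort$n_stage >= 1)
  )
}

#' Pipeline run configuration
#'
#' @param mode `"synthetic"` (generate the cohort from `synthetic`) or
#'   `"real"` (read maps/masks/cohort from the given paths).
#' @param maps_dir,masks_dir Directories of per-patient NIfTI files, matched
#'   by filename stem (a map `<stem>_adc.nii.gz` or `<stem>.nii.gz` pairs with
#'   the mask sharing `<stem>`). `NULL` in real mode runs the cohort-table-only
#'   analysis (demographics + marker summaries).
#' @param cohort_csv Cohort table path (real mode).
#' @param out_dir Output directory for the table bundle; `NULL` returns tables
#'   without writing.
#' @param bin_count,percentiles Feature options, see [compute_features()].
#' @param grouping,gate_alpha,test_override Statistics options, see
#'   [compare_groups()].
#' @param units_hint Stored unit of input ADC maps, see [read_adc_map()].
#' @param synthetic A [synthetic_config()] (synthetic mode).
#' @param seed Seed for synthetic mode (defaults to the synthetic config's).
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(mode = c("synthetic", "real"),
                       maps_dir = NULL, masks_dir = NULL, cohort_csv = NULL,
                       out_dir = NULL, bin_count = 64,
                       percentiles = c("matlab", "type7"),
                       grouping = c("nodal_status", "infiltration"),
                       gate_alpha = 0.05, test_override = NULL,
                       units_hint = c("e-5", "e-3"),
                       synthetic = synthetic_config(), seed = NULL) {
  mode <- match.arg(mode)
  percentiles <- match.arg(percentiles)
  grouping <- match.arg(grouping)
  units_hint <- match.arg(units_hint)
  if (mode == "real") {
    if (is.null(cohort_csv)) {
      abort("real mode requires cohort_csv", class = "adchist_bad_config")
    }
    if (!file.exists(cohort_csv)) {
      abort(sprintf("cohort table not found: %s", cohort_csv),
            class = "adchist_bad_config")
    }
    for (d in c(maps_dir, masks_dir)) {
      if (!is.null(d) && !dir.exists(d)) {
        abort(sprintf("directory not found: %s", d),
              class = "adchist_bad_config")
      }
    }
    if (xor(is.null(maps_dir), is.null(masks_dir))) {
      abort("maps_dir and masks_dir must be given together",
            class = "adchist_bad_config")
    }
  }
  structure(list(
    mode = mode, maps_dir = maps_dir, masks_dir = masks_dir,
    cohort_csv = cohort_csv, out_dir = out_dir,
    bin_count = bin_count, percentiles = percentiles,
    grouping = grouping, gate_alpha = gate_alpha,
    test_override = test_override, units_hint = units_hint,
    synthetic = synthetic, seed = seed %||% synthetic$seed
  ), class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [run_config()]; a `synthetic`
#' section (if present) overrides [synthetic_config()] defaults field by
#' field.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  syn_args <- y$synthetic %||% list()
  if (!is.null(syn_args$group_targets)) {
    syn_args$group_targets <- as_tibble(syn_args$group_targets)
  }
  syn <- do.call(synthetic_config, syn_args)
  args <- y[setdiff(names(y), "synthetic")]
  args$synthetic <- syn
  do.call(run_config, args)
}

file_stem <- function(path) {
  s <- sub("\\.nii(\\.gz)?$", "", basename(path))
  sub("_(adc|map)$", "", s)
}

match_map_mask_files <- function(maps_dir, masks_dir) {
  maps <- list.files(maps_dir, pattern = "\\.nii(\\.gz)?$", full.names = TRUE)
  masks <- list.files(masks_dir, pattern = "\\.nii(\\.gz)?$", full.names = TRUE)
  masks <- masks[!(masks %in% maps & grepl("_mask", masks) == FALSE)]
  mask_stems <- sub("_(mask|seg)$", "", vapply(masks, file_stem, character(1),
                                               USE.NAMES = FALSE))
  map_stems <- vapply(maps, file_stem, character(1), USE.NAMES = FALSE)
  keep <- map_stems %in% mask_stems & !grepl("_(mask|seg)\\.nii", maps)
  tibble(
    patient_id = map_stems[keep],
    map = maps[keep],
    mask = masks[match(map_stems[keep], mask_stems)]
  )
}

feature_table_cols <- c("adc_mean", "adc_min", "adc_max", "p10", "p25",
                        "p75", "p90", "adc_median", "adc_mode",
                        "kurtosis", "skewness", "entropy")

#' Run the full analysis pipeline
#'
#' Synthesizes or ingests a cohort, extracts whole-lesion histogram features,
#' runs the correlation and group-comparison statistics, and (optionally)
#' writes the four cohort tables plus a manifest and log: `table1` feature
#' summaries (median / range / min / max), `table2` marker summaries,
#' `table3` feature-marker Spearman correlations, `table4` Levene-gated group
#' comparison. Identical config + seed produces a byte-identical bundle.
#' Per-patient failures are logged and the patient excluded; more than 50%
#' exclusions aborts the run.
#'
#' @param cfg A [run_config()].
#' @return List of class `adc_run`: `demographics`, `features`, `cohort`,
#'   `table1` .. `table4` (those that apply), `excluded`, `manifest`, `log`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  log_lines <- character(0)
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    inform(line)
  }
  excluded <- tibble(patient_id = character(0), reason = character(0))

  if (cfg$mode == "synthetic") {
    say("synthetic mode: simulating cohort (n = %d, seed = %d)",
        cfg$synthetic$n_patients, cfg$seed)
    sim <- simulate_cohort(cfg$synthetic, seed = cfg$seed, keep_images = FALSE)
    cohort <- sim$cohort
    features <- sim$features
  } else {
    cohort <- read_cohort_table(cfg$cohort_csv)
    say("read cohort table: %d patients", nrow(cohort))
    features <- NULL
    if (!is.null(cfg$maps_dir)) {
      pairs <- match_map_mask_files(cfg$maps_dir, cfg$masks_dir)
      if (nrow(pairs) == 0) {
        abort("no map/mask pairs found by filename stem",
              class = "adchist_bad_config")
      }
      rows <- list()
      for (i in seq_len(nrow(pairs))) {
        res <- tryCatch({
          map <- read_adc_map(pairs$map[i], units_hint = cfg$units_hint)
          mask <- read_mask(pairs$mask[i], reference = map)
          compute_features(extract_voi_values(map, mask),
                           bin_count = cfg$bin_count,
                           percentiles = cfg$percentiles)
        }, error = function(e) e)
        if (inherits(res, "error")) {
          say("excluding %s: %s", pairs$patient_id[i], conditionMessage(res))
          excluded <- dplyr::bind_rows(excluded, tibble(
            patient_id = pairs$patient_id[i], reason = conditionMessage(res)))
        } else {
          rows[[pairs$patient_id[i]]] <- res
        }
      }
      if (nrow(excluded) > nrow(pairs) / 2) {
        abort(sprintf("%d of %d patients failed feature extraction; aborting",
                      nrow(excluded), nrow(pairs)),
              class = "adchist_partial_failure")
      }
      features <- purrr::list_rbind(rows) |>
        dplyr::mutate(patient_id = names(rows), .before = 1)
    }
  }

  demographics <- summarize_demographics(cohort)
  out <- list(demographics = demographics, cohort = cohort,
              features = features, excluded = excluded)

  markers_present <- intersect(marker_names, names(cohort))
  if (length(markers_present) > 0) {
    out$table2 <- purrr::map(markers_present, function(m) {
      dplyr::mutate(summarize_cohort(cohort[[m]]), parameter = m, .before = 1)
    }) |> purrr::list_rbind()
  }

  if (!is.null(features)) {
    fcols <- intersect(feature_table_cols, names(features))
    out$table1 <- purrr::map(fcols, function(f) {
      dplyr::mutate(summarize_cohort(features[[f]]), parameter = f, .before = 1)
    }) |> purrr::list_rbind()
    if (length(markers_present) > 0) {
      out$table3 <- correlate_markers(features, cohort)
    }
    out$table4 <- compare_groups(features, cohort, grouping = cfg$grouping,
                                 gate_alpha = cfg$gate_alpha,
                                 test_override = cfg$test_override)
    say("group comparison (%s): %d/%d features significant at p <= 0.05",
        cfg$grouping, sum(out$table4$significant), nrow(out$table4))
  } else {
    say("no imaging inputs: cohort-table-only analysis (demographics%s)",
        if (length(markers_present) > 0) " + marker summaries" else "")
  }

  manifest <- list(
    config_hash = rlang::hash(cfg[setdiff(names(cfg), "out_dir")]),
    seed = cfg$seed,
    mode = cfg$mode,
    n_patients = nrow(cohort),
    n_excluded = nrow(excluded),
    package_version = as.character(utils::packageVersion("adchist"))
  )
  out$manifest <- manifest
  out$log <- log_lines

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(tbl, name) {
      if (!is.null(tbl)) {
        readr::write_csv(as_tibble(tbl), file.path(cfg$out_dir, name),
                         progress = FALSE)
      }
    }
    wr(out$demographics, "demographics.csv")
    wr(out$table1, "table1_feature_summaries.csv")
    wr(out$table2, "table2_marker_summaries.csv")
    wr(out$table3, "table3_correlations.csv")
    wr(out$table4, "table4_group_comparison.csv")
    if (!is.null(out$features)) wr(out$features, "features.csv")
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    writeLines(log_lines, file.path(cfg$out_dir, "run.log"))
  }
  class(out) <- "adc_run"
  out
}

#' @export
print.adc_run <- function(x, ...) {
  cat(sprintf("<adc_run> %d patients (%d excluded)\n",
              x$manifest$n_patients, x$manifest$n_excluded))
  if (!is.null(x$table4)) {
    sig <- x$table4$feature[x$table4$significant]
    cat(sprintf("  significant group differences: %s\n",
                if (length(sig)) paste(sig, collapse = ", ") else "none"))
  }
  invisible(x)
}

#' @export
glance.adc_run <- function(x, ...) {
  tibble(
    n_patients = x$manifest$n_patients,
    n_excluded = x$manifest$n_excluded,
    mean_age = x$demographics$mean_age,
    n_nodal_negative = x$demographics$n_nodal_negative,
    n_nodal_positive = x$demographics$n_nodal_positive,
    n_significant_comparisons = if (!is.null(x$table4)) sum(x$table4$significant) else NA_integer_,
    seed = x$manifest$seed
  )
}
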