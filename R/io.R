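#' ADC map and lesion mask containers
#'
#' An `adc_map` wraps a 3D array of apparent diffusion coefficient values in
#' the canonical unit of this package, 1e-5 mm^2/s, together with the voxel
#' spacing in mm. A `lesion_mask` is the binary volume-of-interest on the same
#' grid. Both are plain arrays plus metadata; all geometry comes from the
#' stored spacing.
#'
#' @param values 3D numeric array (ADC in 1e-5 mm^2/s, or any nonzero value
#'   for a mask).
#' @param spacing Numeric length-3 voxel spacing `(dx, dy, dz)` in mm.
#' @return An object of class `adc_map` or `lesion_mask`.
#' @export
adc_map <- function(values, spacing = c(1, 1, 1)) {
  values <- unclass(values)
  attributes(values) <- attributes(values)["dim"]
  if (length(dim(values)) != 3) {
    abort("ADC map must be a 3D array", class = "adchist_bad_volume")
  }
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values))
    abort(sprintf("ADC map contains %d non-finite voxels (first indices: %s)",
                  length(bad), paste(utils::head(bad, 5), collapse = ", ")),
          class = "adchist_bad_volume")
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0)) {
    abort("voxel spacing must be 3 strictly positive numbers (mm)",
          class = "adchist_bad_volume")
  }
  structure(list(values = values, spacing = spacing), class = "adc_map")
}

#' @rdname adc_map
#' @export
lesion_mask <- function(values, spacing = c(1, 1, 1)) {
  values <- unclass(values)
  attributes(values) <- attributes(values)["dim"]
  if (length(dim(values)) != 3) {
    abort("lesion mask must be a 3D array", class = "adchist_bad_volume")
  }
  vals <- array(as.integer(values != 0), dim = dim(values))
  structure(list(values = vals, spacing = as.numeric(spacing)),
            class = "lesion_mask")
}

#' @export
print.adc_map <- function(x, ...) {
  cat(sprintf("<adc_map> %s voxels, spacing %s mm, range [%.1f, %.1f] x1e-5 mm^2/s\n",
              paste(dim(x$values), collapse = "x"),
              paste(signif(x$spacing, 3), collapse = "x"),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
print.lesion_mask <- function(x, ...) {
  cat(sprintf("<lesion_mask> %s voxels, %d in VOI\n",
              paste(dim(x$values), collapse = "x"), sum(x$values)))
  invisible(x)
}

voxel_volume_mm3 <- function(x) prod(x$spacing)

#' Read an ADC map from a NIfTI file
#'
#' Values are converted to the canonical 1e-5 mm^2/s scale: maps stored in the
#' common 1e-3 mm^2/s convention are multiplied by 100 (the conversion is
#' reported via a message).
#'
#' @param path Path to a 3D NIfTI volume.
#' @param units_hint Unit the file is stored in: `"e-5"` (default, canonical)
#'   or `"e-3"`.
#' @return An [adc_map()].
#' @export
read_adc_map <- function(path, units_hint = c("e-5", "e-3")) {
  units_hint <- match.arg(units_hint)
  if (!file.exists(path)) {
    abort(sprintf("no such file: %s", path), class = "adchist_io_error")
  }
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3) {
    abort(sprintf("expected a 3D volume, got %dD (%s): %s",
                  length(d), paste(d, collapse = "x"), path),
          class = "adchist_bad_volume")
  }
  vals <- as.array(img)
  if (units_hint == "e-3") {
    vals <- vals * 100
    inform(sprintf("converted %s from 1e-3 to canonical 1e-5 mm^2/s (x100)",
                   basename(path)))
  }
  adc_map(vals, spacing = RNifti::pixdim(img)[seq_len(3)])
}

#' Write an ADC map, mask or DWI stack to NIfTI
#'
#' @param x An [adc_map()], [lesion_mask()] or 4D DWI array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param spacing Voxel spacing, only for bare arrays.
#' @return `path`, invisibly.
#' @export
write_nifti_volume <- function(x, path, spacing = NULL) {
  if (inherits(x, c("adc_map", "lesion_mask"))) {
    vals <- x$values
    spacing <- x$spacing
  } else {
    vals <- x
    spacing <- spacing %||% rep(1, min(length(dim(vals)), 3))
  }
  img <- RNifti::asNifti(vals)
  RNifti::pixdim(img) <- c(spacing, rep(1, length(dim(vals)) - 3))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a lesion mask and check it against its reference ADC map
#'
#' Any nonzero stored value becomes 1. The mask must live on the same grid as
#' the reference map (same array shape; spacing equal to within 1e-3 mm).
#'
#' @param path Path to the mask NIfTI.
#' @param reference The [adc_map()] the mask belongs to.
#' @return A [lesion_mask()].
#' @export
read_mask <- function(path, reference) {
  stopifnot(inherits(reference, "adc_map"))
  if (!file.exists(path)) {
    abort(sprintf("no such file: %s", path), class = "adchist_io_error")
  }
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (!identical(as.integer(d), as.integer(dim(reference$values)))) {
    abort(sprintf("mask grid %s does not match reference grid %s",
                  paste(d, collapse = "x"),
                  paste(dim(reference$values), collapse = "x")),
          class = "adchist_grid_mismatch")
  }
  sp <- RNifti::pixdim(img)[seq_len(3)]
  if (max(abs(sp - reference$spacing)) > 1e-3) {
    abort(sprintf("mask spacing (%s) differs from reference (%s) by more than 1e-3 mm",
                  paste(signif(sp, 6), collapse = "x"),
                  paste(signif(reference$spacing, 6), collapse = "x")),
          class = "adchist_grid_mismatch")
  }
  m <- lesion_mask(as.array(img), spacing = reference$spacing)
  if (sum(m$values) == 0) {
    abort(sprintf("mask is empty: %s", path), class = "adchist_empty_mask")
  }
  m
}

known_infiltration_sites <- c("trachea", "esophagus", "internal jugular vein")

#' Parse free-text infiltration descriptions into site sets
#'
#' Recognizes `trachea`, `esophagus` and `internal jugular vein` anywhere in
#' the text (case-insensitive, arbitrary separators); `none`, an empty string
#' or `NA` give an empty set.
#'
#' @param x Character vector of infiltration descriptions.
#' @return A list of character vectors (one site set per element).
#' @export
parse_infiltration_sites <- function(x) {
  lapply(tolower(as.character(x)), function(s) {
    if (is.na(s) || !nzchar(trimws(s)) || grepl("\\bnone\\b", s)) {
      return(character(0))
    }
    known_infiltration_sites[vapply(known_infiltration_sites,
                                    function(site) grepl(site, s, fixed = TRUE),
                                    logical(1))]
  })
}

normalize_header <- function(x) {
  x <- tolower(trimws(x))
  gsub("[^a-z0-9]+", "_", x)
}

cohort_column_aliases <- c(
  case = "patient_id", patient_id = "patient_id", id = "patient_id",
  age = "age",
  gender = "sex", sex = "sex",
  histological_subtype = "subtype", subtype = "subtype",
  infiltration_pattern = "infiltration", infiltration = "infiltration",
  infiltration_sites = "infiltration",
  m_stage = "m_stage", n_stage = "n_stage",
  cell_count = "cell_count", ki67_pct = "ki67_pct", ki_67 = "ki67_pct",
  p53_pct = "p53_pct", p53 = "p53_pct",
  total_nuclear_area = "total_nuclear_area",
  average_nuclear_area = "average_nuclear_area"
)

valid_subtypes <- c("papillary", "follicular", "anaplastic")

#' Read a cohort clinical/histopathology table
#'
#' Reads a CSV with one row per patient, matching columns case-insensitively:
#' patient id, age (years), sex, histological subtype, infiltration pattern
#' (free text, parsed into a site set), M stage and N stage; optional
#' immunohistopathology columns (cell count per 5 HPF, Ki-67 %, p53 %, total
#' and average nuclear area in um^2) are carried through when present. All
#' row-level validation failures are collected and reported together.
#'
#' @param path Path to the cohort CSV (UTF-8, comma separated, header row).
#' @return A tibble with one row per patient; `infiltration_sites` is a
#'   list-column of site sets.
#' @export
read_cohort_table <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("no such file: %s", path), class = "adchist_io_error")
  }
  raw <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
    error = function(e) abort(sprintf("failed to read cohort table %s: %s",
                                      path, conditionMessage(e)),
                              class = "adchist_io_error")
  )
  if (nrow(raw) == 0 || ncol(raw) == 0) {
    abort(sprintf("cohort table is empty: %s", path),
          class = "adchist_io_error")
  }
  names(raw) <- normalize_header(names(raw))
  known <- intersect(names(raw), names(cohort_column_aliases))
  raw <- raw[known]
  names(raw) <- unname(cohort_column_aliases[known])
  required <- c("patient_id", "age", "sex", "subtype", "infiltration",
                "m_stage", "n_stage")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    abort(sprintf("cohort table %s lacks required columns: %s",
                  path, paste(missing, collapse = ", ")),
          class = "adchist_io_error")
  }
  tbl <- as_tibble(raw)
  tbl$patient_id <- as.character(tbl$patient_id)
  tbl$sex <- tolower(as.character(tbl$sex))
  tbl$subtype <- tolower(trimws(as.character(tbl$subtype)))
  tbl$infiltration_sites <- parse_infiltration_sites(tbl$infiltration)
  tbl$infiltration <- NULL
  tbl$m_stage <- as.integer(tbl$m_stage)
  tbl$n_stage <- as.integer(tbl$n_stage)

  errs <- character(0)
  row_err <- function(i, msg) sprintf("row %d (%s): %s", i, tbl$patient_id[i], msg)
  for (i in seq_len(nrow(tbl))) {
    if (!tbl$subtype[i] %in% valid_subtypes) {
      errs <- c(errs, row_err(i, sprintf("unknown subtype '%s'", tbl$subtype[i])))
    }
    if (is.na(tbl$n_stage[i]) || !tbl$n_stage[i] %in% 0:2) {
      errs <- c(errs, row_err(i, sprintf("n_stage %s outside {0,1,2}", tbl$n_stage[i])))
    }
    if (is.na(tbl$m_stage[i]) || !tbl$m_stage[i] %in% 0:1) {
      errs <- c(errs, row_err(i, sprintf("m_stage %s outside {0,1}", tbl$m_stage[i])))
    }
    if (is.na(tbl$age[i]) || tbl$age[i] < 0) {
      errs <- c(errs, row_err(i, "age missing or negative"))
    }
  }
  for (pct in intersect(c("ki67_pct", "p53_pct"), names(tbl))) {
    bad <- which(!is.na(tbl[[pct]]) & (tbl[[pct]] < 0 | tbl[[pct]] > 100))
    for (i in bad) errs <- c(errs, row_err(i, sprintf("%s outside [0, 100]", pct)))
  }
  for (nn in intersect(c("cell_count", "total_nuclear_area", "average_nuclear_area"),
                       names(tbl))) {
    bad <- which(!is.na(tbl[[nn]]) & tbl[[nn]] < 0)
    for (i in bad) errs <- c(errs, row_err(i, sprintf("%s negative", nn)))
  }
  if (length(errs) > 0) {
    abort(paste0("invalid cohort table:\n", paste("-", errs, collapse = "\n")),
          class = "adchist_invalid_cohort")
  }
  tbl
}

#' Write a cohort table to CSV
#'
#' The inverse of [read_cohort_table()]: the `infiltration_sites` list-column
#' is flattened back to comma-separated text (empty set -> `"none"`).
#'
#' @param cohort Cohort tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_table <- function(cohort, path) {
  out <- cohort
  if (is.list(out$infiltration_sites)) {
    out$infiltration_pattern <- vapply(out$infiltration_sites, function(s) {
      if (length(s) == 0) "none" else paste(s, collapse = ", ")
    }, character(1))
    out$infiltration_sites <- NULL
    out <- dplyr::relocate(out, "infiltration_pattern", .after = "subtype")
  }
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
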