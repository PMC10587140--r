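#' Per-sector DDC index
#'
#' Counts DDC-mask pixels in each sector and expresses them as a percentage
#' of the sector's area: `index = 100 * |ddc intersect sector| / |sector|`.
#' The all-sectors value uses the whole 2.5 mm disc and equals the
#' area-weighted mean of the five sector indices. Full precision is kept;
#' the print method rounds to 3 decimals (the conventional reporting
#' precision for these indices).
#'
#' @param ddc A [binary_image()] DDC mask (output of [ddc_mask()] or a
#'   ground-truth lesion mask).
#' @param sectors A [make_sector_masks()] result on the same grid.
#' @return An object of class `ddc_result`: data frame `sectors` with
#'   columns `sector`, `sector_px`, `ddc_px`, `index_percent` (rows center,
#'   nasal, superior, temporal, inferior, all_sectors), plus fields copied
#'   in by [run_pipeline()] when applicable.
#' @export
compute_index <- function(ddc, sectors) {
  stopifnot(inherits(ddc, "binary_image"), inherits(sectors, "sector_masks"))
  stopifnot_same_geometry(ddc, sectors$center)
  secs <- c("center", "nasal", "superior", "temporal", "inferior")
  rows <- lapply(c(secs, "all_sectors"), function(s) {
    sm <- if (s == "all_sectors") sectors$disc_2_5mm$mask else sectors[[s]]$mask
    n_sec <- sum(sm)
    n_ddc <- sum(ddc$mask & sm)
    data.frame(sector = s, sector_px = n_sec, ddc_px = n_ddc,
               index_percent = 100 * n_ddc / n_sec)
  })
  structure(list(sectors = do.call(rbind, rows),
                 mm_per_px_corrected = sectors$mm_per_px_corrected,
                 threshold = attr(ddc, "threshold"),
                 qc_pass = NA, qc_reasons = character(0)),
            class = "ddc_result")
}

#' @export
print.ddc_result <- function(x, ...) {
  tab <- x$sectors
  tab$index_percent <- sprintf("%.3f%%", tab$index_percent)
  cat("<ddc_result>\n")
  print(tab, row.names = FALSE)
  if (!is.null(x$threshold)) cat("threshold:", x$threshold, "\n")
  if (!is.na(x$qc_pass)) {
    cat("QC:", if (x$qc_pass) "pass" else
      paste("FAIL -", paste(x$qc_reasons, collapse = "; ")), "\n")
  }
  invisible(x)
}

#' Eligibility check for an eye
#'
#' Scan-quality and biometry gates: pass iff signal strength index >= 8 and
#' axial length within \[22, 26\] mm. Missing fields are explicit failure
#' reasons, never a silent pass.
#'
#' @param meta An [eye_meta()].
#' @return List with `pass` (logical) and `reasons` (character vector of
#'   failures, empty when passing).
#' @export
check_eligibility <- function(meta) {
  stopifnot(inherits(meta, "eye_meta"))
  reasons <- character(0)
  if (is.na(meta$signal_strength)) {
    reasons <- c(reasons, "signal strength missing")
  } else if (meta$signal_strength < 8) {
    reasons <- c(reasons, sprintf("signal strength %g < 8", meta$signal_strength))
  }
  if (is.na(meta$axial_length_mm)) {
    reasons <- c(reasons, "axial length missing")
  } else if (meta$axial_length_mm < 22 || meta$axial_length_mm > 26) {
    reasons <- c(reasons, sprintf("axial length %g mm outside [22, 26]",
                                  meta$axial_length_mm))
  }
  list(pass = length(reasons) == 0L, reasons = reasons)
}

#' Run the full DDC quantification pipeline for one eye
#'
#' load (or accept) the en face image, resample to the analysis grid if
#' needed, binarize, delete fine vessels, build Bennett-corrected sector
#' masks, and compute the per-sector index. Deterministic for fixed inputs
#' and configuration. Stage failures are re-raised with the stage name; a
#' QC failure annotates the result rather than aborting (set
#' `config$qc_abort = TRUE` to abort instead).
#'
#' @param image A file path or a [gray_image()].
#' @param meta An [eye_meta()].
#' @param config A [ddc_config()] (defaults used when omitted).
#' @return A `ddc_result` (see [compute_index()]) with `qc_pass`,
#'   `qc_reasons` and `threshold` filled in.
#' @export
run_pipeline <- function(image, meta, config = ddc_config()) {
  stopifnot(inherits(meta, "eye_meta"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  img <- stage("load", {
    if (inherits(image, "gray_image")) image
    else load_enface(image, nominal_width_mm = config$nominal_width_mm)
  })
  if (!is.null(config$target_side_px) && img$side_px != config$target_side_px) {
    img <- stage("resample", resample_to_grid(img, config$target_side_px))
  }
  ddc <- stage("caliber_filter", ddc_mask(
    img,
    contrast = contrast_params(config$saturation_fraction),
    erode = erode_params(config$erode_iterations, config$erode_neighbor_count,
                         config$border_policy)))
  sectors <- stage("sector_geometry", make_sector_masks(
    img$side_px, img$nominal_width_mm, meta,
    reference_al_mm = config$reference_al_mm,
    nasal_side_override = config$nasal_side_override))
  res <- stage("index", compute_index(ddc, sectors))
  qc <- check_eligibility(meta)
  if (!qc$pass && isTRUE(config$qc_abort)) {
    stop("[stage qc] ", paste(qc$reasons, collapse = "; "), call. = FALSE)
  }
  res$qc_pass <- qc$pass
  res$qc_reasons <- qc$reasons
  res$eye_id <- meta$eye_id
  res
}
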