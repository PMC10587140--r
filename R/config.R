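#' Pipeline configuration
#'
#' One object holding every tunable of the quantification pipeline. The
#' defaults are the analysis parameters the pipeline is built around:
#' 0.35% contrast saturation, 3 erosion iterations with neighbor count 1
#' (caliber cutoff 6 px), background border policy, 24.2 mm reference
#' axial length, 3 mm nominal scan width, 1024 px analysis grid, alpha
#' 0.05, indices printed to 3 decimals.
#'
#' @param saturation_fraction See [contrast_params()].
#' @param erode_iterations,erode_neighbor_count,border_policy See
#'   [erode_params()].
#' @param reference_al_mm,nominal_width_mm,nasal_side_override See
#'   [make_sector_masks()].
#' @param target_side_px Analysis grid side; images on another grid are
#'   resampled (set `NULL` to disable). Default 1024.
#' @param alpha Significance level for reports. Default 0.05.
#' @param output_digits Decimal places for printed indices. Default 3.
#' @param qc_abort Abort (rather than annotate) on eligibility failure.
#'   Default FALSE.
#' @return An object of class `ddc_config`.
#' @export
ddc_config <- function(saturation_fraction = 0.0035, erode_iterations = 3,
                       erode_neighbor_count = 1, border_policy = "background",
                       reference_al_mm = 24.2, nominal_width_mm = 3,
                       target_side_px = 1024, nasal_side_override = NULL,
                       alpha = 0.05, output_digits = 3, qc_abort = FALSE) {
  # delegate range validation to the owning modules
  contrast_params(saturation_fraction)
  erode_params(erode_iterations, erode_neighbor_count, border_policy)
  if (!is.null(target_side_px) && target_side_px < 2) {
    stop("target_side_px must be >= 2 or NULL", call. = FALSE)
  }
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  structure(list(saturation_fraction = saturation_fraction,
                 erode_iterations = as.integer(erode_iterations),
                 erode_neighbor_count = as.integer(erode_neighbor_count),
                 border_policy = border_policy,
                 reference_al_mm = reference_al_mm,
                 nominal_width_mm = nominal_width_mm,
                 target_side_px = if (is.null(target_side_px)) NULL else
                   as.integer(target_side_px),
                 nasal_side_override = nasal_side_override,
                 alpha = alpha, output_digits = as.integer(output_digits),
                 qc_abort = isTRUE(qc_abort)),
            class = "ddc_config")
}

#' Write / read a pipeline configuration as YAML
#'
#' The round trip is lossless: `read_config(write_config(cfg, f))` equals
#' `cfg`.
#'
#' @param config A [ddc_config()].
#' @param path YAML file path.
#' @return `write_config` returns `path` invisibly; `read_config` returns
#'   a [ddc_config()].
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "ddc_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(ddc_config, vals)
}

# flatten a ddc_result into one results-table row
result_row <- function(res, error = NA_character_) {
  secs <- c("center", "nasal", "superior", "temporal", "inferior", "all_sectors")
  row <- data.frame(eye_id = if (is.null(res$eye_id)) NA_character_ else res$eye_id)
  for (s in secs) {
    i <- match(s, res$sectors$sector)
    row[[paste0(s, "_px")]] <- res$sectors$ddc_px[i]
    row[[s]] <- res$sectors$index_percent[i]
  }
  row$threshold <- if (is.null(res$threshold)) NA_integer_ else res$threshold
  row$qc_pass <- res$qc_pass
  row$qc_reasons <- paste(res$qc_reasons, collapse = "; ")
  row$error <- error
  row
}

empty_result_row <- function(eye_id, error) {
  r <- result_row(structure(list(
    sectors = data.frame(sector = character(0), sector_px = integer(0),
                         ddc_px = integer(0), index_percent = numeric(0)),
    threshold = NULL, qc_pass = NA, qc_reasons = character(0),
    eye_id = eye_id), class = "ddc_result"), error = error)
  r
}

# eye_meta from one row of a metadata table
meta_from_row <- function(row) {
  gv <- function(nm, default = NA) if (nm %in% names(row)) row[[nm]] else default
  eye_meta(eye_id = as.character(gv("eye_id")),
           laterality = as.character(gv("laterality")),
           axial_length_mm = as.numeric(gv("axial_length_mm")),
           signal_strength = as.numeric(gv("signal_strength")),
           sex = as.character(gv("sex", NA_character_)),
           cst_um = as.numeric(gv("cst_um")),
           va_decimal = as.numeric(gv("va_decimal")),
           dr_grade = as.character(gv("dr_grade", NA_character_)))
}

#' Batch-process a cohort of eyes
#'
#' Runs [run_pipeline()] for every row of a metadata table (CSV with
#' columns `eye_id, image_path, laterality, axial_length_mm,
#' signal_strength, sex, cst_um, va_decimal, dr_grade`; `image_path` is
#' resolved relative to `image_dir` when given). Per-eye failures are
#' recorded in an `error` column and never abort the batch. When
#' `out_path` is given the results table is written as CSV with a
#' provenance header (`#` comment lines: package version, config hash);
#' reruns on identical inputs are bit-identical.
#'
#' @param config A [ddc_config()].
#' @param meta A data frame or path to the metadata CSV.
#' @param image_dir Directory that `image_path` entries are relative to
#'   (`NULL` = use them as given).
#' @param out_path Optional output CSV path.
#' @return Data frame with one row per metadata row: the six sector
#'   indices and pixel counts, threshold, QC verdict and any error.
#' @export
run_batch <- function(config = ddc_config(), meta, image_dir = NULL,
                      out_path = NULL) {
  stopifnot(inherits(config, "ddc_config"))
  if (is.character(meta)) meta <- utils::read.csv(meta, stringsAsFactors = FALSE)
  rows <- vector("list", nrow(meta))
  for (i in seq_len(nrow(meta))) {
    mrow <- meta[i, , drop = FALSE]
    rows[[i]] <- tryCatch({
      path <- mrow$image_path
      if (!is.null(image_dir)) path <- file.path(image_dir, path)
      res <- run_pipeline(path, meta_from_row(mrow), config)
      result_row(res)
    }, error = function(e) {
      empty_result_row(as.character(mrow$eye_id), conditionMessage(e))
    })
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    empty_result_row(NA_character_, NA_character_)[0, ]
  if (!is.null(out_path)) {
    cfg_str <- paste(utils::capture.output(utils::str(unclass(config))),
                     collapse = " ")
    hdr <- c(sprintf("# ddcquant %s",
                     as.character(utils::packageVersion("ddcquant"))),
             sprintf("# config_hash %s",
                     sprintf("%08x", sum(utf8ToInt(cfg_str) *
                                           seq_along(utf8ToInt(cfg_str))) %%
                               .Machine$integer.max)))
    con <- file(out_path, "w")
    writeLines(hdr, con)
    utils::write.csv(out, con, row.names = FALSE)
    close(con)
  }
  out
}
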