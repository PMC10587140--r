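#' Per-eye clinical and geometric metadata
#'
#' @param laterality `"OD"` (right) or `"OS"` (left).
#' @param axial_length_mm Axial length in mm (> 0).
#' @param signal_strength Device signal strength index, 0..10 (eligibility
#'   requires >= 8). `NA` allowed; flagged by [check_eligibility()].
#' @param sex `"male"` or `"female"` (used by the CST-based DME rule).
#' @param cst_um Central subfield thickness in micrometers.
#' @param va_decimal Decimal best-corrected visual acuity (> 0), converted
#'   to logMAR where needed; alternatively supply `va_logmar`.
#' @param va_logmar logMAR visual acuity.
#' @param dr_grade One of `"none"`, `"mild NPDR"`, `"moderate NPDR"`,
#'   `"severe NPDR"`, `"PDR"`.
#' @param eye_id Optional identifier.
#' @return An object of class `eye_meta`.
#' @export
eye_meta <- function(laterality, axial_length_mm, signal_strength = NA,
                     sex = NA_character_, cst_um = NA_real_,
                     va_decimal = NA_real_, va_logmar = NA_real_,
                     dr_grade = NA_character_, eye_id = NA_character_) {
  grades <- c("none", "mild NPDR", "moderate NPDR", "severe NPDR", "PDR")
  if (!laterality %in% c("OD", "OS")) {
    stop("laterality must be 'OD' or 'OS'", call. = FALSE)
  }
  if (!is.na(axial_length_mm) && axial_length_mm <= 0) {
    stop("axial_length_mm must be > 0", call. = FALSE)
  }
  if (!is.na(signal_strength) && (signal_strength < 0 || signal_strength > 10)) {
    stop("signal_strength must be in [0, 10]", call. = FALSE)
  }
  if (!is.na(sex) && !sex %in% c("male", "female")) {
    stop("sex must be 'male' or 'female'", call. = FALSE)
  }
  if (!is.na(dr_grade) && !dr_grade %in% grades) {
    stop("dr_grade must be one of: ", paste(grades, collapse = ", "),
         call. = FALSE)
  }
  if (is.na(va_logmar) && !is.na(va_decimal)) {
    va_logmar <- decimal_to_logmar(va_decimal)
  }
  structure(list(eye_id = eye_id, laterality = laterality,
                 axial_length_mm = axial_length_mm,
                 signal_strength = signal_strength, sex = sex,
                 cst_um = cst_um, va_decimal = va_decimal,
                 va_logmar = va_logmar, dr_grade = dr_grade),
            class = "eye_meta")
}

#' Bennett magnification scale factor
#'
#' Ocular magnification correction for scan dimensions: the true retinal
#' size of a nominally sized scan scales with `(AL - 1.82)` by Bennett's
#' formula, so relative to the device's assumed reference axial length the
#' scan width scales by `(axial_length_mm - 1.82) / (reference_al_mm - 1.82)`.
#' The eye's true scan width is the nominal width times this factor.
#'
#' @param axial_length_mm Measured axial length in mm (> 1.82).
#' @param reference_al_mm Axial length assumed by the device for its nominal
#'   scan size, in mm (> 1.82). Default 24.2.
#' @return Dimensionless scale factor (1 when `axial_length_mm` equals the
#'   reference; strictly increasing in axial length).
#' @export
bennett_scale <- function(axial_length_mm, reference_al_mm = 24.2) {
  if (any(axial_length_mm <= 1.82) || any(reference_al_mm <= 1.82)) {
    stop("axial lengths must exceed 1.82 mm (Bennett model eye constant)",
         call. = FALSE)
  }
  (axial_length_mm - 1.82) / (reference_al_mm - 1.82)
}

#' ETDRS-style sector masks with axial-length correction
#'
#' Builds the five pixel masks used for sector counting: the central 1 mm
#' subfield disc and the four parafoveal quadrants (superior, nasal,
#' inferior, temporal) of the 1--2.5 mm annulus, plus the overall 2.5 mm
#' disc. The fovea is assumed at the exact image center. Physical scale is
#' the Bennett-corrected width: `corrected_mm_per_px = nominal_width_mm *
#' bennett_scale(AL, ref) / side_px`. Membership is by pixel-center
#' distance, inner bounds inclusive and outer bounds exclusive. Quadrants
#' are split by the two 45-degree diagonals through the center; pixels
#' exactly on a diagonal belong to the superior/inferior wedges. In
#' standard fundus orientation the nasal retina is on the image's right
#' half for OD and the left half for OS (overridable).
#'
#' @param side_px Grid side in pixels (>= 64).
#' @param nominal_width_mm Nominal scan width in mm. Default 3.
#' @param meta An [eye_meta()] supplying laterality and axial length.
#' @param reference_al_mm Reference axial length for [bennett_scale()].
#' @param nasal_side_override `"left"` or `"right"` to force which image
#'   half is nasal, ignoring laterality; `NULL` (default) uses laterality.
#' @return An object of class `sector_masks`: list with [binary_image()]
#'   elements `center`, `nasal`, `superior`, `temporal`, `inferior`,
#'   `disc_2_5mm`, plus `mm_per_px_corrected`.
#' @export
make_sector_masks <- function(side_px, nominal_width_mm = 3, meta,
                              reference_al_mm = 24.2,
                              nasal_side_override = NULL) {
  side_px <- as.integer(side_px)
  if (is.na(side_px) || side_px < 64L) stop("side_px must be >= 64", call. = FALSE)
  stopifnot(inherits(meta, "eye_meta"))
  scale <- bennett_scale(meta$axial_length_mm, reference_al_mm)
  width_mm <- nominal_width_mm * scale
  if (width_mm < 2.5) {
    stop(sprintf("corrected field of view %.3f mm cannot contain the 2.5 mm disc",
                 width_mm), call. = FALSE)
  }
  mm_pp <- width_mm / side_px
  ctr <- width_mm / 2
  coord <- (seq_len(side_px) - 0.5) * mm_pp - ctr   # pixel-center offsets, mm
  dy <- matrix(coord, side_px, side_px)             # rows: + = inferior (down)
  dx <- matrix(coord, side_px, side_px, byrow = TRUE)
  d <- sqrt(dx^2 + dy^2)
  center <- d < 0.5
  annulus <- d >= 0.5 & d < 1.25
  vert <- abs(dx) <= abs(dy)                        # closed vertical wedges
  superior <- annulus & vert & dy < 0
  inferior <- annulus & vert & dy > 0
  left  <- annulus & !vert & dx < 0
  right <- annulus & !vert & dx > 0
  nasal_side <- if (!is.null(nasal_side_override)) {
    match.arg(nasal_side_override, c("left", "right"))
  } else if (meta$laterality == "OD") "right" else "left"
  nasal    <- if (nasal_side == "right") right else left
  temporal <- if (nasal_side == "right") left else right
  bi <- function(m) binary_image(m, nominal_width_mm = nominal_width_mm)
  structure(list(center = bi(center), nasal = bi(nasal), superior = bi(superior),
                 temporal = bi(temporal), inferior = bi(inferior),
                 disc_2_5mm = bi(d < 1.25), mm_per_px_corrected = mm_pp),
            class = "sector_masks")
}

#' @export
print.sector_masks <- function(x, ...) {
  cat(sprintf("<sector_masks> %d px grid, %.5f mm/px corrected\n",
              x$center$side_px, x$mm_per_px_corrected))
  for (s in c("center", "nasal", "superior", "temporal", "inferior", "disc_2_5mm")) {
    cat(sprintf("  %-10s %d px\n", s, sum(x[[s]]$mask)))
  }
  invisible(x)
}
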