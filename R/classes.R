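#' Grayscale en face image
#'
#' Container for a square 2-D intensity grid on the 0--255 scale together
#' with its nominal physical geometry. En face OCTA angiograms are acquired
#' as a square field centered on the fovea (3 x 3 mm for the scans this
#' package targets), so the physical side length travels with the pixels.
#'
#' @param pixels Numeric matrix of intensities in `[0, 255]`. Must be square.
#'   Row 1 is the superior (top) edge of the scan.
#' @param nominal_width_mm Physical side length in mm before any ocular
#'   magnification correction. Default 3.
#' @return An object of class `gray_image` with elements `pixels`,
#'   `side_px` and `nominal_width_mm`.
#' @seealso [binary_image()], [load_enface()]
#' @export
gray_image <- function(pixels, nominal_width_mm = 3) {
  pixels <- as.matrix(pixels)
  if (!is.numeric(pixels)) stop("pixels must be numeric", call. = FALSE)
  if (nrow(pixels) != ncol(pixels)) {
    stop("image must be square (got ", nrow(pixels), " x ", ncol(pixels), ")",
         call. = FALSE)
  }
  if (nrow(pixels) < 1L) stop("image must have at least one pixel", call. = FALSE)
  if (anyNA(pixels)) stop("pixels must not contain NA", call. = FALSE)
  rng <- range(pixels)
  if (rng[1] < 0 || rng[2] > 255) {
    stop("intensities must lie in [0, 255]", call. = FALSE)
  }
  if (!is.numeric(nominal_width_mm) || length(nominal_width_mm) != 1L ||
      nominal_width_mm <= 0) {
    stop("nominal_width_mm must be a positive scalar", call. = FALSE)
  }
  structure(list(pixels = pixels, side_px = nrow(pixels),
                 nominal_width_mm = nominal_width_mm),
            class = "gray_image")
}

#' Binary (mask) image
#'
#' Boolean mask sharing the geometry contract of [gray_image()]; `TRUE`
#' pixels are foreground (flow signal).
#'
#' @param mask Logical (or 0/1 numeric) square matrix.
#' @param nominal_width_mm Physical side length in mm. Default 3.
#' @return An object of class `binary_image` with elements `mask`,
#'   `side_px` and `nominal_width_mm`.
#' @export
binary_image <- function(mask, nominal_width_mm = 3) {
  mask <- as.matrix(mask)
  if (is.numeric(mask)) {
    if (!all(mask %in% c(0, 1))) {
      stop("numeric mask values must be strictly 0/1", call. = FALSE)
    }
    mask <- mask > 0
  }
  if (!is.logical(mask)) stop("mask must be logical or 0/1", call. = FALSE)
  if (anyNA(mask)) stop("mask must not contain NA", call. = FALSE)
  if (nrow(mask) != ncol(mask)) {
    stop("mask must be square (got ", nrow(mask), " x ", ncol(mask), ")",
         call. = FALSE)
  }
  if (!is.numeric(nominal_width_mm) || length(nominal_width_mm) != 1L ||
      nominal_width_mm <= 0) {
    stop("nominal_width_mm must be a positive scalar", call. = FALSE)
  }
  structure(list(mask = mask, side_px = nrow(mask),
                 nominal_width_mm = nominal_width_mm),
            class = "binary_image")
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image> %d x %d px, %.3g mm nominal width, range [%g, %g]\n",
              x$side_px, x$side_px, x$nominal_width_mm,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
print.binary_image <- function(x, ...) {
  cat(sprintf("<binary_image> %d x %d px, %.3g mm nominal width, %d fg px (%.3f%%)\n",
              x$side_px, x$side_px, x$nominal_width_mm,
              sum(x$mask), 100 * mean(x$mask)))
  invisible(x)
}

# internal: both arguments share grid size and physical width
stopifnot_same_geometry <- function(a, b) {
  if (a$side_px != b$side_px ||
      !isTRUE(all.equal(a$nominal_width_mm, b$nominal_width_mm))) {
    stop("geometry mismatch: ", a$side_px, " px / ", a$nominal_width_mm,
         " mm vs ", b$side_px, " px / ", b$nominal_width_mm, " mm",
         call. = FALSE)
  }
  invisible(TRUE)
}
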