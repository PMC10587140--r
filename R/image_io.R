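#' Read a grayscale en face angiogram
#'
#' Reads a square single-channel PNG or TIFF raster and returns it as a
#' [gray_image()] with intensities on the 0--255 scale. Multi-channel files
#' are accepted only when all channels are identical (a gray image saved as
#' RGB); sources deeper than 8 bits are linearly rescaled by their maximum
#' so that the brightest pixel maps to 255.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @param nominal_width_mm Physical side length of the scan in mm. Default 3.
#' @return A [gray_image()].
#' @export
load_enface <- function(path, nominal_width_mm = 3) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format '", ext, "' (use PNG or TIFF)",
         call. = FALSE)
  )
  if (length(dim(raw)) == 3L) {
    ch <- dim(raw)[3]
    # drop a pure-padding alpha channel, then require identical color planes
    if (ch == 4L && all(raw[, , 4] == 1)) raw <- raw[, , 1:3, drop = FALSE]
    planes <- lapply(seq_len(dim(raw)[3]), function(k) raw[, , k])
    if (!all(vapply(planes[-1], function(p) identical(p, planes[[1]]), logical(1)))) {
      stop("multichannel image with differing channels is ambiguous: ", path,
           call. = FALSE)
    }
    raw <- planes[[1]]
  }
  if (nrow(raw) != ncol(raw)) {
    stop("en face image must be square, got ", nrow(raw), " x ", ncol(raw),
         call. = FALSE)
  }
  # readPNG/readTIFF normalize to [0,1] by the container depth. Recover 8-bit
  # levels; if the values are not 8-bit representable treat as a deep source
  # and rescale by its maximum.
  v8 <- raw * 255
  if (max(abs(v8 - round(v8))) < 1e-6) {
    px <- round(v8)
  } else {
    mx <- max(raw)
    px <- if (mx > 0) raw / mx * 255 else raw
  }
  gray_image(px, nominal_width_mm = nominal_width_mm)
}

#' Resample an image onto a different square grid
#'
#' Bilinear interpolation with a pixel-center convention: pixel `(r, c)` of
#' an `n`-pixel side sits at `((r - 0.5)/n, (c - 0.5)/n)` in unit-square
#' coordinates. Device exports that convert the native 300 x 300 A-scan grid
#' to a 1024 x 1024 analysis grid are emulated this way. The physical width
#' is unchanged; output intensities stay within the input range (bilinear
#' weights are convex).
#'
#' @param img A [gray_image()].
#' @param target_side_px Side length of the target grid (>= 2).
#' @return A [gray_image()] with `side_px = target_side_px`.
#' @export
resample_to_grid <- function(img, target_side_px) {
  stopifnot(inherits(img, "gray_image"))
  target_side_px <- as.integer(target_side_px)
  if (is.na(target_side_px) || target_side_px < 2L) {
    stop("target_side_px must be >= 2", call. = FALSE)
  }
  n_s <- img$side_px
  if (target_side_px == n_s) return(img)
  # source coordinate (0-based, pixel centers at 0..n_s-1) of each target center
  x <- ((seq_len(target_side_px) - 0.5) / target_side_px) * n_s - 0.5
  x <- pmin(pmax(x, 0), n_s - 1)
  i0 <- pmin(floor(x), n_s - 2)
  w <- x - i0
  # separable: rows then columns
  p <- img$pixels
  rows <- p[i0 + 1, , drop = FALSE] * (1 - w) + p[i0 + 2, , drop = FALSE] * w
  out <- rows[, i0 + 1, drop = FALSE] * rep(1 - w, each = target_side_px) +
         rows[, i0 + 2, drop = FALSE] * rep(w, each = target_side_px)
  gray_image(pmin(pmax(out, 0), 255), nominal_width_mm = img$nominal_width_mm)
}

#' Write a binary mask as an 8-bit image
#'
#' Foreground is written as 255, background as 0; [load_mask()] reads it
#' back losslessly.
#'
#' @param mask A [binary_image()].
#' @param path Output path ending in `.png`, `.tif` or `.tiff`.
#' @return `path`, invisibly.
#' @export
save_mask <- function(mask, path) {
  stopifnot(inherits(mask, "binary_image"))
  ext <- tolower(tools::file_ext(path))
  m <- mask$mask * 1.0  # 1 -> 255 at 8-bit depth
  ok <- switch(ext,
    png = tryCatch({ png::writePNG(m, target = path); TRUE },
                   error = function(e) stop("cannot write ", path, ": ",
                                            conditionMessage(e), call. = FALSE)),
    tif = ,
    tiff = tryCatch({ tiff::writeTIFF(m, where = path, bits.per.sample = 8L); TRUE },
                    error = function(e) stop("cannot write ", path, ": ",
                                             conditionMessage(e), call. = FALSE)),
    stop("unsupported mask format '", ext, "'", call. = FALSE)
  )
  invisible(path)
}

#' Read a binary mask written by [save_mask()]
#'
#' @param path Path to an 8-bit 0/255 mask image.
#' @param nominal_width_mm Physical side length in mm. Default 3.
#' @return A [binary_image()].
#' @export
load_mask <- function(path, nominal_width_mm = 3) {
  g <- load_enface(path, nominal_width_mm = nominal_width_mm)
  if (!all(g$pixels %in% c(0, 255))) {
    stop("not a binary 0/255 mask: ", path, call. = FALSE)
  }
  binary_image(g$pixels == 255, nominal_width_mm = nominal_width_mm)
}
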