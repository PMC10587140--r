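#' Contrast-adjustment parameters
#'
#' @param saturation_fraction Proportion of pixels allowed to clip at each
#'   tail of the intensity distribution during the automatic
#'   brightness/contrast stretch. Default 0.0035 (the ImageJ "Auto" default
#'   of 0.35% saturated pixels).
#' @return An object of class `contrast_params`.
#' @export
contrast_params <- function(saturation_fraction = 0.0035) {
  if (!is.numeric(saturation_fraction) || length(saturation_fraction) != 1L ||
      saturation_fraction < 0 || saturation_fraction >= 0.5) {
    stop("saturation_fraction must lie in [0, 0.5)", call. = FALSE)
  }
  structure(list(saturation_fraction = saturation_fraction),
            class = "contrast_params")
}

#' 256-bin intensity histogram
#'
#' Counts of rounded intensities at the integer levels 0..255. Thresholding
#' operates on this histogram.
#'
#' @param img A [gray_image()] or a numeric vector/matrix of intensities in
#'   `[0, 255]`.
#' @return Integer vector of length 256 (level `k` at index `k + 1`),
#'   summing to the pixel count.
#' @export
hist256 <- function(img) {
  v <- if (inherits(img, "gray_image")) img$pixels else img
  v <- round(as.numeric(v))
  if (anyNA(v) || any(v < 0 | v > 255)) {
    stop("intensities must lie in [0, 255]", call. = FALSE)
  }
  tabulate(v + 1L, nbins = 256L)
}

#' Automatic brightness/contrast adjustment
#'
#' ImageJ-style linear stretch: the lower and upper intensity quantiles at
#' `saturation_fraction` are mapped to 0 and 255 and values outside clip.
#' With `k = floor(saturation_fraction * n)`, the bounds are the smallest
#' level retained after discarding the `k` darkest pixels and the largest
#' after discarding the `k` brightest. A constant (zero-dynamic-range)
#' image is returned unchanged with a message.
#'
#' @param img A [gray_image()].
#' @param params A [contrast_params()].
#' @return A [gray_image()] with stretched intensities (continuous in
#'   `[0, 255]`; quantization to integer levels happens in [binarize()]).
#' @export
autoadjust_contrast <- function(img, params = contrast_params()) {
  stopifnot(inherits(img, "gray_image"), inherits(params, "contrast_params"))
  h <- hist256(img)
  n <- sum(h)
  k <- floor(params$saturation_fraction * n)
  cs <- cumsum(h)
  lo <- min(which(cs > k)) - 1L            # intensity level, 0-based
  cs_top <- rev(cumsum(rev(h)))
  hi <- max(which(cs_top > k)) - 1L
  if (hi <= lo) {
    message("autoadjust_contrast: zero dynamic range, image returned unchanged")
    return(img)
  }
  out <- (img$pixels - lo) / (hi - lo) * 255
  gray_image(pmin(pmax(out, 0), 255), nominal_width_mm = img$nominal_width_mm)
}

#' Kapur maximum-entropy threshold
#'
#' Returns the intensity level `t` maximizing the Kapur--Sahoo--Wong
#' criterion: the sum of the Shannon entropies of the normalized histogram
#' restricted to the background class (levels <= `t`) and the foreground
#' class (levels > `t`). Candidates range over splits leaving both classes
#' nonempty; ties break toward the smallest `t`. This is the "MaxEntropy"
#' auto-threshold of ImageJ. Empty bins contribute nothing (0 log 0 = 0);
#' natural logarithms are used (the argmax is base-invariant).
#'
#' @param hist Integer vector of 256 nonnegative counts (see [hist256()]).
#' @return Integer threshold level in 0..254; foreground is intensity > t.
#' @export
kapur_threshold <- function(hist) {
  if (length(hist) != 256L || any(hist < 0)) {
    stop("hist must be 256 nonnegative counts", call. = FALSE)
  }
  if (sum(hist > 0) < 2L) {
    stop("degenerate histogram: fewer than two populated levels", call. = FALSE)
  }
  p <- hist / sum(hist)
  plogp <- ifelse(p > 0, p * log(p), 0)
  P <- cumsum(p)        # P[t+1] = mass of levels <= t
  S <- cumsum(plogp)
  Pt <- P[1:255]        # candidate t = 0..254
  St <- S[1:255]
  total_S <- S[256]
  ok <- Pt > 0 & Pt < 1
  # H_bg = log P - S_bg / P ; H_fg likewise on the complement
  crit <- rep(-Inf, 255)
  crit[ok] <- (log(Pt[ok]) - St[ok] / Pt[ok]) +
              (log(1 - Pt[ok]) - (total_S - St[ok]) / (1 - Pt[ok]))
  which.max(crit) - 1L  # which.max takes the first (smallest t) on ties
}

#' Binarize an en face angiogram
#'
#' The vessel-mask step: automatic contrast adjustment, re-quantization to
#' integer levels, Kapur maximum-entropy thresholding of the adjusted
#' histogram. Foreground (flow signal) is the class strictly above the
#' threshold, i.e. always the brighter class.
#'
#' @param img A [gray_image()].
#' @param params A [contrast_params()].
#' @return A [binary_image()] vessel mask. The chosen threshold is attached
#'   as attribute `"threshold"`.
#' @export
binarize <- function(img, params = contrast_params()) {
  stopifnot(inherits(img, "gray_image"))
  adj <- autoadjust_contrast(img, params)
  q <- round(adj$pixels)
  t <- kapur_threshold(tabulate(q + 1L, nbins = 256L))
  out <- binary_image(q > t, nominal_width_mm = img$nominal_width_mm)
  attr(out, "threshold") <- t
  out
}
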