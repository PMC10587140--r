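# run expr with a temporary RNG state seeded by `seed`, restoring afterwards
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Specification for a synthetic en face OCTA phantom
#'
#' The phantom emulates the morphology the caliber filter is built for: a
#' mesh of normal-caliber deep capillaries (all widths at or below the
#' 6-pixel deletion cutoff) plus dot-like (microaneurysm-like ellipses) and
#' string-like (short dilated segments) lesions of supra-threshold caliber.
#' Vessel paths are smoothed random walks stroked at sampled widths;
#' intensities are class means with additive Gaussian noise.
#'
#' @param side_px Grid side in pixels. Default 1024 (the analysis grid).
#' @param nominal_width_mm Physical width in mm. Default 3.
#' @param mesh_density Target fraction of pixels covered by the normal
#'   mesh. Default 0.2.
#' @param mesh_width_px Inclusive integer range of normal-capillary stroke
#'   widths. Default `c(2, 5)`; must stay at or below 6 so the mesh is
#'   sub-threshold for the default erosion.
#' @param n_dot_lesions,dot_diameter_px Count and diameter range (px) of
#'   dot lesions. Defaults 12 and `c(8, 14)`.
#' @param n_string_lesions,string_width_px,string_length_px Count, width
#'   and length ranges (px) of string lesions. Defaults 6, `c(8, 12)`,
#'   `c(30, 80)`.
#' @param background_intensity,vessel_intensity,lesion_intensity Mean
#'   intensity levels (0--255). Defaults 30, 170, 200.
#' @param noise_sd Additive Gaussian noise SD. Default 12.
#' @param seed Integer seed; the phantom is fully reproducible from it.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(side_px = 1024, nominal_width_mm = 3,
                         mesh_density = 0.2, mesh_width_px = c(2, 5),
                         n_dot_lesions = 12, dot_diameter_px = c(8, 14),
                         n_string_lesions = 6, string_width_px = c(8, 12),
                         string_length_px = c(30, 80),
                         background_intensity = 30, vessel_intensity = 170,
                         lesion_intensity = 200, noise_sd = 12, seed = 1) {
  sp <- list(side_px = as.integer(side_px), nominal_width_mm = nominal_width_mm,
             mesh_density = mesh_density, mesh_width_px = as.integer(mesh_width_px),
             n_dot_lesions = as.integer(n_dot_lesions),
             dot_diameter_px = dot_diameter_px,
             n_string_lesions = as.integer(n_string_lesions),
             string_width_px = as.integer(string_width_px),
             string_length_px = string_length_px,
             background_intensity = background_intensity,
             vessel_intensity = vessel_intensity,
             lesion_intensity = lesion_intensity,
             noise_sd = noise_sd, seed = as.integer(seed))
  if (sp$side_px < 64L) stop("side_px must be >= 64", call. = FALSE)
  if (sp$mesh_density < 0 || sp$mesh_density >= 1) {
    stop("mesh_density must be in [0, 1)", call. = FALSE)
  }
  if (max(sp$mesh_width_px) > 6L) {
    stop("mesh widths must be <= 6 px (sub-threshold for the default erosion)",
         call. = FALSE)
  }
  if (min(sp$mesh_width_px) < 1L) stop("mesh widths must be >= 1", call. = FALSE)
  if (min(sp$dot_diameter_px) <= 6 || min(sp$string_width_px) <= 6) {
    stop("lesion calibers must exceed 6 px (supra-threshold)", call. = FALSE)
  }
  ints <- c(sp$background_intensity, sp$vessel_intensity, sp$lesion_intensity)
  if (any(ints < 0 | ints > 255)) stop("intensities must lie in [0, 255]", call. = FALSE)
  if (sp$noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (sp$n_dot_lesions < 0 || sp$n_string_lesions < 0) {
    stop("lesion counts must be >= 0", call. = FALSE)
  }
  structure(sp, class = "phantom_spec")
}

# smoothed random-walk path: persistent-heading control points, spline-densified
# to <= 1 px spacing; returns matrix of (row, col) in [1, n]
random_path <- function(n, start, n_ctrl, step) {
  theta <- stats::runif(1, 0, 2 * pi)
  pts <- matrix(NA_real_, n_ctrl, 2)
  pts[1, ] <- start
  for (i in 2:n_ctrl) {
    theta <- theta + stats::rnorm(1, 0, 0.7)
    p <- pts[i - 1, ] + step * c(sin(theta), cos(theta))
    # reflect off the borders to keep paths inside the field
    for (k in 1:2) {
      if (p[k] < 1) { p[k] <- 2 - p[k]; }
      if (p[k] > n) { p[k] <- 2 * n - p[k]; }
      p[k] <- min(max(p[k], 1), n)
    }
    pts[i, ] <- p
  }
  m <- max(16L, ceiling(2 * step * n_ctrl))
  t0 <- seq_len(n_ctrl)
  tt <- seq(1, n_ctrl, length.out = m)
  cbind(stats::spline(t0, pts[, 1], xout = tt)$y,
        stats::spline(t0, pts[, 2], xout = tt)$y)
}

# mark rounded path points into a logical matrix, clipped to the grid
mark_path <- function(mat, path) {
  r <- pmin(pmax(round(path[, 1]), 1), nrow(mat))
  c <- pmin(pmax(round(path[, 2]), 1), ncol(mat))
  mat[cbind(r, c)] <- TRUE
  mat
}

# thicken a centreline mask to a stroke of radius r (Euclidean, via the
# distance transform); r = 0 returns the centreline itself
stroke <- function(centerline, r) {
  if (!any(centerline)) return(centerline)
  if (r <= 0) return(centerline)
  dm <- EBImage::distmap(1 - centerline)
  matrix(dm <= r, nrow(centerline))
}

stroke_radius <- function(width_px) max(0L, as.integer((width_px - 1) %/% 2))

# uniform integer draw on [lo, hi]; immune to sample()'s scalar expansion
sample_range <- function(lo, hi) lo + sample.int(hi - lo + 1L, 1L) - 1L

# guarantee the mesh is sub-threshold by construction: individual strokes are
# <= 6 px wide, but confluences of overlapping strokes can exceed the caliber
# cutoff. Remove the 7x7 neighborhood of every pixel that would survive the
# default 3-iteration erosion; monotonicity of erosion makes one pass exact
# (erode3(thinned) is empty).
thin_to_subthreshold <- function(mesh) {
  bi <- binary_image(mesh)
  surv <- delete_fine_vessels(bi, erode_params(3, 1))$mask
  if (!any(surv)) return(mesh)
  dil <- EBImage::dilate(surv * 1, EBImage::makeBrush(7, "box")) > 0
  mesh & !dil
}

#' Generate a synthetic en face OCTA phantom
#'
#' Builds the capillary mesh by adding smoothed random-walk paths (stroked
#' at widths drawn from `mesh_width_px`) until the target vessel-pixel
#' fraction is reached, attaches dot lesions (random-orientation ellipses)
#' and string lesions (short wide strokes) at mesh points, and renders the
#' intensity image as class means plus Gaussian noise clipped to
#' `[0, 255]`. Fully reproducible from `spec$seed`; the caller's RNG state
#' is untouched.
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `phantom_result`: `image` ([gray_image()]),
#'   `vessel_truth` and `lesion_truth` ([binary_image()] ground-truth
#'   masks, `lesion_truth` a subset of `vessel_truth`), `lesion_records`
#'   (data frame: type, center_row, center_col, caliber_px), `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    n <- spec$side_px
    widths <- seq(spec$mesh_width_px[1], spec$mesh_width_px[2])
    radii <- sort(unique(vapply(widths, stroke_radius, integer(1))))
    centerlines <- lapply(radii, function(r) matrix(FALSE, n, n))
    names(centerlines) <- as.character(radii)
    step <- n / 10
    n_ctrl <- 8L
    mesh <- matrix(FALSE, n, n)
    mesh_pts <- NULL
    attempts <- 0L
    batch <- max(4L, ceiling(spec$mesh_density * n * n /
                               (step * (n_ctrl - 1) * mean(widths)) / 2))
    while (mean(mesh) < spec$mesh_density) {
      attempts <- attempts + 1L
      if (attempts > 10L) {
        stop("requested mesh density ", spec$mesh_density,
             " unreachable", call. = FALSE)
      }
      for (b in seq_len(batch)) {
        w <- sample_range(spec$mesh_width_px[1], spec$mesh_width_px[2])
        r <- as.character(stroke_radius(w))
        path <- random_path(n, stats::runif(2, 1, n), n_ctrl, step)
        centerlines[[r]] <- mark_path(centerlines[[r]], path)
      }
      mesh <- Reduce(`|`, Map(function(cl, r) stroke(cl, as.integer(r)),
                              centerlines, names(centerlines)))
      mesh <- thin_to_subthreshold(mesh)
      if (spec$mesh_density == 0) break
    }
    mesh_idx <- which(mesh)

    lesion <- matrix(FALSE, n, n)
    records <- list()
    attach_point <- function() {
      if (length(mesh_idx) > 0) {
        i <- mesh_idx[sample.int(length(mesh_idx), 1)]
        c((i - 1) %% n + 1, (i - 1) %/% n + 1)
      } else stats::runif(2, n * 0.1, n * 0.9)
    }
    # dot lesions: ellipses (fusiform/saccular outpouchings)
    for (k in seq_len(spec$n_dot_lesions)) {
      ctr <- attach_point()
      ax <- stats::runif(2, spec$dot_diameter_px[1], spec$dot_diameter_px[2]) / 2
      phi <- stats::runif(1, 0, pi)
      ext <- ceiling(max(ax))
      rr <- max(1, floor(ctr[1] - ext)):min(n, ceiling(ctr[1] + ext))
      cc <- max(1, floor(ctr[2] - ext)):min(n, ceiling(ctr[2] + ext))
      dy <- outer(rr - ctr[1], rep(1, length(cc)))
      dx <- outer(rep(1, length(rr)), cc - ctr[2])
      u <- dx * cos(phi) + dy * sin(phi)
      v <- -dx * sin(phi) + dy * cos(phi)
      lesion[rr, cc] <- lesion[rr, cc] | ((u / ax[1])^2 + (v / ax[2])^2 <= 1)
      records[[length(records) + 1L]] <-
        data.frame(type = "dot", center_row = ctr[1], center_col = ctr[2],
                   caliber_px = 2 * min(ax))
    }
    # string lesions: short wide strokes along smooth paths
    str_lines <- list()
    for (k in seq_len(spec$n_string_lesions)) {
      ctr <- attach_point()
      len <- stats::runif(1, spec$string_length_px[1], spec$string_length_px[2])
      w <- sample_range(spec$string_width_px[1], spec$string_width_px[2])
      r <- stroke_radius(w)
      path <- random_path(n, ctr, 4L, len / 3)
      key <- as.character(r)
      if (is.null(str_lines[[key]])) str_lines[[key]] <- matrix(FALSE, n, n)
      str_lines[[key]] <- mark_path(str_lines[[key]], path)
      records[[length(records) + 1L]] <-
        data.frame(type = "string", center_row = ctr[1], center_col = ctr[2],
                   caliber_px = 2 * r + 1)
    }
    for (key in names(str_lines)) {
      lesion <- lesion | stroke(str_lines[[key]], as.integer(key))
    }

    vessel <- mesh | lesion
    img <- matrix(spec$background_intensity, n, n)
    img[vessel] <- spec$vessel_intensity
    img[lesion] <- spec$lesion_intensity
    if (spec$noise_sd > 0) img <- img + stats::rnorm(n * n, 0, spec$noise_sd)
    img <- pmin(pmax(img, 0), 255)

    structure(list(
      image = gray_image(img, nominal_width_mm = spec$nominal_width_mm),
      vessel_truth = binary_image(vessel, nominal_width_mm = spec$nominal_width_mm),
      lesion_truth = binary_image(lesion, nominal_width_mm = spec$nominal_width_mm),
      lesion_records = if (length(records)) do.call(rbind, records) else
        data.frame(type = character(0), center_row = numeric(0),
                   center_col = numeric(0), caliber_px = numeric(0)),
      spec = spec), class = "phantom_result")
  })
}

#' Generate a synthetic cohort of phantom eyes
#'
#' Control eyes carry no dilated lesions; DR eyes draw dot/string lesion
#' counts from configurable ranges. Per-eye metadata (laterality, axial
#' length, signal strength, sex, CST, visual acuity, DR grade) is sampled
#' from distributions chosen to respect the eligibility gates. Everything
#' is deterministic given `seed`.
#'
#' @param n_control,n_dr Numbers of control and DR eyes (>= 1 unless 0 is
#'   explicitly wanted for one group).
#' @param overrides Named list of [phantom_spec()] arguments overriding the
#'   defaults for every eye (e.g. `list(side_px = 256)`).
#' @param seed Integer master seed.
#' @param dr_dot_range,dr_string_range Inclusive ranges the per-eye DR
#'   lesion counts are drawn from. Defaults `c(5, 20)` and `c(2, 8)`.
#' @return List of entries, each with `phantom` ([generate_phantom()]
#'   output), `meta` ([eye_meta()]) and `group` (`"control"`/`"DR"`).
#' @export
make_cohort <- function(n_control, n_dr, overrides = list(), seed = 1,
                        dr_dot_range = c(5, 20), dr_string_range = c(2, 8)) {
  stopifnot(n_control >= 0, n_dr >= 0, n_control + n_dr >= 1)
  with_seed(seed, {
    n_tot <- n_control + n_dr
    eye_seeds <- sample.int(.Machine$integer.max - 1L, n_tot)
    grades <- c("mild NPDR", "moderate NPDR", "severe NPDR", "PDR")
    out <- vector("list", n_tot)
    for (i in seq_len(n_tot)) {
      is_dr <- i > n_control
      args <- list(seed = eye_seeds[i])
      if (is_dr) {
        args$n_dot_lesions <- sample_range(dr_dot_range[1], dr_dot_range[2])
        args$n_string_lesions <- sample_range(dr_string_range[1], dr_string_range[2])
      } else {
        args$n_dot_lesions <- 0L
        args$n_string_lesions <- 0L
      }
      args <- utils::modifyList(args, overrides)
      sex <- sample(c("male", "female"), 1)
      dme <- is_dr && stats::runif(1) < 0.4
      cst <- if (dme) stats::rnorm(1, 380, 40) else if (is_dr)
        stats::rnorm(1, 280, 20) else stats::rnorm(1, 250, 15)
      meta <- eye_meta(
        eye_id = sprintf("%s_%03d", if (is_dr) "dr" else "ctl", i),
        laterality = sample(c("OD", "OS"), 1),
        axial_length_mm = min(max(stats::rnorm(1, 24.2, 0.7), 22), 26),
        signal_strength = sample(8:10, 1),
        sex = sex, cst_um = max(cst, 150),
        va_decimal = if (dme) stats::runif(1, 0.2, 0.8) else if (is_dr)
          stats::runif(1, 0.5, 1.2) else stats::runif(1, 0.8, 1.5),
        dr_grade = if (is_dr) sample(grades, 1, prob = c(0.3, 0.3, 0.2, 0.2))
        else "none")
      out[[i]] <- list(phantom = generate_phantom(do.call(phantom_spec, args)),
                       meta = meta, group = if (is_dr) "DR" else "control")
    }
    out
  })
}
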