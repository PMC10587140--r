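# Independent brute-force oracles used across the suite. Each one is a
# direct, unoptimized transcription of the defining formula, kept separate
# from the package's implementation path.

# Kapur criterion by exhaustive evaluation over all 255 splits
oracle_kapur <- function(hist) {
  p <- hist / sum(hist)
  ent <- function(q) {
    q <- q[q > 0]
    q <- q / sum(q)
    -sum(q * log(q))
  }
  best <- -Inf; best_t <- NA
  for (t in 0:254) {
    bg <- p[1:(t + 1)]; fg <- p[(t + 2):256]
    if (sum(bg) == 0 || sum(fg) == 0) next
    crit <- ent(bg) + ent(fg)
    if (crit > best + 1e-12) { best <- crit; best_t <- t }
  }
  best_t
}

# erosion by a (2k+1) x (2k+1) square structuring element: AND of all shifts,
# outside the image counting as background
oracle_box_erode <- function(mask, k) {
  n <- nrow(mask)
  pad <- matrix(FALSE, n + 2 * k, n + 2 * k)
  pad[(k + 1):(k + n), (k + 1):(k + n)] <- mask
  out <- matrix(TRUE, n, n)
  for (dr in -k:k) for (dc in -k:k) {
    out <- out & pad[(k + 1):(k + n) + dr, (k + 1):(k + n) + dc]
  }
  out
}

# bilinear interpolation of source matrix `src` at one target pixel center,
# pixel-center convention, 0-based coordinates clamped to the grid
oracle_bilinear_at <- function(src, i, j, n_t) {
  n_s <- nrow(src)
  at <- function(idx) {
    x <- ((idx - 0.5) / n_t) * n_s - 0.5
    x <- min(max(x, 0), n_s - 1)
    i0 <- min(floor(x), n_s - 2)
    c(i0, x - i0)
  }
  a <- at(i); b <- at(j)
  (1 - a[2]) * (1 - b[2]) * src[a[1] + 1, b[1] + 1] +
    (1 - a[2]) * b[2] * src[a[1] + 1, b[1] + 2] +
    a[2] * (1 - b[2]) * src[a[1] + 2, b[1] + 1] +
    a[2] * b[2] * src[a[1] + 2, b[1] + 2]
}

# two-sided Fisher p by enumeration of all tables with the observed margins
oracle_fisher <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  amin <- max(0, c1 - r2); amax <- min(r1, c1)
  pr <- vapply(amin:amax, function(x) {
    exp(lchoose(r1, x) + lchoose(r2, c1 - x) - lchoose(r1 + r2, c1))
  }, numeric(1))
  p_obs <- pr[a - amin + 1]
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

# random binary mask with given foreground probability
random_mask <- function(n, p = 0.5) matrix(stats::runif(n * n) < p, n, n)

# a full-width horizontal stripe of height w centered in an n x n grid
stripe_mask <- function(n, w) {
  m <- matrix(FALSE, n, n)
  r0 <- floor((n - w) / 2) + 1
  m[r0:(r0 + w - 1), ] <- TRUE
  binary_image(m)
}

default_meta <- function(laterality = "OD", al = 24.2) {
  eye_meta(laterality, al, signal_strength = 9, sex = "male",
           cst_um = 250, va_decimal = 1.0, dr_grade = "none")
}

all_sectors_index <- function(res) {
  res$sectors$index_percent[res$sectors$sector == "all_sectors"]
}
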