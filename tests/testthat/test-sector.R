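test_that("bennett_scale evaluates the axial-length ratio", {
  expect_equal(bennett_scale(24.2, 24.2), 1.0)
  expect_equal(bennett_scale(26.0, 24.2), (26.0 - 1.82) / (24.2 - 1.82))
  expect_equal(round(bennett_scale(26.0, 24.2), 4), 1.0804)
  als <- seq(22, 26, by = 0.5)
  expect_true(all(diff(bennett_scale(als, 24.2)) > 0))
  expect_error(bennett_scale(1.5, 24.2), "1.82")
  expect_error(bennett_scale(24, 1.0), "1.82")
})

test_that("sector masks are disjoint and partition the 2.5 mm disc", {
  for (al in c(22, 24.2, 26)) {
    sm <- make_sector_masks(256, 3, default_meta(al = al))
    parts <- list(sm$center$mask, sm$nasal$mask, sm$superior$mask,
                  sm$temporal$mask, sm$inferior$mask)
    overlap <- Reduce(`+`, parts)
    expect_true(all(overlap <= 1))                      # pairwise disjoint
    expect_identical(overlap > 0, sm$disc_2_5mm$mask)   # union = disc
    annulus <- sm$nasal$mask | sm$superior$mask | sm$temporal$mask |
      sm$inferior$mask
    expect_identical(annulus, sm$disc_2_5mm$mask & !sm$center$mask)
  }
})

test_that("center-mask pixel count matches the per-pixel distance oracle", {
  side <- 256
  sm <- make_sector_masks(side, 3, default_meta())
  mm_pp <- sm$mm_per_px_corrected
  ctr <- side * mm_pp / 2
  count <- 0L
  for (r in seq_len(side)) {
    dy <- (r - 0.5) * mm_pp - ctr
    dx <- (seq_len(side) - 0.5) * mm_pp - ctr
    count <- count + sum(sqrt(dx^2 + dy^2) < 0.5)
  }
  expect_identical(sum(sm$center$mask), count)
  # area agrees with pi * 0.5^2 within discretization (0.5%)
  area <- count * mm_pp^2
  expect_lt(abs(area - pi * 0.25) / (pi * 0.25), 0.005)
})

test_that("quadrants are symmetric and laterality swaps nasal/temporal", {
  sm <- make_sector_masks(256, 3, default_meta("OD"))
  # exact grid symmetries: top/bottom and left/right reflections
  expect_identical(sum(sm$superior$mask), sum(sm$inferior$mask))
  expect_identical(sum(sm$nasal$mask), sum(sm$temporal$mask))
  # vertical wedges exceed horizontal ones by exactly the 45-degree tie
  # pixels, which the closed-wedge rule assigns to superior/inferior
  mm_pp <- sm$mm_per_px_corrected
  off <- (seq_len(256) - 0.5) * mm_pp - 256 * mm_pp / 2
  dy <- matrix(off, 256, 256); dx <- t(dy)
  d <- sqrt(dx^2 + dy^2)
  ties <- sum(abs(dx) == abs(dy) & d >= 0.5 & d < 1.25)
  expect_identical(sum(sm$superior$mask) + sum(sm$inferior$mask) -
                     sum(sm$nasal$mask) - sum(sm$temporal$mask), ties)
  os <- make_sector_masks(256, 3, default_meta("OS"))
  expect_identical(os$nasal$mask, sm$temporal$mask)
  expect_identical(os$temporal$mask, sm$nasal$mask)
  expect_identical(os$superior$mask, sm$superior$mask)
  expect_identical(os$inferior$mask, sm$inferior$mask)
  # explicit override beats laterality
  ov <- make_sector_masks(256, 3, default_meta("OS"),
                          nasal_side_override = "right")
  expect_identical(ov$nasal$mask, sm$nasal$mask)
})

test_that("superior wedge sits at the top of the image", {
  sm <- make_sector_masks(128, 3, default_meta())
  rows_sup <- which(rowSums(sm$superior$mask) > 0)
  rows_inf <- which(rowSums(sm$inferior$mask) > 0)
  expect_lt(max(rows_sup), 65)
  expect_gt(min(rows_inf), 64)
})

test_that("physical disc area is axial-length invariant, pixel count is not", {
  counts <- numeric(0)
  for (al in c(22, 24.2, 26)) {
    sm <- make_sector_masks(256, 3, default_meta(al = al))
    n_px <- sum(sm$disc_2_5mm$mask)
    counts <- c(counts, n_px)
    area <- n_px * sm$mm_per_px_corrected^2
    expect_lt(abs(area - pi * 1.25^2) / (pi * 1.25^2), 0.005)
  }
  # longer eye -> wider true field -> fewer pixels per mm -> smaller disc in px
  expect_true(all(diff(counts) < 0))
})

test_that("geometry errors are raised for infeasible fields of view", {
  expect_error(make_sector_masks(32, 3, default_meta()), ">= 64")
  expect_error(make_sector_masks(256, 3, default_meta(al = 20)),
               "cannot contain")
})
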