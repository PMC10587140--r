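test_that("compute_index handles the empty and full extremes", {
  sm <- make_sector_masks(128, 3, default_meta())
  empty <- compute_index(binary_image(matrix(FALSE, 128, 128)), sm)
  expect_true(all(empty$sectors$index_percent == 0))
  full <- compute_index(binary_image(matrix(TRUE, 128, 128)), sm)
  expect_true(all(full$sectors$index_percent == 100))
  expect_error(compute_index(binary_image(matrix(FALSE, 64, 64)), sm),
               "geometry mismatch")
})

test_that("index on a truth mask equals the set-count ratio exactly", {
  p <- generate_phantom(phantom_spec(side_px = 256, seed = 41))
  sm <- make_sector_masks(256, 3, default_meta())
  res <- compute_index(p$lesion_truth, sm)
  for (s in c("center", "nasal", "superior", "temporal", "inferior")) {
    overlap <- sum(p$lesion_truth$mask & sm[[s]]$mask)
    expect_equal(res$sectors$index_percent[res$sectors$sector == s],
                 100 * overlap / sum(sm[[s]]$mask))
  }
})

test_that("all-sectors index is the area-weighted mean of sector indices", {
  p <- generate_phantom(phantom_spec(side_px = 256, seed = 42))
  sm <- make_sector_masks(256, 3, default_meta())
  res <- compute_index(ddc_mask(p$image), sm)
  tab <- res$sectors
  five <- tab[tab$sector != "all_sectors", ]
  expect_equal(sum(five$ddc_px), tab$ddc_px[tab$sector == "all_sectors"])
  weighted <- sum(five$index_percent * five$sector_px) / sum(five$sector_px)
  expect_equal(weighted, tab$index_percent[tab$sector == "all_sectors"])
})

test_that("eligibility gates follow the signal-strength and biometry rules", {
  ok <- check_eligibility(eye_meta("OD", 24, signal_strength = 8))
  expect_true(ok$pass); expect_length(ok$reasons, 0)
  low_ss <- check_eligibility(eye_meta("OD", 24, signal_strength = 7))
  expect_false(low_ss$pass)
  expect_match(low_ss$reasons, "signal strength", all = FALSE)
  short_al <- check_eligibility(eye_meta("OD", 21.9, signal_strength = 9))
  expect_false(short_al$pass)
  expect_match(short_al$reasons, "axial length", all = FALSE)
  # boundary values are inclusive
  expect_true(check_eligibility(eye_meta("OS", 22, signal_strength = 8))$pass)
  expect_true(check_eligibility(eye_meta("OS", 26, signal_strength = 10))$pass)
  # missing data fails loudly, never silently passes
  missing_ss <- check_eligibility(eye_meta("OD", 24))
  expect_false(missing_ss$pass)
  expect_match(missing_ss$reasons, "missing", all = FALSE)
})

test_that("run_pipeline is deterministic and stage-labels its errors", {
  p <- generate_phantom(phantom_spec(side_px = 256, seed = 43))
  cfg <- ddc_config(target_side_px = 256)
  r1 <- run_pipeline(p$image, default_meta(), cfg)
  r2 <- run_pipeline(p$image, default_meta(), cfg)
  expect_identical(r1$sectors, r2$sectors)
  expect_error(run_pipeline(gray_image(matrix(1, 256, 256)), default_meta(), cfg),
               "\\[stage caliber_filter\\]")
  expect_error(run_pipeline("no/such/file.png", default_meta(), cfg),
               "\\[stage load\\]")
})

test_that("qc failure annotates by default and aborts when configured", {
  p <- generate_phantom(phantom_spec(side_px = 256, seed = 44))
  meta_bad <- eye_meta("OD", 24.2, signal_strength = 5)
  cfg <- ddc_config(target_side_px = 256)
  r <- run_pipeline(p$image, meta_bad, cfg)
  expect_false(r$qc_pass)
  expect_match(r$qc_reasons, "signal strength", all = FALSE)
  cfg_abort <- ddc_config(target_side_px = 256, qc_abort = TRUE)
  expect_error(run_pipeline(p$image, meta_bad, cfg_abort), "\\[stage qc\\]")
})

test_that("lesion placement is reflected in the sector indices", {
  # lesion-free: negligible signal anywhere
  p0 <- generate_phantom(phantom_spec(side_px = 256, seed = 45,
                                      n_dot_lesions = 0, n_string_lesions = 0))
  r0 <- run_pipeline(p0$image, default_meta(), ddc_config(target_side_px = 256))
  expect_lte(all_sectors_index(r0), 0.01)

  # lesions only in the central subfield: quadrants stay clean
  n <- 256
  p1 <- generate_phantom(phantom_spec(side_px = n, seed = 46,
                                      n_dot_lesions = 0, n_string_lesions = 0))
  ctr <- (n + 1) / 2
  r_px <- 0.4 / (3 / n)   # 0.4 mm radius, safely inside the 0.5 mm subfield
  blob <- outer(seq_len(n) - ctr, rep(1, n))^2 + outer(rep(1, n), seq_len(n) - ctr)^2
  lesion <- sqrt(blob) < r_px
  img <- p1$image$pixels; img[lesion] <- 200
  r1 <- run_pipeline(gray_image(img), default_meta(), ddc_config(target_side_px = n))
  tab <- r1$sectors
  expect_gt(tab$index_percent[tab$sector == "center"], 0)
  for (s in c("nasal", "superior", "temporal", "inferior")) {
    expect_lte(tab$index_percent[tab$sector == s], 0.01)
  }
})
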