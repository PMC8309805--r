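test_that("zero translation is an exact identity", {
  img <- mammogram(matrix(runif(48), 6, 8))
  expect_identical(translate_pixels(img, 0, 0)$pixels, img$pixels)
})

test_that("translation moves pixels by (Bx, My) with zero fill", {
  p <- matrix(0, 20, 20)
  p[11, 11] <- 1   # 0-based (10, 10)
  out <- translate_pixels(mammogram(p), 3, 5)
  expect_equal(out$pixels[16, 14], 1)   # 0-based (15, 13)
  expect_equal(sum(out$pixels), 1)
})

test_that("translation composed with its inverse restores the overlap", {
  set.seed(21)
  p <- matrix(runif(30 * 30), 30, 30)
  img <- mammogram(p)
  there <- translate_pixels(img, 4, 2)
  back <- translate_pixels(there, -4, -2)
  # overlapping region: rows 1..28, cols 1..26 of the original survive
  expect_identical(back$pixels[1:28, 1:26], p[1:28, 1:26])
  # vacated band is zero-filled
  expect_true(all(back$pixels[29:30, ] == 0))
  expect_error(translate_pixels(img, 30, 0))
})

test_that("the detector recovers all in-range spots on noise-free phantoms", {
  sp <- phantom_spec(archetype = "diffuse", n_spots = 6,
                     diameter_range_mm = c(0.2, 0.45), noise_sd = 0,
                     seed = 11)
  ph <- generate_phantom(sp)
  cand <- detect_candidates(ph$image)
  expect_equal(nrow(cand), 6L)
  truth <- ph$truth
  for (i in seq_len(nrow(truth$spot_centers))) {
    d <- sqrt((cand$row - truth$spot_centers[i, 1])^2 +
                (cand$col - truth$spot_centers[i, 2])^2)
    j <- which.min(d)
    expect_lte(d[j], 1)                                    # center within 1 px
    expect_lte(abs(cand$diameter_mm[j] - truth$spot_diameters_mm[i]),
               sp$pixel_spacing_mm)                        # within 1 px-equiv
  }
})

test_that("blank images yield no candidates", {
  blank <- generate_phantom(phantom_spec(archetype = "none", noise_sd = 0))
  expect_equal(nrow(detect_candidates(blank$image)), 0L)
})

test_that("the 0.1-0.5 mm filter rejects an oversized spot", {
  # render one 0.9 mm spot by bypassing the spec's 0.7 mm cap: paste the
  # profile directly on a flat background
  p <- matrix(0.3, 120, 120)
  r_px <- 0.9 / (2 * 0.1)
  sigma <- r_px / sqrt(2 * log(2))
  for (r in 1:120) for (c in 1:120) {
    d2 <- (r - 60)^2 + (c - 60)^2
    if (d2 <= r_px^2) p[r, c] <- p[r, c] + 0.4 * exp(-d2 / (2 * sigma^2))
  }
  img <- mammogram(p, pixel_spacing_mm = 0.1)
  expect_equal(nrow(detect_candidates(img)), 0L)
  # the same spot is found when the band is widened: it was size-filtered,
  # not missed
  wide <- detect_candidates(img, diameter_limits_mm = c(0.1, 2))
  expect_equal(nrow(wide), 1L)
  expect_gt(wide$diameter_mm, 0.5)
})

test_that("detection requires a known pixel spacing", {
  img <- mammogram(matrix(runif(100), 10, 10))
  expect_error(detect_candidates(img), "spacing unknown")
})

test_that("ROI patches are centered, padded and labeled", {
  sp <- phantom_spec(archetype = "diffuse", n_spots = 6,
                     diameter_range_mm = c(0.2, 0.45), noise_sd = 0,
                     seed = 11)
  ph <- generate_phantom(sp)
  cand <- detect_candidates(ph$image)
  patches <- extract_roi_patches(ph$image, cand, patch_px = 32L)
  expect_length(patches, 6L)
  for (pt in patches) {
    expect_equal(dim(pt$pixels), c(32L, 32L))
    expect_identical(pt$label, ph$image$label)
  }

  # center pixel of the patch equals the image pixel at the candidate
  mid <- data.frame(row = 120, col = 160)
  pc <- extract_roi_patches(ph$image, mid, patch_px = 32L)[[1]]
  expect_identical(pc$pixels[16, 16], ph$image$pixels[120, 160])

  # a corner candidate zero-pads on the top/left
  corner <- data.frame(row = 1, col = 1)
  pcorner <- extract_roi_patches(ph$image, corner, patch_px = 32L)[[1]]
  expect_true(all(pcorner$pixels[1:15, ] == 0))
  expect_true(all(pcorner$pixels[, 1:15] == 0))
  expect_identical(pcorner$pixels[16, 16], ph$image$pixels[1, 1])
})
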