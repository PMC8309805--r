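test_that("a spot-free noise-free spec renders a constant background", {
  ph <- generate_phantom(phantom_spec(archetype = "none", noise_sd = 0,
                                      background_level = 0.3))
  expect_true(all(ph$image$pixels == 0.3))
  expect_equal(nrow(ph$truth$spot_centers), 0L)
  expect_identical(ph$truth$class_label, 0L)
})

test_that("class labels follow the archetype rule", {
  expect_identical(archetype_label("clustered"), 1L)
  expect_identical(archetype_label("segmental"), 1L)
  expect_identical(archetype_label("regional"), 0L)
  expect_identical(archetype_label("diffuse"), 0L)
  expect_identical(archetype_label("none"), 0L)
  ph <- generate_phantom(phantom_spec(archetype = "clustered", n_spots = 8,
                                      seed = 2))
  expect_identical(ph$truth$class_label, 1L)
  expect_equal(nrow(ph$truth$spot_centers), 8L)
})

test_that("phantom generation is deterministic in (spec, seed)", {
  sp <- phantom_spec(archetype = "segmental", n_spots = 10, seed = 77)
  a <- generate_phantom(sp)
  b <- generate_phantom(sp)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$truth, b$truth)
})

test_that("rendered spot diameter matches the annotation at half-peak", {
  # 0.4 mm spot at 0.1 mm/px must span ~4 px when thresholded at half the
  # peak contrast and summarised as an equivalent-circle diameter
  sp <- phantom_spec(archetype = "diffuse", n_spots = 1,
                     diameter_range_mm = c(0.4, 0.4), noise_sd = 0,
                     seed = 5, spot_contrast = 0.4, background_level = 0.3)
  ph <- generate_phantom(sp)
  excess <- ph$image$pixels - 0.3
  area <- sum(excess >= 0.2)              # at or above half-peak
  d_px <- 2 * sqrt(area / pi)
  expect_lt(abs(d_px - 4), 1)
})

test_that("annotated centers are local maxima in noise-free phantoms", {
  for (arch in c("clustered", "segmental", "regional", "diffuse")) {
    ph <- generate_phantom(phantom_spec(archetype = arch, n_spots = 6,
                                        noise_sd = 0, seed = 13))
    px <- ph$image$pixels
    h <- nrow(px); w <- ncol(px)
    for (i in seq_len(nrow(ph$truth$spot_centers))) {
      r <- ph$truth$spot_centers[i, 1]
      c <- ph$truth$spot_centers[i, 2]
      nb <- px[max(1, r - 1):min(h, r + 1), max(1, c - 1):min(w, c + 1)]
      expect_gte(px[r, c], max(nb))
    }
  }
})

test_that("sub-resolution spot specs are rejected", {
  expect_error(phantom_spec(pixel_spacing_mm = 0.5,
                            diameter_range_mm = c(0.1, 0.7)),
               "sub-resolution")
  expect_error(phantom_spec(diameter_range_mm = c(0.05, 0.4)),
               "\\[0.1, 0.7\\]")
})

test_that("generate_dataset respects counts, labels and determinism", {
  empty <- generate_dataset(0, 0, phantom_spec(), seed = 42L)
  expect_length(empty$phantoms, 0L)

  small_spec <- phantom_spec(width_px = 64L, height_px = 48L, n_spots = 4L)
  ds <- generate_dataset(7, 5, small_spec, seed = 42L)
  expect_equal(sum(ds$manifest$label == 0), 7L)
  expect_equal(sum(ds$manifest$label == 1), 5L)
  expect_true(all(ds$manifest$archetype[ds$manifest$label == 1] %in%
                    c("clustered", "segmental")))
  expect_true(all(ds$manifest$archetype[ds$manifest$label == 0] %in%
                    c("regional", "diffuse", "none")))
  ds2 <- generate_dataset(7, 5, small_spec, seed = 42L)
  for (i in seq_along(ds$phantoms))
    expect_identical(ds$phantoms[[i]]$image$pixels,
                     ds2$phantoms[[i]]$image$pixels)
  ds3 <- generate_dataset(3, 2, small_spec, seed = 43L)
  expect_false(identical(ds$phantoms[[1]]$image$pixels,
                         ds3$phantoms[[1]]$image$pixels))
})

test_that("phantom datasets round-trip through PNG + CSV manifests", {
  out <- withr::local_tempdir()
  ds <- generate_dataset(2, 1, phantom_spec(width_px = 48L, height_px = 40L,
                                            n_spots = 3L), seed = 9L)
  man <- write_phantom_dataset(ds, out)
  expect_true(file.exists(file.path(out, "manifest.csv")))
  expect_length(list.files(out, pattern = "phantom_.*\\.png$"), 3L)
  back <- read_mammogram_png(file.path(out, man$filename[1]))
  expect_equal(dim(back$pixels), c(40L, 48L))
  # 8-bit quantisation bounds the PNG round-trip error
  expect_lt(max(abs(back$pixels - ds$phantoms[[1]]$image$pixels)), 1 / 255)
})
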