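# DICOM conversion, bilinear resizing and the grayscale channel
# conversions.

make_dicom_fixture <- function(path, pixels, ...) {
  write_dicom(pixels, path, ...)
  path
}

test_that("DICOM to PNG conversion is pixel-lossless", {
  out <- withr::local_tempdir()
  px <- matrix(c(0L, 17L, 255L, 34L, 1L, 2L, 3L, 4L,
                 250L, 249L, 128L, 64L, 5L, 6L, 7L, 8L), 4, 4, byrow = TRUE)
  f <- make_dicom_fixture(file.path(out, "a.dcm"), px,
                          patient_id = "P001", bits_stored = 8L)
  res <- dicom_to_png(f, out)
  decoded <- round(png::readPNG(res$png_paths[1]) * 255)
  expect_identical(decoded, px + 0)  # exact integer round-trip

  # 12-bit data exceeds the 8-bit PNG range and goes through the 16-bit
  # encoder, still losslessly
  px12 <- matrix(sample.int(4096L, 36) - 1L, 6, 6)
  f12 <- make_dicom_fixture(file.path(out, "b.dcm"), px12,
                            patient_id = "P002", bits_stored = 12L)
  res12 <- dicom_to_png(f12, out)
  decoded12 <- round(png::readPNG(res12$png_paths[1]) * 65535)
  expect_identical(decoded12, px12 + 0)
})

test_that("patient metadata accumulates in the CSV", {
  out <- withr::local_tempdir()
  px <- matrix(0:15, 4, 4)
  paths <- vapply(1:3, function(i)
    make_dicom_fixture(file.path(out, sprintf("p%d.dcm", i)), px,
                       patient_id = sprintf("P%03d", i), patient_age = 40 + i,
                       view = "CC"), "")
  res <- dicom_to_png(paths, out)
  csv <- read.csv(file.path(out, "patients.csv"))
  expect_equal(nrow(csv), 3L)
  expect_true("P001" %in% csv$patient_id)
  expect_equal(csv$age, c(41L, 42L, 43L))
  expect_length(list.files(out, pattern = "\\.png$"), 3L)
})

test_that("the DICOM writer is readable by an independent parser", {
  # pydicom (through the system python) decodes the same pixels and header
  py <- Sys.which("python")
  out <- withr::local_tempdir()
  px <- matrix(sample.int(4096L, 24) - 1L, 4, 6)
  f <- make_dicom_fixture(file.path(out, "x.dcm"), px, patient_id = "XY99",
                          bits_stored = 12L, pixel_spacing_mm = 0.07)
  script <- sprintf(
    "import pydicom, sys; d = pydicom.dcmread(r'%s')
print(d.PatientID); print(d.Rows, d.Columns)
import numpy as np; a = d.pixel_array
print(int(a.sum())); print(int(a[2, 3]))", f)
  res <- system2(py, c("-c", shQuote(script)), stdout = TRUE)
  expect_equal(res[1], "XY99")
  expect_equal(res[2], "4 6")
  expect_equal(as.integer(res[3]), sum(px))
  expect_equal(as.integer(res[4]), px[3, 4])
})

test_that("malformed DICOM inputs raise descriptive errors", {
  out <- withr::local_tempdir()
  bad <- file.path(out, "notdicom.dcm")
  writeBin(as.raw(1:200), bad)
  expect_error(read_dicom(bad), "DICM")
})

test_that("resize hits the target size and matches the bilinear oracle", {
  big <- mammogram(matrix(runif(60 * 40), 40, 60))
  small <- resize_image(big, 32, 24)
  expect_equal(dim(small$pixels), c(24L, 32L))

  # identity resize returns the pixels untouched
  same <- resize_image(big, 60, 40)
  expect_identical(same$pixels, big$pixels)

  # 4x4 ramp down to 2x2 equals the per-pixel oracle
  r <- ramp_image(4, 4)
  down <- resize_image(r, 2, 2)
  expect_equal(down$pixels, oracle_bilinear_resize(r$pixels, 2, 2),
               tolerance = 1e-12)
  # and a non-integer ratio case
  up <- resize_image(r, 7, 5)
  expect_equal(up$pixels, oracle_bilinear_resize(r$pixels, 5, 7),
               tolerance = 1e-12)
})

test_that("grayscale conversions follow the channel formulas", {
  set.seed(4)
  px <- array(runif(8 * 8 * 3), c(8, 8, 3))
  img <- mammogram(px)
  avg <- rgb_to_gray_average(img)
  expect_equal(avg$pixels, (px[, , 1] + px[, , 2] + px[, , 3]) / 3)

  one <- mammogram(array(c(0.3, 0.6, 0.9), c(1, 1, 3)))
  expect_equal(rgb_to_gray_average(one)$pixels[1, 1], 0.6)

  # weighted conversion: scalar-loop oracle
  w <- c(0.299, 0.587, 0.114)
  wtd <- rgb_to_gray_weighted(img, w)
  oracle <- matrix(0, 8, 8)
  for (r in 1:8) for (c in 1:8)
    oracle[r, c] <- sum(px[r, c, ] * w)
  expect_equal(max(abs(wtd$pixels - oracle)), 0)

  # uniform weights reduce to the average method
  expect_equal(rgb_to_gray_weighted(img, rep(1 / 3, 3))$pixels, avg$pixels,
               tolerance = 1e-12)
  # red-only weights select the red channel
  red <- mammogram(array(c(1, 0, 0), c(1, 1, 3)))
  expect_equal(rgb_to_gray_weighted(red, w)$pixels[1, 1], 0.299)

  expect_error(rgb_to_gray_weighted(img, c(0.5, 0.5, 0.5)), "sum to 1")
  expect_error(rgb_to_gray_average(avg), "single-channel")
})

test_that("gray_to_rgb replicates planes and inverts through averaging", {
  g <- mammogram(matrix(runif(30), 5, 6))
  rgb <- gray_to_rgb(g)
  expect_equal(dim(rgb$pixels), c(5L, 6L, 3L))
  for (k in 1:3) expect_identical(rgb$pixels[, , k], g$pixels)
  expect_identical(rgb_to_gray_average(rgb)$pixels, g$pixels)
  zero <- gray_to_rgb(mammogram(matrix(0, 1, 1)))
  expect_identical(as.numeric(zero$pixels), c(0, 0, 0))
})
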