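# Minimal 16-bit grayscale PNG encoder. The png package (used everywhere
# else for I/O) reads 16-bit PNGs but only writes 8-bit ones; DICOM pixel
# arrays are commonly 10-16 bit and must survive conversion losslessly, so
# deep images are encoded here (colour type 0, no filtering, zlib via
# memCompress) and read back with png::readPNG.

.crc32_table <- local({
  tab_hi <- integer(256)
  tab_lo <- integer(256)
  poly_hi <- 0xEDB8L
  poly_lo <- 0x8320L
  for (n in 0:255) {
    hi <- 0L
    lo <- n
    for (k in 1:8) {
      odd <- bitwAnd(lo, 1L)
      lo <- bitwOr(bitwShiftR(lo, 1L), bitwShiftL(bitwAnd(hi, 1L), 15L))
      hi <- bitwShiftR(hi, 1L)
      if (odd == 1L) {
        hi <- bitwXor(hi, poly_hi)
        lo <- bitwXor(lo, poly_lo)
      }
    }
    tab_hi[n + 1L] <- hi
    tab_lo[n + 1L] <- lo
  }
  list(hi = tab_hi, lo = tab_lo)
})

# CRC-32 (IEEE, reflected) over a raw vector, kept in two 16-bit halves so
# everything stays inside R's signed 32-bit integers.
.crc32 <- function(bytes) {
  hi <- 0xFFFFL
  lo <- 0xFFFFL
  b <- as.integer(bytes)
  for (i in seq_along(b)) {
    idx <- bitwXor(bitwAnd(lo, 0xFFL), b[i]) + 1L
    new_lo <- bitwOr(bitwShiftR(lo, 8L),
                     bitwShiftL(bitwAnd(hi, 0xFFL), 8L))
    new_hi <- bitwShiftR(hi, 8L)
    hi <- bitwXor(new_hi, .crc32_table$hi[idx])
    lo <- bitwXor(new_lo, .crc32_table$lo[idx])
  }
  hi <- bitwXor(hi, 0xFFFFL)
  lo <- bitwXor(lo, 0xFFFFL)
  as.raw(c(bitwShiftR(hi, 8L), bitwAnd(hi, 0xFFL),
           bitwShiftR(lo, 8L), bitwAnd(lo, 0xFFL)))
}

.u32be <- function(x) {
  as.raw(c(x %/% 16777216, (x %/% 65536) %% 256, (x %/% 256) %% 256,
           x %% 256))
}

.png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  c(.u32be(length(data)), body, .crc32(body))
}

#' Write a 16-bit grayscale PNG
#'
#' Encodes an integer matrix (values in `0:65535`, row-major image layout:
#' `[r, c]` = row r, column c) as a 16-bit grayscale PNG. Read it back with
#' `png::readPNG`, which returns values scaled by 1/65535.
#'
#' @param pixels integer-valued matrix with entries in 0..65535.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_png_gray16 <- function(pixels, path) {
  stopifnot(is.matrix(pixels), all(pixels >= 0), all(pixels <= 65535),
            all(pixels == round(pixels)))
  h <- nrow(pixels)
  w <- ncol(pixels)
  ihdr <- c(.u32be(w), .u32be(h),
            as.raw(c(16L, 0L, 0L, 0L, 0L)))  # depth 16, gray, no interlace
  # scanlines: filter byte 0 then big-endian 16-bit samples, row by row
  v <- as.integer(t(pixels))                  # row-major sample order
  samples <- as.raw(rbind(v %/% 256L, v %% 256L))
  dim(samples) <- NULL
  m <- matrix(samples, nrow = 2L * w, ncol = h)
  raw_img <- as.raw(rbind(matrix(as.raw(0L), 1L, h), m))
  idat <- memCompress(raw_img, type = "gzip")  # zlib stream (0x78 ...)
  out <- c(as.raw(c(0x89, 0x50, 0x4E, 0x47, 0x0D, 0x0A, 0x1A, 0x0A)),
           .png_chunk("IHDR", ihdr),
           .png_chunk("IDAT", idat),
           .png_chunk("IEND", raw()))
  writeBin(out, path)
  invisible(path)
}
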