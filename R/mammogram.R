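#' Mammogram image container
#'
#' A light-weight container for a single mammogram: a grayscale matrix
#' (`H x W`, intensities in `[0, 1]`) or an RGB array (`H x W x 3`), with
#' optional physical pixel spacing, projection view and class label.
#' Pixels are stored row-major conceptually: element `[r, c]` is image row
#' `r` (top to bottom) and column `c` (left to right); shapes are reported
#' height x width (x channels).
#'
#' @param pixels numeric matrix (grayscale) or `H x W x 3` array (RGB) of
#'   finite intensities.
#' @param pixel_spacing_mm optional positive scalar, physical size of one
#'   pixel in millimetres.
#' @param view optional projection view, `"CC"` (craniocaudal) or `"MLO"`
#'   (mediolateral-oblique).
#' @param label optional class label: `0` = benign, `1` = malignant.
#' @return An object of class `mammogram`.
#' @examples
#' img <- mammogram(matrix(0.5, 24, 32), pixel_spacing_mm = 0.1)
#' dim(img$pixels)
#' @export
mammogram <- function(pixels, pixel_spacing_mm = NULL, view = NULL,
                      label = NULL) {
  if (is.matrix(pixels)) {
    nchan <- 1L
  } else if (is.array(pixels) && length(dim(pixels)) == 3L) {
    if (dim(pixels)[3] != 3L)
      stop("3-D pixel arrays must have exactly 3 planes (RGB)")
    nchan <- 3L
  } else {
    stop("'pixels' must be a matrix (grayscale) or an H x W x 3 array (RGB)")
  }
  if (!all(is.finite(pixels))) stop("pixel intensities must be finite")
  if (!is.null(pixel_spacing_mm)) {
    stopifnot(is.numeric(pixel_spacing_mm), length(pixel_spacing_mm) == 1L,
              pixel_spacing_mm > 0)
  }
  if (!is.null(view)) view <- match.arg(view, c("CC", "MLO"))
  if (!is.null(label)) stopifnot(label %in% c(0L, 1L))
  structure(
    list(pixels = pixels, pixel_spacing_mm = pixel_spacing_mm,
         view = view, label = if (is.null(label)) NULL else as.integer(label),
         n_channels = nchan),
    class = "mammogram")
}

#' @export
print.mammogram <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<mammogram> %d x %d px, %s%s%s%s\n", d[1], d[2],
              if (x$n_channels == 1L) "grayscale" else "RGB",
              if (is.null(x$pixel_spacing_mm)) ""
              else sprintf(", %.4g mm/px", x$pixel_spacing_mm),
              if (is.null(x$view)) "" else paste0(", view ", x$view),
              if (is.null(x$label)) ""
              else paste0(", label ", x$label)))
  invisible(x)
}

image_height <- function(img) dim(img$pixels)[1]
image_width <- function(img) dim(img$pixels)[2]

#' Write a mammogram as a PNG file
#'
#' Intensities are clipped to `[0, 1]` and written at the requested bit
#' depth (8 or 16 bit).
#'
#' @param img a [mammogram()].
#' @param path output file path.
#' @param bit_depth 8 or 16.
#' @return `path`, invisibly.
#' @export
write_mammogram_png <- function(img, path, bit_depth = 8L) {
  stopifnot(inherits(img, "mammogram"), bit_depth %in% c(8L, 16L))
  px <- pmin(pmax(img$pixels, 0), 1)
  png::writePNG(px, target = path, dpi = NULL,
                asp = NULL, text = NULL)
  invisible(path)
}

#' Read a PNG file as a mammogram
#'
#' @param path PNG file path.
#' @param pixel_spacing_mm,view,label forwarded to [mammogram()].
#' @return A [mammogram()] with intensities in `[0, 1]`.
#' @export
read_mammogram_png <- function(path, pixel_spacing_mm = NULL, view = NULL,
                               label = NULL) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3L && dim(px)[3] > 3L) px <- px[, , 1:3]  # drop alpha
  mammogram(px, pixel_spacing_mm = pixel_spacing_mm, view = view,
            label = label)
}
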