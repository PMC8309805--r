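#' Resize a mammogram with bilinear interpolation
#'
#' Resamples to exactly `target_w x target_h` pixels using center-aligned
#' bilinear interpolation (the behaviour of OpenCV's INTER_LINEAR). The
#' intensity range is untouched. Anisotropic resizes change the physical
#' spacing differently per axis, so the spacing field is kept (rescaled)
#' only when the horizontal and vertical scale factors agree to 1e-6 and
#' dropped otherwise.
#'
#' @param img a [mammogram()].
#' @param target_w,target_h positive integer output width and height.
#' @return A resized [mammogram()].
#' @examples
#' img <- mammogram(matrix(runif(12), 3, 4))
#' dim(resize_image(img, 8, 6)$pixels)  # 6 x 8
#' @export
resize_image <- function(img, target_w, target_h) {
  stopifnot(inherits(img, "mammogram"), target_w >= 1, target_h >= 1)
  h <- image_height(img)
  w <- image_width(img)
  px <- .map_planes(img$pixels, function(p) .resize_plane(p, target_h,
                                                          target_w))
  spacing <- NULL
  if (!is.null(img$pixel_spacing_mm)) {
    fy <- h / target_h
    fx <- w / target_w
    if (abs(fy - fx) < 1e-6) spacing <- img$pixel_spacing_mm * fx
  }
  mammogram(px, pixel_spacing_mm = spacing, view = img$view,
            label = img$label)
}

#' Convert RGB to grayscale by channel averaging
#'
#' Each output pixel is the arithmetic mean of the red, green and blue
#' values, `G = (r + g + b) / 3`.
#'
#' @param img a 3-plane (RGB) [mammogram()].
#' @return A single-plane [mammogram()].
#' @export
rgb_to_gray_average <- function(img) {
  stopifnot(inherits(img, "mammogram"))
  if (img$n_channels != 3L)
    stop("input is already single-channel; rgb_to_gray_average needs RGB")
  p <- img$pixels
  px <- matrix((p[, , 1] + p[, , 2] + p[, , 3]) / 3, dim(p)[1], dim(p)[2])
  mammogram(px, pixel_spacing_mm = img$pixel_spacing_mm, view = img$view,
            label = img$label)
}

#' Convert RGB to grayscale with channel weights
#'
#' Weighted conversion `NG = r * Pr + g * Pg + b * Pb`, with weights
#' summing to 1. The default weights are the BT.601 luma coefficients
#' (0.299, 0.587, 0.114), the convention common imaging libraries apply;
#' uniform weights (1/3 each) reduce this to [rgb_to_gray_average()].
#'
#' @param img a 3-plane (RGB) [mammogram()].
#' @param weights numeric length-3 vector `(Pr, Pg, Pb)` summing to 1
#'   within 1e-9.
#' @return A single-plane [mammogram()].
#' @export
rgb_to_gray_weighted <- function(img, weights = c(0.299, 0.587, 0.114)) {
  stopifnot(inherits(img, "mammogram"))
  if (img$n_channels != 3L)
    stop("input is already single-channel; rgb_to_gray_weighted needs RGB")
  if (length(weights) != 3L || abs(sum(weights) - 1) > 1e-9)
    stop("channel weights (Pr, Pg, Pb) must sum to 1")
  p <- img$pixels
  px <- matrix(p[, , 1] * weights[1] + p[, , 2] * weights[2] +
                 p[, , 3] * weights[3], dim(p)[1], dim(p)[2])
  mammogram(px, pixel_spacing_mm = img$pixel_spacing_mm, view = img$view,
            label = img$label)
}

#' Replicate a grayscale image into three RGB planes
#'
#' Produces `r = g = b =` input, the representation the network input layer
#' expects (H x W x 3).
#'
#' @param img a single-plane [mammogram()].
#' @return A 3-plane [mammogram()].
#' @export
gray_to_rgb <- function(img) {
  stopifnot(inherits(img, "mammogram"))
  if (img$n_channels != 1L) stop("gray_to_rgb needs a single-plane image")
  px <- array(img$pixels, dim = c(dim(img$pixels), 3L))
  mammogram(px, pixel_spacing_mm = img$pixel_spacing_mm, view = img$view,
            label = img$label)
}
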