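# Offline dataset inflation. Each mammogram is rotated at a fixed set of
# angles (default 45, 90, 180 and 360 degrees), keeping the full rotated
# extent inside the frame and resizing back to the target dimensions, so
# one input yields five outputs (original + four rotations) and class
# proportions are preserved. The 360-degree copy duplicates the original by
# construction; it is kept deliberately because the 5x inflation arithmetic
# (577 originals -> 2885 images) depends on it.

#' Augmentation plan
#'
#' @param angles_deg rotation angles in degrees.
#' @param include_original keep the unrotated image in the output.
#' @param hflip,vflip also emit horizontally / vertically mirrored copies
#'   (off by default: offline inflation uses rotations only).
#' @param target_w,target_h output frame size; `NA` keeps each source
#'   image's own size.
#' @return An `augment_plan` object.
#' @export
augment_plan <- function(angles_deg = c(45, 90, 180, 360),
                         include_original = TRUE, hflip = FALSE,
                         vflip = FALSE, target_w = NA_integer_,
                         target_h = NA_integer_) {
  if (length(angles_deg) == 0L && !include_original && !hflip && !vflip)
    stop("empty plan: no angles, no flips, original excluded")
  structure(list(angles_deg = angles_deg,
                 include_original = include_original, hflip = hflip,
                 vflip = vflip, target_w = target_w, target_h = target_h),
            class = "augment_plan")
}

#' Rotate a mammogram, fitting the full extent into the frame
#'
#' The image is rotated counterclockwise about its center; the canvas is
#' expanded so no corner is cropped (background fill 0) and the result is
#' resized to `target_w x target_h` (defaults: the source size). Multiples
#' of 90 degrees take an exact index-permutation path with no
#' interpolation.
#'
#' @param img a [mammogram()].
#' @param angle_deg rotation angle in degrees.
#' @param target_w,target_h output frame, defaulting to the input size.
#' @return The rotated [mammogram()].
#' @export
rotate_keep_frame <- function(img, angle_deg, target_w = NULL,
                              target_h = NULL) {
  stopifnot(inherits(img, "mammogram"), is.finite(angle_deg))
  if (is.null(target_w)) target_w <- image_width(img)
  if (is.null(target_h)) target_h <- image_height(img)
  px <- .map_planes(img$pixels,
                    function(p) .rotate_fit_plane(p, angle_deg, target_h,
                                                  target_w))
  mammogram(px, pixel_spacing_mm = NULL, view = img$view, label = img$label)
}

.flip_h <- function(p) p[, ncol(p):1, drop = FALSE]
.flip_v <- function(p) p[nrow(p):1, , drop = FALSE]

#' Inflate a labeled image collection by rotation (and optional flips)
#'
#' With the default plan every input image yields five outputs (the
#' original plus rotations at 45, 90, 180 and 360 degrees), each
#' inheriting the source label, so 425 benign + 152 malignant inputs
#' become 2125 + 760 = 2885 images.
#'
#' @param images list of [mammogram()] objects (labels attached).
#' @param plan an [augment_plan()].
#' @return A list with `images` (augmented list) and `manifest`
#'   (data.frame: source index, transform tag, label).
#' @export
augment_dataset <- function(images, plan = augment_plan()) {
  stopifnot(inherits(plan, "augment_plan"))
  out <- list()
  rows <- list()
  emit <- function(im, src, tag) {
    out[[length(out) + 1L]] <<- im
    rows[[length(rows) + 1L]] <<-
      data.frame(source = src, transform = tag,
                 label = if (is.null(im$label)) NA_integer_ else im$label)
  }
  for (i in seq_along(images)) {
    img <- images[[i]]
    tw <- if (is.na(plan$target_w)) image_width(img) else plan$target_w
    th <- if (is.na(plan$target_h)) image_height(img) else plan$target_h
    if (plan$include_original) {
      orig <- if (tw == image_width(img) && th == image_height(img)) img
              else resize_image(img, tw, th)
      emit(orig, i, "original")
    }
    for (a in plan$angles_deg)
      emit(rotate_keep_frame(img, a, tw, th), i, sprintf("rot%g", a))
    if (plan$hflip) {
      f <- mammogram(.map_planes(img$pixels, .flip_h), view = img$view,
                     label = img$label)
      emit(if (tw == image_width(f) && th == image_height(f)) f
           else resize_image(f, tw, th), i, "hflip")
    }
    if (plan$vflip) {
      f <- mammogram(.map_planes(img$pixels, .flip_v), view = img$view,
                     label = img$label)
      emit(if (tw == image_width(f) && th == image_height(f)) f
           else resize_image(f, tw, th), i, "vflip")
    }
  }
  list(images = out, manifest = do.call(rbind, rows))
}
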