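# Microcalcification candidate detection and ROI patch extraction.
#
# Candidates are bright, compact structures: a white top-hat transform
# (image minus its morphological opening with a disc slightly larger than
# the largest MC, 0.7 mm) suppresses the parenchymal background, a robust
# relative threshold (median + k * MAD, with an absolute floor) binarises
# the residue, and connected components become candidates. Each component's
# physical size is summarised as its equivalent-circle diameter
# 2 * sqrt(area / pi) * spacing; candidates outside the 0.1-0.5 mm ROI
# band are discarded.

#' Translate image pixels by an integer offset
#'
#' Shifts the whole pixel grid by `bx` columns (x) and `my` rows (y), the
#' affine translation `[x', y'] = [x + bx, y + my]`. Vacated pixels are
#' filled with 0; the image size is unchanged. A zero shift is an exact
#' identity.
#'
#' @param img a [mammogram()].
#' @param bx,my integer shifts along x (columns) and y (rows); absolute
#'   values must be smaller than the image width and height.
#' @return The translated [mammogram()].
#' @export
translate_pixels <- function(img, bx, my) {
  stopifnot(inherits(img, "mammogram"),
            bx == round(bx), my == round(my),
            abs(bx) < image_width(img), abs(my) < image_height(img))
  bx <- as.integer(bx)
  my <- as.integer(my)
  px <- .map_planes(img$pixels, function(p) .translate_plane(p, bx, my))
  mammogram(px, pixel_spacing_mm = img$pixel_spacing_mm, view = img$view,
            label = img$label)
}

#' Detect microcalcification candidates
#'
#' @param img a single-plane [mammogram()]; pixel spacing must be known
#'   (either on the image or via `spacing_mm`), since the diameter filter
#'   is physical.
#' @param spacing_mm mm per pixel; defaults to the image's own spacing.
#' @param se_diameter_mm diameter of the disc structuring element for the
#'   top-hat opening; slightly larger than the 0.7 mm maximum MC size.
#' @param k robust threshold factor: threshold = median + k * MAD of the
#'   top-hat residue.
#' @param min_threshold absolute floor on the threshold (guards the
#'   noise-free case where the MAD collapses to zero).
#' @param diameter_limits_mm candidates whose equivalent-circle diameter
#'   falls outside this band are discarded (ROI filter, default
#'   0.1-0.5 mm).
#' @return data.frame with columns `row`, `col` (intensity-weighted
#'   centroid, 1-based pixels), `diameter_mm` and `score` (peak top-hat
#'   response), one row per retained candidate.
#' @export
detect_candidates <- function(img, spacing_mm = NULL, se_diameter_mm = 0.9,
                              k = 3, min_threshold = 0.02,
                              diameter_limits_mm = c(0.1, 0.5)) {
  stopifnot(inherits(img, "mammogram"))
  if (img$n_channels != 1L)
    stop("detect_candidates needs a single-plane image")
  if (is.null(spacing_mm)) spacing_mm <- img$pixel_spacing_mm
  if (is.null(spacing_mm))
    stop("pixel spacing unknown: the physical diameter filter is undefined")
  p <- img$pixels
  se_px <- max(3L, as.integer(round(se_diameter_mm / spacing_mm)))
  if (se_px %% 2L == 0L) se_px <- se_px + 1L
  brush <- EBImage::makeBrush(se_px, shape = "disc")
  tophat <- p - EBImage::opening(p, brush)
  thr <- max(median(tophat) + k * mad(tophat), min_threshold)
  mask <- tophat > thr
  if (!any(mask))
    return(data.frame(row = numeric(0), col = numeric(0),
                      diameter_mm = numeric(0), score = numeric(0)))
  lab <- EBImage::bwlabel(mask)
  ncomp <- max(lab)
  rows_idx <- row(p)
  cols_idx <- col(p)
  out <- vector("list", ncomp)
  for (i in seq_len(ncomp)) {
    sel <- lab == i
    area <- sum(sel)
    d_mm <- 2 * sqrt(area / pi) * spacing_mm
    wgt <- tophat[sel]
    out[[i]] <- data.frame(
      row = sum(rows_idx[sel] * wgt) / sum(wgt),
      col = sum(cols_idx[sel] * wgt) / sum(wgt),
      diameter_mm = d_mm, score = max(wgt))
  }
  res <- do.call(rbind, out)
  res <- res[res$diameter_mm >= diameter_limits_mm[1] &
               res$diameter_mm <= diameter_limits_mm[2], , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Extract square ROI patches around candidates
#'
#' Cuts a `patch_px x patch_px` window centered on each candidate
#' (candidate pixel at patch position `patch_px/2` on both axes),
#' zero-padding where the window leaves the image. Every patch inherits
#' the image-level label.
#'
#' @param img a single-plane [mammogram()].
#' @param candidates data.frame from [detect_candidates()] (columns `row`,
#'   `col`, optionally `diameter_mm`).
#' @param patch_px even patch side length, at most `min(width, height)`.
#' @param label 0/1 label stamped on each patch; defaults to the image's.
#' @param source_image identifier recorded on each patch.
#' @return A list of `roi_patch` objects (fields: `pixels`, `center`,
#'   `diameter_mm`, `label`, `source_image`).
#' @export
extract_roi_patches <- function(img, candidates, patch_px = 32L,
                                label = img$label, source_image = NA) {
  stopifnot(inherits(img, "mammogram"), patch_px %% 2L == 0L,
            patch_px <= min(image_width(img), image_height(img)))
  h <- image_height(img)
  w <- image_width(img)
  half <- patch_px %/% 2L
  lapply(seq_len(nrow(candidates)), function(i) {
    cr <- as.integer(round(candidates$row[i]))
    cc <- as.integer(round(candidates$col[i]))
    patch <- matrix(0, patch_px, patch_px)
    rr <- (cr - half + 1L):(cr + half)
    cc_rng <- (cc - half + 1L):(cc + half)
    ok_r <- rr >= 1L & rr <= h
    ok_c <- cc_rng >= 1L & cc_rng <= w
    patch[which(ok_r), which(ok_c)] <-
      img$pixels[rr[ok_r], cc_rng[ok_c], drop = FALSE]
    structure(
      list(pixels = patch, center = c(row = cr, col = cc),
           diameter_mm = if ("diameter_mm" %in% names(candidates))
             candidates$diameter_mm[i] else NA_real_,
           label = label, source_image = source_image),
      class = "roi_patch")
  })
}
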