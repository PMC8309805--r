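# Plane-level geometric primitives. All operate on plain numeric matrices
# ([row, col], row 1 = image top) and use the center-aligned sampling
# convention of OpenCV's INTER_LINEAR: source coordinate of destination
# pixel j (0-based) is (j + 0.5) * size_in / size_out - 0.5, clamped.
# Rotations are counterclockwise as seen on screen; exact index
# permutations are used for multiples of 90 degrees so no interpolation
# error enters on those paths.

.resize_plane <- function(p, out_h, out_w) {
  h <- nrow(p)
  w <- ncol(p)
  if (out_h == h && out_w == w) return(p)
  sy <- pmin(pmax((seq_len(out_h) - 0.5) * h / out_h - 0.5, 0), h - 1)
  sx <- pmin(pmax((seq_len(out_w) - 0.5) * w / out_w - 0.5, 0), w - 1)
  y0 <- floor(sy); fy <- sy - y0
  x0 <- floor(sx); fx <- sx - x0
  iy0 <- as.integer(y0) + 1L; iy1 <- pmin(iy0 + 1L, h)
  ix0 <- as.integer(x0) + 1L; ix1 <- pmin(ix0 + 1L, w)
  FY <- matrix(fy, out_h, out_w)
  FX <- matrix(fx, out_h, out_w, byrow = TRUE)
  (1 - FY) * (1 - FX) * p[iy0, ix0, drop = FALSE] +
    FY * (1 - FX) * p[iy1, ix0, drop = FALSE] +
    (1 - FY) * FX * p[iy0, ix1, drop = FALSE] +
    FY * FX * p[iy1, ix1, drop = FALSE]
}

.rot90_ccw <- function(p, quarter_turns) {
  q <- quarter_turns %% 4L
  if (q == 0L) p
  else if (q == 1L) t(p[, ncol(p):1, drop = FALSE])
  else if (q == 2L) p[nrow(p):1, ncol(p):1, drop = FALSE]
  else t(p[nrow(p):1, , drop = FALSE])
}

# Rotate into an out_h x out_w frame about both centers, bilinear sampling,
# zero fill outside the source.
.rotate_plane_any <- function(p, angle_deg, out_h, out_w) {
  h <- nrow(p)
  w <- ncol(p)
  th <- angle_deg * pi / 180
  ct <- cos(th)
  st <- sin(th)
  xd <- matrix(seq_len(out_w) - (out_w + 1) / 2, out_h, out_w, byrow = TRUE)
  yd <- matrix(seq_len(out_h) - (out_h + 1) / 2, out_h, out_w)
  # inverse map (screen-CCW forward rotation, y axis pointing down)
  xs <- xd * ct - yd * st + (w + 1) / 2
  ys <- xd * st + yd * ct + (h + 1) / 2
  x0 <- floor(xs); fx <- xs - x0
  y0 <- floor(ys); fy <- ys - y0
  gather <- function(iy, ix) {
    ok <- iy >= 1 & iy <= h & ix >= 1 & ix <= w
    v <- p[cbind(as.vector(pmin(pmax(iy, 1L), h)),
                 as.vector(pmin(pmax(ix, 1L), w)))]
    v * as.vector(ok)
  }
  out <- (1 - fy) * (1 - fx) * gather(y0, x0) +
    fy * (1 - fx) * gather(y0 + 1, x0) +
    (1 - fy) * fx * gather(y0, x0 + 1) +
    fy * fx * gather(y0 + 1, x0 + 1)
  matrix(out, out_h, out_w)
}

# Rotate keeping the whole extent (expanded canvas), then resize to the
# requested frame.
.rotate_fit_plane <- function(p, angle_deg, target_h, target_w) {
  a <- angle_deg %% 360
  if (a %% 90 == 0) {
    r <- .rot90_ccw(p, as.integer(round(a / 90)))
    return(.resize_plane(r, target_h, target_w))
  }
  h <- nrow(p)
  w <- ncol(p)
  th <- a * pi / 180
  fit_w <- ceiling(w * abs(cos(th)) + h * abs(sin(th)) - 1e-9)
  fit_h <- ceiling(h * abs(cos(th)) + w * abs(sin(th)) - 1e-9)
  r <- .rotate_plane_any(p, a, fit_h, fit_w)
  .resize_plane(r, target_h, target_w)
}

.translate_plane <- function(p, bx, my) {
  h <- nrow(p)
  w <- ncol(p)
  out <- matrix(0, h, w)
  r_lo <- max(1L, 1L - my); r_hi <- min(h, h - my)
  c_lo <- max(1L, 1L - bx); c_hi <- min(w, w - bx)
  if (r_lo <= r_hi && c_lo <= c_hi) {
    src_r <- r_lo:r_hi
    src_c <- c_lo:c_hi
    out[src_r + my, src_c + bx] <- p[src_r, src_c, drop = FALSE]
  }
  out
}

# Apply a plane function to each channel of a mammogram's pixel data.
.map_planes <- function(px, f) {
  if (is.matrix(px)) return(f(px))
  planes <- lapply(seq_len(dim(px)[3]), function(k) f(px[, , k]))
  array(unlist(planes, use.names = FALSE),
        dim = c(dim(planes[[1]]), length(planes)))
}
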