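# Brute-force reference implementations used as independent oracles.
# All are deliberately naive (nested scalar loops) and stay independent of
# the package's code paths.

# Depthwise stage then pointwise stage, same padding, stride 1.
oracle_separable_conv <- function(x, dw, pw) {
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]
  kh <- dim(dw)[1]; kw <- dim(dw)[2]
  ph <- (kh - 1) %/% 2; pq <- (kw - 1) %/% 2
  mid <- array(0, c(H, W, C))
  for (c in 1:C) for (h in 1:H) for (w in 1:W) {
    acc <- 0
    for (i in 1:kh) for (j in 1:kw) {
      hi <- h + i - 1 - ph; wi <- w + j - 1 - pq
      if (hi >= 1 && hi <= H && wi >= 1 && wi <= W)
        acc <- acc + x[hi, wi, c] * dw[i, j, c]
    }
    mid[h, w, c] <- acc
  }
  nf <- ncol(pw)
  out <- array(0, c(H, W, nf))
  for (f in 1:nf) for (h in 1:H) for (w in 1:W)
    out[h, w, f] <- sum(mid[h, w, ] * pw[, f])
  out
}

# Per-pixel center-aligned bilinear interpolation (clamped borders).
oracle_bilinear_resize <- function(p, out_h, out_w) {
  h <- nrow(p); w <- ncol(p)
  out <- matrix(0, out_h, out_w)
  for (r in 1:out_h) for (c in 1:out_w) {
    sy <- min(max((r - 0.5) * h / out_h - 0.5, 0), h - 1)
    sx <- min(max((c - 0.5) * w / out_w - 0.5, 0), w - 1)
    y0 <- floor(sy); x0 <- floor(sx)
    fy <- sy - y0; fx <- sx - x0
    y1 <- min(y0 + 1, h - 1); x1 <- min(x0 + 1, w - 1)
    out[r, c] <- (1 - fy) * (1 - fx) * p[y0 + 1, x0 + 1] +
      fy * (1 - fx) * p[y1 + 1, x0 + 1] +
      (1 - fy) * fx * p[y0 + 1, x1 + 1] +
      fy * fx * p[y1 + 1, x1 + 1]
  }
  out
}

# Mann-Whitney pair counting with half credit for ties.
oracle_auc_pairs <- function(y, s) {
  pos <- s[y == 1]; neg <- s[y == 0]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}

# Exact 90-degree counterclockwise index permutation (square or not).
oracle_rot90_ccw <- function(p) {
  h <- nrow(p); w <- ncol(p)
  out <- matrix(0, w, h)
  for (r in 1:w) for (c in 1:h) out[r, c] <- p[c, w + 1 - r]
  out
}

# Confusion tally by explicit looping.
oracle_confusion <- function(y_true, y_pred) {
  tp <- tn <- fp <- fn <- 0L
  for (i in seq_along(y_true)) {
    if (y_true[i] == 1 && y_pred[i] == 1) tp <- tp + 1L
    else if (y_true[i] == 0 && y_pred[i] == 0) tn <- tn + 1L
    else if (y_true[i] == 0 && y_pred[i] == 1) fp <- fp + 1L
    else fn <- fn + 1L
  }
  c(TP = tp, TN = tn, FP = fp, FN = fn)
}

# Small deterministic test images.
ramp_image <- function(h, w) {
  mammogram(matrix(seq(0, 1, length.out = h * w), h, w, byrow = TRUE))
}
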