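# Network runtime: parameter initialisation, batched forward and backward
# passes, and AdaGrad updates. Activations are H x W x C x N arrays until
# the flatten layer, then features x N matrices. Convolution and pooling
# kernels are compiled (src/nn_ops.cpp); pointwise (1x1) convolutions,
# batch normalisation and dense layers reduce to BLAS matrix algebra.

.he_init <- function(n, fan_in) rnorm(n, 0, sqrt(2 / fan_in))

# Move channel next to features: (H,W,C,N) -> matrix (H*W*N) x C
.to_channel_mat <- function(x) {
  d <- dim(x)
  m <- aperm(x, c(1L, 2L, 4L, 3L))
  dim(m) <- c(d[1] * d[2] * d[4], d[3])
  m
}
.from_channel_mat <- function(m, d) {
  dim(m) <- c(d[1], d[2], d[4], d[3])
  aperm(m, c(1L, 2L, 4L, 3L))
}

#' Initialise trainable parameters for a network specification
#'
#' He-normal initialisation for convolutional and ReLU dense weights,
#' Glorot-style scaling for the softmax projection; zero biases; batch
#' normalisation starts at identity (gamma 1, beta 0) with zeroed running
#' statistics.
#'
#' @param spec a [network_spec()].
#' @param seed RNG seed for the draw.
#' @return A model object (list of per-layer parameter lists) of class
#'   `mc_model`.
#' @export
init_network <- function(spec, seed = 42L) {
  stopifnot(inherits(spec, "network_spec"))
  tr <- shape_trace(spec)
  set.seed(seed)
  layers <- vector("list", length(spec$layers))
  for (i in seq_along(spec$layers)) {
    l <- spec$layers[[i]]
    inshape <- tr$shape[[i]]
    par <- list(kind = l$kind, spec = l)
    if (l$kind == "separable_conv") {
      C <- inshape[3]
      par$dw <- array(.he_init(prod(l$kernel) * C, prod(l$kernel)),
                      dim = c(l$kernel, C))
      par$pw <- matrix(.he_init(C * l$n_filters, C), C, l$n_filters)
      par$b <- numeric(l$n_filters)
    } else if (l$kind == "conv2d") {
      C <- inshape[3]
      fan <- prod(l$kernel) * C
      par$w <- array(.he_init(fan * l$n_filters, fan),
                     dim = c(l$kernel, C, l$n_filters))
      par$b <- numeric(l$n_filters)
    } else if (l$kind == "batch_norm") {
      C <- inshape[3]
      par$gamma <- rep(1, C)
      par$beta <- numeric(C)
      par$run_mean <- numeric(C)
      par$run_var <- rep(1, C)
    } else if (l$kind == "dense") {
      par$w <- matrix(.he_init(inshape[1] * l$units, inshape[1]),
                      l$units, inshape[1])
      par$b <- numeric(l$units)
    } else if (l$kind == "softmax") {
      par$w <- matrix(rnorm(inshape[1] * l$units,
                            0, sqrt(1 / inshape[1])),
                      l$units, inshape[1])
      par$b <- numeric(l$units)
    }
    layers[[i]] <- par
  }
  structure(list(spec = spec, layers = layers), class = "mc_model")
}

.bn_eps <- 1e-3
.bn_momentum <- 0.9

# Forward pass. training = TRUE uses batch statistics, applies dropout and
# records caches for the backward pass. bn_momentum = 0 with dropout off
# (the "calibrate" path) re-estimates the running batch-norm moments from
# the data actually flowing through the trained weights, which keeps
# inference consistent with training after short runs where an exponential
# running average would still be dominated by its initialisation.
.forward <- function(model, x, training = FALSE,
                     bn_momentum = .bn_momentum, dropout_on = training) {
  caches <- vector("list", length(model$layers))
  a <- x
  for (i in seq_along(model$layers)) {
    p <- model$layers[[i]]
    l <- p$spec
    cache <- list()
    if (p$kind == "separable_conv") {
      dwo <- cpp_depthwise_fwd(a, p$dw, l$stride[1], l$stride[2])
      d <- dim(dwo)
      xm <- .to_channel_mat(dwo)
      zm <- sweep(xm %*% p$pw, 2L, p$b, `+`)
      z <- .from_channel_mat(zm, c(d[1], d[2], ncol(p$pw), d[4]))
      cache <- list(x = a, dwo = dwo)
      a <- if (l$activation == "relu") pmax(z, 0) else z
      cache$z_pos <- if (l$activation == "relu") z > 0 else NULL
    } else if (p$kind == "conv2d") {
      z <- cpp_conv2d_fwd(a, p$w, p$b, l$stride[1], l$stride[2])
      cache <- list(x = a)
      a <- if (l$activation == "relu") pmax(z, 0) else z
      cache$z_pos <- if (l$activation == "relu") z > 0 else NULL
    } else if (p$kind == "batch_norm") {
      d <- dim(a)
      xm <- .to_channel_mat(a)
      if (training) {
        mu <- colMeans(xm)
        xc <- sweep(xm, 2L, mu)
        v <- colMeans(xc^2)
        model$layers[[i]]$run_mean <-
          bn_momentum * p$run_mean + (1 - bn_momentum) * mu
        model$layers[[i]]$run_var <-
          bn_momentum * p$run_var + (1 - bn_momentum) * v
      } else {
        mu <- p$run_mean
        xc <- sweep(xm, 2L, mu)
        v <- p$run_var
      }
      istd <- 1 / sqrt(v + .bn_eps)
      xhat <- sweep(xc, 2L, istd, `*`)
      ym <- sweep(sweep(xhat, 2L, p$gamma, `*`), 2L, p$beta, `+`)
      cache <- list(xhat = xhat, istd = istd, d = d)
      a <- .from_channel_mat(ym, d)
    } else if (p$kind == "max_pool") {
      mp <- cpp_maxpool_fwd(a, l$kernel[1], l$kernel[2])
      cache <- list(xdim = dim(a), argmax = mp$argmax)
      a <- mp$y
    } else if (p$kind == "flatten") {
      cache <- list(xdim = dim(a))
      dim(a) <- c(prod(dim(a)[1:3]), dim(a)[4])
    } else if (p$kind == "dropout") {
      if (dropout_on) {
        keep <- 1 - l$rate
        mask <- (matrix(runif(length(a)), nrow(a), ncol(a)) < keep) / keep
        a <- a * mask
        cache <- list(mask = mask)
      }
    } else if (p$kind == "dense") {
      z <- sweep(p$w %*% a, 1L, p$b, `+`)
      cache <- list(x = a)
      a <- if (l$activation == "relu") pmax(z, 0) else z
      cache$z_pos <- if (l$activation == "relu") z > 0 else NULL
    } else if (p$kind == "softmax") {
      z <- sweep(p$w %*% a, 1L, p$b, `+`)
      cache <- list(x = a)
      zs <- sweep(z, 2L, apply(z, 2L, max))
      e <- exp(zs)
      a <- sweep(e, 2L, colSums(e), `/`)
    }
    caches[[i]] <- cache
  }
  list(probs = a, caches = caches, model = model)
}

# Backward pass from softmax + sparse categorical cross-entropy.
# y: integer labels 0..K-1; sample_w: per-sample loss weights.
.backward <- function(model, caches, probs, y, sample_w) {
  n <- ncol(probs)
  grads <- vector("list", length(model$layers))
  wsum <- sum(sample_w)
  delta <- probs
  idx <- cbind(y + 1L, seq_len(n))
  delta[idx] <- delta[idx] - 1
  delta <- sweep(delta, 2L, sample_w / wsum, `*`)   # d loss / d logits
  for (i in rev(seq_along(model$layers))) {
    p <- model$layers[[i]]
    l <- p$spec
    cache <- caches[[i]]
    g <- list()
    if (p$kind == "softmax") {
      g$w <- delta %*% t(cache$x)
      g$b <- rowSums(delta)
      delta <- t(p$w) %*% delta
    } else if (p$kind == "dense") {
      if (!is.null(cache$z_pos)) delta <- delta * cache$z_pos
      g$w <- delta %*% t(cache$x)
      g$b <- rowSums(delta)
      delta <- t(p$w) %*% delta
    } else if (p$kind == "dropout") {
      if (!is.null(cache$mask)) delta <- delta * cache$mask
    } else if (p$kind == "flatten") {
      dim(delta) <- cache$xdim
    } else if (p$kind == "max_pool") {
      delta <- cpp_maxpool_bwd(as.integer(cache$xdim), cache$argmax, delta)
    } else if (p$kind == "batch_norm") {
      dm <- .to_channel_mat(delta)
      xhat <- cache$xhat
      m <- nrow(dm)
      g$gamma <- colSums(dm * xhat)
      g$beta <- colSums(dm)
      dxhat <- sweep(dm, 2L, p$gamma, `*`)
      dx <- sweep(dxhat, 2L, colSums(dxhat) / m) -
        xhat * matrix(colSums(dxhat * xhat) / m, m, ncol(dm),
                      byrow = TRUE)
      dx <- sweep(dx, 2L, cache$istd, `*`)
      delta <- .from_channel_mat(dx, cache$d)
    } else if (p$kind == "conv2d") {
      if (!is.null(cache$z_pos)) delta <- delta * cache$z_pos
      bw <- cpp_conv2d_bwd(cache$x, p$w, delta, l$stride[1], l$stride[2])
      g$w <- bw$dw
      g$b <- bw$db
      delta <- bw$dx
    } else if (p$kind == "separable_conv") {
      if (!is.null(cache$z_pos)) delta <- delta * cache$z_pos
      d <- dim(delta)
      dm <- .to_channel_mat(delta)                  # (H*W*N) x F
      xm <- .to_channel_mat(cache$dwo)              # (H*W*N) x C
      g$pw <- t(xm) %*% dm
      g$b <- colSums(dm)
      d_dwo_m <- dm %*% t(p$pw)
      d_dwo <- .from_channel_mat(d_dwo_m,
                                 c(d[1], d[2], nrow(p$pw), d[4]))
      bw <- cpp_depthwise_bwd(cache$x, p$dw, d_dwo, l$stride[1],
                              l$stride[2])
      g$dw <- bw$dw
      delta <- bw$dx
    }
    grads[[i]] <- g
  }
  grads
}

# AdaGrad update in place; state holds accumulated squared gradients.
.adagrad_update <- function(model, grads, state, lr, eps = 1e-7) {
  for (i in seq_along(model$layers)) {
    g <- grads[[i]]
    if (is.null(g) || length(g) == 0L) next
    for (nm in names(g)) {
      pname <- switch(nm, gamma = "gamma", beta = "beta", dw = "dw",
                      pw = "pw", w = "w", b = "b")
      acc <- state[[i]][[nm]]
      if (is.null(acc)) acc <- g[[nm]] * 0
      acc <- acc + g[[nm]]^2
      state[[i]][[nm]] <- acc
      model$layers[[i]][[pname]] <-
        model$layers[[i]][[pname]] - lr * g[[nm]] / (sqrt(acc) + eps)
    }
  }
  list(model = model, state = state)
}

#' Class probabilities for a batch of images
#'
#' Runs the network in inference mode (running batch-norm statistics, no
#' dropout). With `tta = TRUE`, predictions are averaged over the four
#' shape-preserving dihedral views of each image (identity, horizontal
#' flip, vertical flip, 180-degree rotation) — exact index permutations,
#' no interpolation. The microcalcification distribution archetypes are
#' invariant under these views, so averaging reduces prediction variance
#' without changing what is being classified.
#'
#' @param model a trained `mc_model` (from [init_network()] or
#'   [train_model()]).
#' @param x `H x W x C x N` input tensor (see [stack_images()]).
#' @param tta average over the four shape-preserving dihedral views.
#' @return `N x n_classes` matrix of class probabilities.
#' @export
predict_proba <- function(model, x, tta = FALSE) {
  stopifnot(inherits(model, "mc_model"), length(dim(x)) == 4L)
  if (!tta) return(t(.forward(model, x, training = FALSE)$probs))
  views <- list(identity,
                function(p) .flip_h(p),
                function(p) .flip_v(p),
                function(p) .flip_h(.flip_v(p)))
  acc <- 0
  for (v in views) {
    xv <- x
    for (n in seq_len(dim(x)[4]))
      for (c in seq_len(dim(x)[3]))
        xv[, , c, n] <- v(x[, , c, n])
    acc <- acc + t(.forward(model, xv, training = FALSE)$probs)
  }
  acc / length(views)
}

#' Stack mammograms into a network input tensor
#'
#' Resizes each image to `target_h x target_w`, replicates grayscale
#' images to the requested channel count, and stacks the batch into an
#' `H x W x C x N` array.
#'
#' @param images list of [mammogram()] objects.
#' @param target_h,target_w spatial size of the tensor.
#' @param channels 1 or 3.
#' @return An `H x W x C x N` numeric array.
#' @export
stack_images <- function(images, target_h, target_w, channels = 3L) {
  n <- length(images)
  out <- array(0, dim = c(target_h, target_w, channels, n))
  for (i in seq_len(n)) {
    img <- images[[i]]
    if (image_height(img) != target_h || image_width(img) != target_w)
      img <- resize_image(img, target_w, target_h)
    px <- img$pixels
    if (is.matrix(px)) {
      for (k in seq_len(channels)) out[, , k, i] <- px
    } else {
      stopifnot(channels == dim(px)[3])
      out[, , , i] <- px
    }
  }
  out
}
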