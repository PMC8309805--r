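# Declarative network descriptions for the two classifiers:
#
#  * FC-DSCNN — six depthwise-separable convolutional layers with filter
#    schedule 32, 64, 64, 128, 128, 128 (each followed by batch
#    normalisation; 2x2 max-pooling after filter-count changes), then
#    flatten, dropout 0.5, a 256-unit dense layer and a 2-way softmax.
#  * DCNN — the identical topology with standard convolutions substituted
#    for the separable ones.
#
# Shapes are H x W x C. Convolutions use "same" zero padding (3x3 kernels,
# stride 1 preserves H and W); pooling uses floor division.

.layer_kinds <- c("separable_conv", "conv2d", "batch_norm", "max_pool",
                  "flatten", "dropout", "dense", "softmax")

#' Declarative layer specification
#'
#' @param kind layer kind: `"separable_conv"`, `"conv2d"`, `"batch_norm"`,
#'   `"max_pool"`, `"flatten"`, `"dropout"`, `"dense"` or `"softmax"`.
#' @param n_filters filter count (convolutional kinds).
#' @param kernel length-2 kernel size `(kh, kw)` (convolution/pooling).
#' @param stride length-2 stride `(sh, sw)`.
#' @param activation `"relu"` or `"none"`.
#' @param rate dropout rate (dropout only).
#' @param units output width (dense / softmax).
#' @return A `layer_spec` object.
#' @export
layer_spec <- function(kind, n_filters = NA_integer_, kernel = c(3L, 3L),
                       stride = c(1L, 1L), activation = "none",
                       rate = NA_real_, units = NA_integer_) {
  kind <- match.arg(kind, .layer_kinds)
  activation <- match.arg(activation, c("none", "relu"))
  stopifnot(all(kernel >= 1), all(stride >= 1))
  if (kind %in% c("separable_conv", "conv2d")) {
    stopifnot(!is.na(n_filters), n_filters >= 1)
    if (any(kernel %% 2L == 0L))
      stop("convolution kernels must have odd dimensions")
  }
  if (kind == "dropout") stopifnot(!is.na(rate), rate >= 0, rate < 1)
  if (kind %in% c("dense", "softmax")) stopifnot(!is.na(units), units >= 1)
  structure(list(kind = kind, n_filters = as.integer(n_filters),
                 kernel = as.integer(kernel), stride = as.integer(stride),
                 activation = activation, rate = rate,
                 units = as.integer(units)),
            class = "layer_spec")
}

#' Declarative network specification
#'
#' @param name network name.
#' @param input_shape length-3 integer vector `(H, W, C)`.
#' @param layers ordered list of [layer_spec()] objects; the last must be a
#'   softmax with `n_classes` units.
#' @param n_classes number of output classes.
#' @return A `network_spec` object.
#' @export
network_spec <- function(name, input_shape, layers, n_classes = 2L) {
  stopifnot(length(input_shape) == 3L, all(input_shape >= 1),
            length(layers) >= 1L,
            all(vapply(layers, inherits, logical(1), "layer_spec")))
  last <- layers[[length(layers)]]
  if (last$kind != "softmax" || last$units != n_classes)
    stop("the final layer must be a softmax with n_classes units")
  structure(list(name = name, input_shape = as.integer(input_shape),
                 layers = layers, n_classes = as.integer(n_classes)),
            class = "network_spec")
}

#' @export
print.network_spec <- function(x, ...) {
  cat(sprintf("<network_spec> %s, input %s, %d layers, %d classes\n",
              x$name, paste(x$input_shape, collapse = "x"),
              length(x$layers), x$n_classes))
  tr <- shape_trace(x)
  print(tr)
  invisible(x)
}

.conv_block_layers <- function(conv_kind, n_filters, repeats) {
  out <- list()
  for (i in seq_len(repeats)) {
    out <- c(out, list(
      layer_spec(conv_kind, n_filters = n_filters, kernel = c(3L, 3L),
                 stride = c(1L, 1L), activation = "relu"),
      layer_spec("batch_norm")))
  }
  c(out, list(layer_spec("max_pool", kernel = c(2L, 2L),
                         stride = c(2L, 2L))))
}

.build_vgg_like <- function(conv_kind, name, input_shape, n_classes) {
  layers <- c(
    .conv_block_layers(conv_kind, 32L, 1L),
    .conv_block_layers(conv_kind, 64L, 2L),
    .conv_block_layers(conv_kind, 128L, 3L),
    list(layer_spec("flatten"),
         layer_spec("dropout", rate = 0.5),
         layer_spec("dense", units = 256L, activation = "relu"),
         layer_spec("softmax", units = as.integer(n_classes))))
  network_spec(name, input_shape, layers, n_classes = n_classes)
}

#' Build the FC-DSCNN classifier specification
#'
#' Six depthwise-separable 3x3 convolutions (32, 64, 64, 128, 128, 128
#' filters, ReLU), batch normalisation after each, 2x2 max-pooling after
#' each filter-size group, then flatten, dropout 0.5, dense 256 (ReLU) and
#' a softmax over the classes. At the native 240 x 320 x 3 input the
#' flattened feature vector has 30 * 40 * 128 = 153,600 entries.
#'
#' @param input_shape `(H, W, C)` input shape.
#' @param n_classes output classes (2: benign / malignant).
#' @return A [network_spec()].
#' @export
build_fc_dscnn <- function(input_shape = c(240L, 320L, 3L), n_classes = 2L) {
  .build_vgg_like("separable_conv", "FC-DSCNN", input_shape, n_classes)
}

#' Build the standard-convolution baseline (DCNN) specification
#'
#' Identical topology to [build_fc_dscnn()] with ordinary 3x3 convolutions
#' in place of the depthwise-separable ones.
#'
#' @inheritParams build_fc_dscnn
#' @return A [network_spec()].
#' @export
build_dcnn <- function(input_shape = c(240L, 320L, 3L), n_classes = 2L) {
  .build_vgg_like("conv2d", "DCNN", input_shape, n_classes)
}

.conv_out <- function(n, stride) as.integer((n - 1L) %/% stride + 1L)

#' Symbolic shape propagation through a network specification
#'
#' Propagates the input shape layer by layer ("same" padding for
#' convolutions, floor division for pooling) and returns one row per layer
#' plus the input row. Errors name the first inconsistent layer.
#'
#' @param spec a [network_spec()].
#' @return data.frame with columns `layer` (1-based index; 0 = input),
#'   `kind`, and `output` (shape as a "HxWxC" or flat-length string), plus
#'   a list column `shape` of integer vectors.
#' @examples
#' tr <- shape_trace(build_fc_dscnn())
#' tr$output[tr$kind == "flatten"]  # "153600"
#' @export
shape_trace <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  shp <- spec$input_shape
  rows <- list(data.frame(layer = 0L, kind = "input",
                          output = paste(shp, collapse = "x")))
  shapes <- list(shp)
  for (i in seq_along(spec$layers)) {
    l <- spec$layers[[i]]
    bad <- function(msg) stop(sprintf("layer %d (%s): %s", i, l$kind, msg))
    if (l$kind %in% c("separable_conv", "conv2d")) {
      if (length(shp) != 3L) bad("needs an H x W x C input")
      shp <- c(.conv_out(shp[1], l$stride[1]), .conv_out(shp[2],
                                                         l$stride[2]),
               l$n_filters)
    } else if (l$kind == "batch_norm") {
      if (length(shp) != 3L) bad("needs an H x W x C input")
    } else if (l$kind == "max_pool") {
      if (length(shp) != 3L) bad("needs an H x W x C input")
      shp <- c(shp[1] %/% l$kernel[1], shp[2] %/% l$kernel[2], shp[3])
      if (any(shp[1:2] < 1L)) bad("pooling window larger than its input")
    } else if (l$kind == "flatten") {
      if (length(shp) != 3L) bad("input already flat")
      shp <- prod(shp)
    } else if (l$kind == "dropout") {
      # shape preserved
    } else if (l$kind %in% c("dense", "softmax")) {
      if (length(shp) != 1L) bad("needs a flat input (add a flatten layer)")
      shp <- l$units
    }
    shp <- as.integer(shp)
    rows[[i + 1L]] <- data.frame(layer = i, kind = l$kind,
                                 output = paste(shp, collapse = "x"))
    shapes[[i + 1L]] <- shp
  }
  out <- do.call(rbind, rows)
  out$shape <- shapes
  out
}

#' Trainable parameter counts per layer
#'
#' Separable convolutions hold `kh * kw * C` depthwise weights plus
#' `C * F` pointwise weights and `F` biases; standard convolutions hold
#' `kh * kw * C * F + F`; batch normalisation `2 * C` (scale and shift);
#' dense/softmax `in * units + units`.
#'
#' @param spec a [network_spec()].
#' @return data.frame with `layer`, `kind`, `params`; the total is in
#'   `attr(, "total")` and the convolutional-stage subtotal (convolution
#'   layers only) in `attr(, "conv_stage")`.
#' @export
count_parameters <- function(spec) {
  tr <- shape_trace(spec)
  params <- integer(length(spec$layers))
  for (i in seq_along(spec$layers)) {
    l <- spec$layers[[i]]
    inshape <- tr$shape[[i]]        # shape entering layer i
    params[i] <- switch(l$kind,
      separable_conv = prod(l$kernel) * inshape[3] +
        inshape[3] * l$n_filters + l$n_filters,
      conv2d = prod(l$kernel) * inshape[3] * l$n_filters + l$n_filters,
      batch_norm = 2L * inshape[3],
      dense = ,
      softmax = inshape[1] * l$units + l$units,
      0L)
  }
  out <- data.frame(layer = seq_along(spec$layers),
                    kind = vapply(spec$layers, `[[`, "", "kind"),
                    params = params)
  attr(out, "total") <- sum(params)
  attr(out, "conv_stage") <-
    sum(params[out$kind %in% c("separable_conv", "conv2d")])
  out
}

#' Depthwise-separable convolution of a single tensor
#'
#' The factorised convolution at the heart of the FC-DSCNN: stage one
#' convolves every input channel independently with its own `kh x kw`
#' spatial filter (depthwise); stage two mixes channels at each pixel with
#' `1 x 1 x C` filters producing `F` output maps (pointwise). "Same" zero
#' padding is used, so at stride 1 the spatial size is preserved.
#'
#' @param x `H x W x C` numeric array.
#' @param depthwise_kernels `kh x kw x C` array (odd `kh`, `kw`), one
#'   spatial filter per input channel.
#' @param pointwise_kernels `C x F` matrix (or `1 x 1 x C x F` array) of
#'   channel-mixing weights.
#' @param stride length-2 stride for the depthwise stage.
#' @return `H' x W' x F` numeric array.
#' @export
depthwise_separable_conv <- function(x, depthwise_kernels,
                                     pointwise_kernels,
                                     stride = c(1L, 1L)) {
  stopifnot(is.array(x), length(dim(x)) == 3L,
            length(dim(depthwise_kernels)) == 3L)
  dk <- dim(depthwise_kernels)
  if (any(dk[1:2] %% 2L == 0L))
    stop("depthwise kernels must have odd spatial dimensions")
  if (length(dim(pointwise_kernels)) == 4L) {
    pd <- dim(pointwise_kernels)
    stopifnot(pd[1] == 1L, pd[2] == 1L)
    pointwise_kernels <- matrix(pointwise_kernels, pd[3], pd[4])
  }
  pointwise_kernels <- as.matrix(pointwise_kernels)
  C <- dim(x)[3]
  if (dk[3] != C)
    stop("depthwise kernel channel count (", dk[3],
         ") does not match input channels (", C, ")")
  if (nrow(pointwise_kernels) != C)
    stop("pointwise kernel rows (", nrow(pointwise_kernels),
         ") do not match input channels (", C, ")")
  x4 <- x
  dim(x4) <- c(dim(x), 1L)
  dw <- cpp_depthwise_fwd(x4, depthwise_kernels, as.integer(stride[1]),
                          as.integer(stride[2]))
  d <- dim(dw)
  xm <- matrix(dw, ncol = C)                 # (H'*W') x C, batch of 1
  ym <- xm %*% pointwise_kernels
  array(ym, dim = c(d[1], d[2], ncol(pointwise_kernels)))
}

#' Serialize a network specification to JSON
#'
#' The JSON round-trips losslessly through [network_from_json()].
#'
#' @param spec a [network_spec()].
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @return The JSON string (invisibly when written to a file).
#' @export
network_to_json <- function(spec, path = NULL) {
  stopifnot(inherits(spec, "network_spec"))
  payload <- list(name = spec$name, input_shape = spec$input_shape,
                  n_classes = spec$n_classes,
                  layers = lapply(spec$layers, unclass))
  js <- jsonlite::toJSON(payload, auto_unbox = FALSE, digits = NA,
                         null = "null", na = "null", pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Deserialize a network specification from JSON
#'
#' @param path file path or JSON string produced by [network_to_json()].
#' @return A [network_spec()].
#' @export
network_from_json <- function(path) {
  payload <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  layers <- lapply(payload$layers, function(l) {
    layer_spec(kind = l$kind,
               n_filters = if (is.null(l$n_filters)) NA_integer_
                           else as.integer(l$n_filters),
               kernel = as.integer(unlist(l$kernel)),
               stride = as.integer(unlist(l$stride)),
               activation = l$activation,
               rate = if (is.null(l$rate)) NA_real_ else as.numeric(l$rate),
               units = if (is.null(l$units)) NA_integer_
                       else as.integer(l$units))
  })
  network_spec(payload$name, as.integer(unlist(payload$input_shape)),
               layers, n_classes = as.integer(payload$n_classes))
}
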