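# Training orchestration: stratified train/validation/test splits with
# optional k-fold assignment, a step learning-rate schedule, AdaGrad
# optimisation of the sparse categorical cross-entropy (with
# inverse-frequency class weighting for imbalance), and optional
# on-the-fly augmentation.

#' Training configuration
#'
#' Defaults follow the published hyperparameter set: batch size 32,
#' learning rate 0.001 decayed by a factor 0.1 every 5 epochs, dropout
#' 0.5, 20 epochs, AdaGrad, sparse categorical cross-entropy, random seed
#' 42. The class-weight policy is inverse-frequency weighting normalised
#' to mean 1 (`class_weight = "balanced"`); the original configuration
#' string is kept in `$class_weight_range` for provenance.
#'
#' @param batch_size minibatch size.
#' @param learning_rate initial AdaGrad learning rate.
#' @param dropout dropout rate of the pre-dense dropout layer.
#' @param epochs training epochs; must be at least `lr_decay_every`.
#' @param optimizer only `"adagrad"` is implemented.
#' @param class_weight `"balanced"` (inverse-frequency, mean 1) or
#'   `"none"`.
#' @param target_size `(width, height)` the pipeline resizes images to.
#' @param random_seed seed for weight init, shuffling and dropout.
#' @param loss only `"sparse_categorical_crossentropy"`.
#' @param lr_decay_factor,lr_decay_every step-decay schedule: the rate is
#'   multiplied by `lr_decay_factor` after every `lr_decay_every` epochs.
#' @return A `train_config` object.
#' @export
train_config <- function(batch_size = 32L, learning_rate = 0.001,
                         dropout = 0.5, epochs = 20L,
                         optimizer = "adagrad", class_weight = "balanced",
                         target_size = c(320L, 240L), random_seed = 42L,
                         loss = "sparse_categorical_crossentropy",
                         lr_decay_factor = 0.1, lr_decay_every = 5L) {
  optimizer <- match.arg(optimizer, "adagrad")
  loss <- match.arg(loss, "sparse_categorical_crossentropy")
  class_weight <- match.arg(class_weight, c("balanced", "none"))
  stopifnot(batch_size >= 1, learning_rate > 0, dropout >= 0, dropout < 1,
            epochs >= 1, lr_decay_factor > 0, lr_decay_every >= 1,
            epochs >= lr_decay_every)
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, dropout = dropout,
                 epochs = as.integer(epochs), optimizer = optimizer,
                 class_weight = class_weight,
                 class_weight_range = c(-1, 1),
                 target_size = as.integer(target_size),
                 random_seed = as.integer(random_seed), loss = loss,
                 lr_decay_factor = lr_decay_factor,
                 lr_decay_every = as.integer(lr_decay_every)),
            class = "train_config")
}

#' Split plan
#'
#' @param train_frac,val_frac,test_frac partition fractions in (0, 1)
#'   summing to 1 (default 60/20/20).
#' @param n_folds folds for cross-validation assignment.
#' @param seed shuffling seed.
#' @return A `split_plan` object.
#' @export
split_plan <- function(train_frac = 0.6, val_frac = 0.2, test_frac = 0.2,
                       n_folds = 5L, seed = 42L) {
  stopifnot(train_frac > 0, val_frac > 0, test_frac > 0,
            abs(train_frac + val_frac + test_frac - 1) < 1e-9, n_folds >= 2)
  structure(list(train_frac = train_frac, val_frac = val_frac,
                 test_frac = test_frac, n_folds = as.integer(n_folds),
                 seed = as.integer(seed)),
            class = "split_plan")
}

#' Stratified train/validation/test and fold assignment
#'
#' Items are shuffled within each class and dealt into train, validation
#' and test partitions at the plan's fractions (rounding by at most one
#' item per class), plus a stratified fold index for k-fold
#' cross-validation. The assignment is a pure function of (labels, plan).
#'
#' @param labels integer class labels (one per item).
#' @param plan a [split_plan()].
#' @return data.frame with `index`, `label`, `split` ("train", "val",
#'   "test") and `fold` (1..n_folds); each item belongs to exactly one
#'   split and one fold.
#' @export
make_splits <- function(labels, plan = split_plan()) {
  stopifnot(inherits(plan, "split_plan"), length(labels) >= plan$n_folds)
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(plan$seed)
  out <- data.frame(index = seq_along(labels), label = labels,
                    split = NA_character_, fold = NA_integer_)
  for (cl in sort(unique(labels))) {
    idx <- sample(which(labels == cl))
    n <- length(idx)
    n_tr <- round(plan$train_frac * n)
    n_va <- round(plan$val_frac * n)
    if (n_tr + n_va > n) n_va <- n - n_tr
    split <- rep("test", n)
    split[seq_len(n_tr)] <- "train"
    if (n_va > 0) split[n_tr + seq_len(n_va)] <- "val"
    out$split[idx] <- split
    out$fold[idx] <- rep_len(seq_len(plan$n_folds), n)
  }
  for (s in c("train", "val", "test"))
    for (cl in unique(labels))
      if (!any(out$split == s & out$label == cl))
        stop("class ", cl, " absent from the ", s, " partition; ",
             "use more items or different fractions")
  out
}

#' Step learning-rate schedule
#'
#' `lr(epoch) = learning_rate * lr_decay_factor ^ floor(epoch /
#' lr_decay_every)` with `epoch` counted from 0: the rate drops by the
#' decay factor after every `lr_decay_every` epochs.
#'
#' @param epoch 0-based epoch index, below `cfg$epochs`.
#' @param cfg a [train_config()].
#' @return The learning rate for that epoch.
#' @export
lr_schedule <- function(epoch, cfg = train_config()) {
  stopifnot(epoch >= 0, epoch < cfg$epochs)
  cfg$learning_rate * cfg$lr_decay_factor^(epoch %/% cfg$lr_decay_every)
}

.class_weights <- function(y, policy) {
  if (policy == "none") return(setNames(rep(1, length(unique(y))),
                                        sort(unique(y))))
  tab <- table(y)
  w <- length(y) / (length(tab) * as.numeric(tab))
  w <- w / mean(w)
  setNames(w, names(tab))
}

# Random on-the-fly batch augmentation: small rotations, shifts and flips.
.augment_batch <- function(xb, max_rot = 20, max_shift_frac = 0.1) {
  d <- dim(xb)
  for (n in seq_len(d[4])) {
    ang <- runif(1, -max_rot, max_rot)
    bx <- sample.int(2L * floor(max_shift_frac * d[2]) + 1L, 1L) -
      floor(max_shift_frac * d[2]) - 1L
    my <- sample.int(2L * floor(max_shift_frac * d[1]) + 1L, 1L) -
      floor(max_shift_frac * d[1]) - 1L
    fh <- runif(1) < 0.5
    for (c in seq_len(d[3])) {
      pl <- .rotate_fit_plane(xb[, , c, n], ang, d[1], d[2])
      pl <- .translate_plane(pl, bx, my)
      if (fh) pl <- .flip_h(pl)
      xb[, , c, n] <- pl
    }
  }
  xb
}

.weighted_ce <- function(probs, y, sample_w) {
  p <- probs[cbind(y + 1L, seq_len(ncol(probs)))]
  sum(sample_w * -log(pmax(p, 1e-12))) / sum(sample_w)
}

#' Train a classifier on a labeled image tensor
#'
#' Minibatch AdaGrad on the sparse categorical cross-entropy with
#' inverse-frequency class weights, the step learning-rate schedule of
#' [lr_schedule()], and per-epoch train/validation loss and accuracy
#' history. Aborts with the epoch index if the loss turns non-finite.
#'
#' @param spec a [network_spec()]; its input shape must match `x`.
#' @param x `H x W x C x N` input tensor.
#' @param y integer labels (0-based classes), length `N`.
#' @param cfg a [train_config()].
#' @param train_idx,val_idx 1-based item indices of the training and
#'   validation partitions (e.g. from [make_splits()]).
#' @param online_augment apply random rotations/shifts/flips to each
#'   training batch.
#' @param verbose print one line per epoch.
#' @return An `mc_fit` list: `model` (trained `mc_model`), `history`
#'   (data.frame: epoch, lr, train_loss, train_acc, val_loss, val_acc),
#'   `cfg`, `class_weights`.
#' @export
train_model <- function(spec, x, y, cfg = train_config(), train_idx,
                        val_idx = integer(0), online_augment = FALSE,
                        verbose = FALSE) {
  stopifnot(inherits(spec, "network_spec"), length(dim(x)) == 4L,
            dim(x)[4] == length(y), all(y %in% 0:(spec$n_classes - 1L)))
  if (!all(dim(x)[1:3] == spec$input_shape))
    stop("input tensor shape ", paste(dim(x)[1:3], collapse = "x"),
         " does not match the network input shape ",
         paste(spec$input_shape, collapse = "x"))
  model <- init_network(spec, seed = cfg$random_seed)
  state <- vector("list", length(model$layers))
  cw <- .class_weights(y[train_idx], cfg$class_weight)
  hist_rows <- vector("list", cfg$epochs)
  set.seed(cfg$random_seed + 1L)
  for (epoch in seq_len(cfg$epochs)) {
    lr <- lr_schedule(epoch - 1L, cfg)
    idx <- sample(train_idx)
    nb <- ceiling(length(idx) / cfg$batch_size)
    tr_loss <- 0
    tr_correct <- 0
    for (b in seq_len(nb)) {
      bi <- idx[((b - 1L) * cfg$batch_size + 1L):
                  min(b * cfg$batch_size, length(idx))]
      xb <- x[, , , bi, drop = FALSE]
      if (online_augment) xb <- .augment_batch(xb)
      yb <- y[bi]
      sw <- as.numeric(cw[as.character(yb)])
      fw <- .forward(model, xb, training = TRUE)
      model <- fw$model
      loss <- .weighted_ce(fw$probs, yb, sw)
      if (!is.finite(loss))
        stop("training diverged (non-finite loss) at epoch ", epoch)
      grads <- .backward(model, fw$caches, fw$probs, yb, sw)
      up <- .adagrad_update(model, grads, state, lr)
      model <- up$model
      state <- up$state
      tr_loss <- tr_loss + loss * length(bi)
      tr_correct <- tr_correct +
        sum(max.col(t(fw$probs)) - 1L == yb)
    }
    # re-estimate batch-norm population moments on (a subset of) the
    # training data with the epoch's final weights, so inference-mode
    # statistics reflect the trained network rather than a lagging
    # exponential average
    cal_idx <- train_idx[seq_len(min(length(train_idx), 256L))]
    model <- .forward(model, x[, , , cal_idx, drop = FALSE],
                      training = TRUE, bn_momentum = 0,
                      dropout_on = FALSE)$model
    row <- data.frame(epoch = epoch, lr = lr,
                      train_loss = tr_loss / length(idx),
                      train_acc = tr_correct / length(idx),
                      val_loss = NA_real_, val_acc = NA_real_)
    if (length(val_idx) > 0L) {
      pv <- .forward(model, x[, , , val_idx, drop = FALSE],
                     training = FALSE)$probs
      swv <- as.numeric(cw[as.character(y[val_idx])])
      row$val_loss <- .weighted_ce(pv, y[val_idx], swv)
      row$val_acc <- mean(max.col(t(pv)) - 1L == y[val_idx])
    }
    hist_rows[[epoch]] <- row
    if (verbose)
      message(sprintf(
        "epoch %2d lr %.2g train loss %.4f acc %.3f val loss %s acc %s",
        epoch, lr, row$train_loss, row$train_acc,
        format(row$val_loss, digits = 4), format(row$val_acc, digits = 3)))
  }
  structure(list(model = model, history = do.call(rbind, hist_rows),
                 cfg = cfg, class_weights = cw),
            class = "mc_fit")
}
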