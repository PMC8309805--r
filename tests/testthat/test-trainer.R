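test_that("the learning-rate schedule steps down every five epochs", {
  cfg <- train_config()
  expect_equal(lr_schedule(0, cfg), 0.001)
  expect_equal(lr_schedule(4, cfg), 0.001)
  expect_equal(lr_schedule(5, cfg), 1e-4)
  expect_equal(lr_schedule(19, cfg), 0.001 * 0.1^3)
  # non-increasing, piecewise constant with breaks at multiples of 5
  lrs <- vapply(0:19, lr_schedule, 0, cfg = cfg)
  expect_true(all(diff(lrs) <= 0))
  expect_equal(unique(lrs), 0.001 * 0.1^(0:3))
  expect_error(lr_schedule(20, cfg))
  expect_error(train_config(epochs = 3, lr_decay_every = 5))
})

test_that("splits are stratified, exhaustive and reproducible", {
  labels <- c(rep(0L, 70), rep(1L, 30))
  plan <- split_plan(seed = 1L)
  s <- make_splits(labels, plan)
  expect_equal(nrow(s), 100L)
  expect_equal(sum(s$split == "train"), 60L)
  expect_equal(sum(s$split == "val"), 20L)
  expect_equal(sum(s$split == "test"), 20L)
  # per-class 60/20/20 within one item
  for (cl in 0:1) {
    n_cl <- sum(labels == cl)
    for (frac_split in list(c(0.6, "train"), c(0.2, "val"), c(0.2, "test")))
      expect_lte(abs(sum(s$split == frac_split[2] & s$label == cl) -
                       as.numeric(frac_split[1]) * n_cl), 1)
  }
  expect_identical(make_splits(labels, plan), s)
  expect_false(identical(make_splits(labels, split_plan(seed = 2L))$split,
                         s$split))
})

test_that("five folds partition fifty items exactly once each", {
  labels <- rep(0:1, 25)
  s <- make_splits(labels, split_plan(n_folds = 5L, seed = 3L))
  expect_true(all(s$fold %in% 1:5))
  expect_true(all(table(s$fold) == 10L))
  # every item has exactly one fold assignment
  expect_false(any(is.na(s$fold)))
  # folds are label-stratified
  expect_true(all(table(s$fold, s$label) == 5L))
})

test_that("degenerate splits that lose a class are refused", {
  labels <- c(rep(0L, 50), 1L, 1L)   # 2 positives cannot fill 3 partitions
  expect_error(make_splits(labels, split_plan(seed = 1L)), "absent")
})

test_that("training history bookkeeping records every epoch", {
  set.seed(50)
  n <- 32
  x <- array(runif(8 * 8 * 3 * n), c(8, 8, 3, n))
  y <- rep(0:1, n / 2)
  spec <- build_fc_dscnn(c(8L, 8L, 3L))
  cfg <- train_config(epochs = 6, batch_size = 16)
  fit <- train_model(spec, x, y, cfg, train_idx = 1:24, val_idx = 25:32)
  expect_equal(nrow(fit$history), 6L)
  expect_true(all(is.finite(fit$history$train_loss)))
  expect_true(all(is.finite(fit$history$val_loss)))
  # rate holds for five epochs, then steps down by the decay factor
  expect_equal(fit$history$lr, c(rep(0.001, 5), 0.001 * 0.1))
  p <- predict_proba(fit$model, x)
  expect_equal(dim(p), c(n, 2L))
  expect_equal(rowSums(p), rep(1, n), tolerance = 1e-9)
})

test_that("a linearly separable toy problem is learned to accuracy 1", {
  set.seed(51)
  n <- 64
  x <- array(0, c(12, 16, 3, n))
  y <- rep(0:1, each = n / 2)
  for (i in 1:n) x[, , , i] <- runif(12 * 16 * 3, 0, 0.4) + 0.5 * y[i]
  spec <- build_fc_dscnn(c(12L, 16L, 3L))
  fit <- train_model(spec, x, y, train_config(epochs = 10, batch_size = 16),
                     train_idx = 1:n)
  p <- predict_proba(fit$model, x)
  expect_equal(mean((p[, 2] > 0.5) == y), 1.0)
  # loss decreases over the first five epochs (one slack step allowed)
  d <- diff(fit$history$train_loss[1:5])
  expect_lte(sum(d >= 0), 1L)
})

test_that("mismatched input tensors and divergence are reported", {
  x <- array(runif(6 * 6 * 3 * 8), c(6, 6, 3, 8))
  y <- rep(0:1, 4)
  spec <- build_fc_dscnn(c(12L, 16L, 3L))
  expect_error(train_model(spec, x, y, train_config(epochs = 5),
                           train_idx = 1:8),
               "does not match")
})

test_that("the DCNN baseline trains through the same interface", {
  set.seed(52)
  n <- 32
  x <- array(0, c(8, 8, 3, n))
  y <- rep(0:1, n / 2)
  for (i in 1:n) x[, , , i] <- runif(192, 0, 0.4) + 0.5 * y[i]
  spec <- build_dcnn(c(8L, 8L, 3L))
  fit <- train_model(spec, x, y, train_config(epochs = 6, batch_size = 16),
                     train_idx = 1:n)
  p <- predict_proba(fit$model, x)
  expect_gte(mean((p[, 2] > 0.5) == y), 0.9)
})

test_that("class weighting balances an imbalanced loss", {
  w <- mammocad:::.class_weights(c(0, 0, 0, 0, 1), "balanced")
  expect_equal(mean(w), 1)
  expect_gt(w[["1"]], w[["0"]])
  expect_equal(as.numeric(w[["1"]] / w[["0"]]), 4)
  w2 <- mammocad:::.class_weights(c(0, 1), "none")
  expect_true(all(w2 == 1))
})

test_that("backpropagation gradients match finite differences", {
  set.seed(2)
  spec <- network_spec("tiny", c(6L, 8L, 3L), list(
    layer_spec("separable_conv", n_filters = 4L, activation = "relu"),
    layer_spec("batch_norm"),
    layer_spec("max_pool", kernel = c(2L, 2L), stride = c(2L, 2L)),
    layer_spec("conv2d", n_filters = 5L, activation = "relu"),
    layer_spec("batch_norm"),
    layer_spec("flatten"),
    layer_spec("dense", units = 7L, activation = "relu"),
    layer_spec("softmax", units = 2L)), n_classes = 2L)
  model <- init_network(spec, seed = 3)
  n <- 4
  x <- array(rnorm(6 * 8 * 3 * n), c(6, 8, 3, n))
  y <- c(0L, 1L, 1L, 0L)
  sw <- rep(1, n)
  lossfn <- function(m)
    mammocad:::.weighted_ce(mammocad:::.forward(m, x,
                                                training = TRUE)$probs,
                            y, sw)
  fw <- mammocad:::.forward(model, x, training = TRUE)
  gr <- mammocad:::.backward(fw$model, fw$caches, fw$probs, y, sw)
  eps <- 1e-6
  for (li in seq_along(model$layers)) {
    g <- gr[[li]]
    if (is.null(g) || length(g) == 0) next
    for (nm in names(g)) {
      arr <- model$layers[[li]][[nm]]
      for (ii in sample(length(arr), min(3, length(arr)))) {
        m2 <- model
        m2$layers[[li]][[nm]][ii] <- arr[ii] + eps
        m3 <- model
        m3$layers[[li]][[nm]][ii] <- arr[ii] - eps
        num <- (lossfn(m2) - lossfn(m3)) / (2 * eps)
        ana <- g[[nm]][ii]
        expect_lt(abs(num - ana) / max(1e-8, abs(num) + abs(ana)), 1e-4)
      }
    }
  }
})
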