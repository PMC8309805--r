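test_that("confusion tallies match hand counts and the loop oracle", {
  cc <- confusion_from_predictions(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(c(cc$TP, cc$TN, cc$FP, cc$FN), c(2L, 2L, 0L, 0L))
  cc2 <- confusion_from_predictions(c(1, 0), c(0, 1))
  expect_equal(c(cc2$TP, cc2$FN, cc2$FP, cc2$TN), c(0L, 1L, 1L, 0L))
  set.seed(10)
  yt <- rbinom(200, 1, 0.4)
  yp <- rbinom(200, 1, 0.5)
  cc3 <- confusion_from_predictions(yt, yp)
  want <- oracle_confusion(yt, yp)
  expect_equal(c(cc3$TP, cc3$TN, cc3$FP, cc3$FN),
               as.integer(want[c("TP", "TN", "FP", "FN")]))
  expect_error(confusion_from_predictions(c(1, 0), c(1)), "length")
})

test_that("rate metrics implement their defining ratios", {
  expect_equal(sensitivity(confusion_counts(9, 0, 0, 1)), 0.9)
  expect_equal(sensitivity(confusion_counts(760, 0, 0, 0)), 1.0)
  expect_equal(fpi(confusion_counts(0, 6, 0, 0, N = 6)), 0)
  expect_equal(fpi(confusion_counts(0, 0, 12, 1, N = 6)), 2)
  expect_equal(fpi(confusion_counts(10, 5, 49, 2, N = 20)), 2.45)
  expect_equal(accuracy(confusion_counts(5, 5, 0, 0)), 1.0)
  expect_equal(accuracy(confusion_counts(25, 25, 25, 25)), 0.5)
  expect_equal(accuracy(confusion_counts(30, 50, 10, 10)), 0.8)
  expect_error(sensitivity(confusion_counts(0, 5, 3, 0)), "undefined")
})

test_that("metric identities hold on random confusion tables", {
  set.seed(77)
  for (i in 1:1000) {
    tp <- sample(0:50, 1); fn <- sample(0:50, 1)
    tn <- sample(0:50, 1); fp <- sample(0:50, 1)
    if (tp + fn == 0 || tn + fp == 0) next
    cc <- confusion_counts(tp, tn, fp, fn)
    # sensitivity + miss rate = 1
    expect_equal(sensitivity(cc) + fn / (tp + fn), 1, tolerance = 1e-12)
    # accuracy is the prevalence-weighted mix of sensitivity and specificity
    prev <- (tp + fn) / (tp + fn + tn + fp)
    expect_equal(accuracy(cc),
                 prev * sensitivity(cc) + (1 - prev) * specificity(cc),
                 tolerance = 1e-12)
    expect_equal(fpi(cc), fp / cc$N, tolerance = 1e-12)
  }
})

test_that("threshold-sweep AUC equals the pair-counting oracle", {
  set.seed(5)
  for (i in 1:200) {
    n <- sample(6:25, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))      # both classes present
    s <- round(runif(n), sample(c(1, 2, 7), 1))  # induce ties sometimes
    expect_equal(auc_roc(y, s), oracle_auc_pairs(y, s), tolerance = 1e-12)
  }
})

test_that("AUC endpoints behave for separated and uninformative scores", {
  y <- c(0, 0, 0, 1, 1, 1)
  expect_equal(auc_roc(y, c(0.1, 0.2, 0.3, 0.7, 0.8, 0.9)), 1.0)
  expect_equal(auc_roc(y, rep(0.5, 6)), 0.5)
  rep_ <- full_report(y, c(0.1, 0.2, 0.3, 0.7, 0.8, 0.9))
  expect_equal(rep_$auc, 1.0)
  expect_equal(rep_$f1, 1.0)
  expect_error(roc_curve(c(1, 1, 1), c(0.2, 0.5, 0.7)), "single class")
})

test_that("full_report is consistent with thresholded confusion counts", {
  set.seed(12)
  y <- rbinom(40, 1, 0.5)
  s <- runif(40)
  rep_ <- full_report(y, s, threshold = 0.5)
  cc <- confusion_from_predictions(y, as.integer(s > 0.5))
  expect_equal(rep_$sensitivity, sensitivity(cc))
  expect_equal(rep_$specificity, specificity(cc))
  expect_equal(rep_$accuracy, accuracy(cc))
  expect_equal(rep_$recall, rep_$sensitivity)  # one number for both columns
  expect_equal(rep_$fpi, fpi(cc))
  p <- precision(cc)
  expect_equal(rep_$f1, 2 * p * rep_$recall / (p + rep_$recall))

  # degenerate single-class truth: AUC NA, defined metrics kept
  rep0 <- full_report(rep(0, 10), runif(10))
  expect_true(is.na(rep0$auc))
  expect_true(is.na(rep0$sensitivity))
  expect_false(is.na(rep0$specificity))
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(31)
  y <- rbinom(60, 1, 0.45)
  s <- pmin(pmax(rnorm(60, 0.4 + 0.3 * y, 0.2), 0), 1)
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                        direction = "<")))
  expect_equal(auc_roc(y, s), ref, tolerance = 1e-12)
})

test_that("choose_threshold places a sensitivity-first operating point", {
  y <- c(rep(1, 10), rep(0, 10))
  s <- c(seq(0.35, 0.9, length.out = 10), seq(0.05, 0.6, length.out = 10))
  thr <- choose_threshold(y, s, target_sensitivity = 0.95)
  # all but at most 5% of positives score above the chosen threshold
  expect_gte(mean(s[y == 1] > thr), 0.95)
  # it is the HIGHEST such threshold: nudging it up loses the target
  expect_lt(mean(s[y == 1] > thr + 0.06), 0.95)
  # degenerate: no threshold reaches the target -> fallback 0.5
  expect_equal(choose_threshold(c(1, 0), c(0.2, 0.9),
                                target_sensitivity = 1), 0.5)
})
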