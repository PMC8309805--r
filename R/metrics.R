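# Imagewise evaluation. Positive class = malignant (label 1). Rates:
#   sensitivity (= recall) = TP / (TP + FN)
#   specificity            = TN / (TN + FP)
#   precision              = TP / (TP + FP)
#   accuracy               = (TP + TN) / (TP + TN + FP + FN)
#   FPi (false positives per image) = FP / N, N = images evaluated
# Undefined ratios (zero denominators) raise errors from the scalar
# functions; full_report() reports NA for the metrics that are undefined
# and keeps the rest.

#' Confusion counts from paired label vectors
#'
#' Tallies TP/TN/FP/FN with 1 = malignant as the positive class, plus the
#' number of evaluated images `N` used by [fpi()].
#'
#' @param y_true,y_pred equal-length 0/1 label vectors.
#' @param n_images number of images the predictions cover; defaults to
#'   `length(y_true)` (one prediction per image).
#' @return A `confusion_counts` object (fields TP, TN, FP, FN, N).
#' @export
confusion_from_predictions <- function(y_true, y_pred,
                                       n_images = length(y_true)) {
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred have different lengths")
  stopifnot(all(y_true %in% 0:1), all(y_pred %in% 0:1), n_images >= 1)
  confusion_counts(TP = sum(y_true == 1 & y_pred == 1),
                   TN = sum(y_true == 0 & y_pred == 0),
                   FP = sum(y_true == 0 & y_pred == 1),
                   FN = sum(y_true == 1 & y_pred == 0),
                   N = n_images)
}

#' Confusion count container
#'
#' @param TP,TN,FP,FN non-negative integer tallies.
#' @param N positive count of evaluated images.
#' @return A `confusion_counts` object.
#' @export
confusion_counts <- function(TP, TN, FP, FN, N = TP + TN + FP + FN) {
  stopifnot(TP >= 0, TN >= 0, FP >= 0, FN >= 0, N >= 1)
  structure(list(TP = as.integer(TP), TN = as.integer(TN),
                 FP = as.integer(FP), FN = as.integer(FN),
                 N = as.integer(N)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP=%d TN=%d FP=%d FN=%d N=%d\n",
              x$TP, x$TN, x$FP, x$FN, x$N))
  invisible(x)
}

#' Sensitivity (true-positive rate)
#'
#' `TP / (TP + FN)`; identical to recall.
#'
#' @param c a [confusion_counts()].
#' @return Sensitivity in `[0, 1]`.
#' @export
sensitivity <- function(c) {
  if (c$TP + c$FN == 0)
    stop("sensitivity undefined: no positive ground-truth instances")
  c$TP / (c$TP + c$FN)
}

#' Specificity (true-negative rate)
#'
#' `TN / (TN + FP)`.
#'
#' @inheritParams sensitivity
#' @return Specificity in `[0, 1]`.
#' @export
specificity <- function(c) {
  if (c$TN + c$FP == 0)
    stop("specificity undefined: no negative ground-truth instances")
  c$TN / (c$TN + c$FP)
}

#' Precision (positive predictive value)
#'
#' `TP / (TP + FP)`.
#'
#' @inheritParams sensitivity
#' @return Precision in `[0, 1]`.
#' @export
precision <- function(c) {
  if (c$TP + c$FP == 0)
    stop("precision undefined: no positive predictions")
  c$TP / (c$TP + c$FP)
}

#' False positives per image
#'
#' `FPi = FP / N` where `N` is the number of evaluated images.
#'
#' @inheritParams sensitivity
#' @return Non-negative rate.
#' @export
fpi <- function(c) c$FP / c$N

#' Accuracy
#'
#' `(TP + TN) / (TP + TN + FP + FN)`.
#'
#' @inheritParams sensitivity
#' @return Accuracy in `[0, 1]`.
#' @export
accuracy <- function(c) {
  tot <- c$TP + c$TN + c$FP + c$FN
  if (tot == 0) stop("accuracy undefined: no classified instances")
  (c$TP + c$TN) / tot
}

#' ROC curve by threshold sweep
#'
#' Sweeps the decision threshold over the unique scores (descending) and
#' returns the (FPR, TPR) staircase, including the (0,0) and (1,1)
#' endpoints. Tied scores move diagonally, so an uninformative constant
#' score yields the chance diagonal.
#'
#' @param y_true 0/1 labels with both classes present.
#' @param scores class-1 probabilities in `[0, 1]`.
#' @return data.frame with `threshold`, `fpr`, `tpr`.
#' @export
roc_curve <- function(y_true, scores) {
  stopifnot(length(y_true) == length(scores), all(y_true %in% 0:1))
  n_pos <- sum(y_true == 1)
  n_neg <- sum(y_true == 0)
  if (n_pos == 0 || n_neg == 0)
    stop("ROC undefined: y_true contains a single class")
  ord <- order(scores, decreasing = TRUE)
  ys <- y_true[ord]
  ss <- scores[ord]
  keep <- c(diff(ss) != 0, TRUE)   # last index of each tied block
  tpr <- cumsum(ys == 1)[keep] / n_pos
  fpr <- cumsum(ys == 0)[keep] / n_neg
  data.frame(threshold = c(Inf, ss[keep]), fpr = c(0, fpr),
             tpr = c(0, tpr))
}

#' Area under the ROC curve (trapezoidal)
#'
#' @inheritParams roc_curve
#' @return AUC in `[0, 1]`.
#' @export
auc_roc <- function(y_true, scores) {
  rc <- roc_curve(y_true, scores)
  sum(diff(rc$fpr) * (head(rc$tpr, -1) + rc$tpr[-1]) / 2)
}

#' Full evaluation report
#'
#' Thresholds the scores, tallies the confusion counts and reports
#' sensitivity, specificity, accuracy, F1, precision, recall (= the
#' sensitivity value), FPi and trapezoidal AUC. Metrics whose denominator
#' is empty are reported as `NA`; in particular the AUC of a single-class
#' truth vector is `NA` while the defined metrics are kept.
#'
#' @param y_true 0/1 labels.
#' @param scores class-1 probabilities in `[0, 1]`.
#' @param threshold decision threshold in (0, 1); a score above it
#'   predicts class 1.
#' @param n_images images evaluated (defaults to one per score).
#' @return A `metrics_report` (list) with the metric fields plus the
#'   underlying `counts`.
#' @export
full_report <- function(y_true, scores, threshold = 0.5,
                        n_images = length(y_true)) {
  stopifnot(all(scores >= 0), all(scores <= 1), threshold > 0,
            threshold < 1)
  y_pred <- as.integer(scores > threshold)
  cc <- confusion_from_predictions(y_true, y_pred, n_images)
  safe <- function(f) tryCatch(f(cc), error = function(e) NA_real_)
  sens <- safe(sensitivity)
  spec <- safe(specificity)
  prec <- safe(precision)
  f1 <- if (is.na(prec) || is.na(sens) || prec + sens == 0) NA_real_
        else 2 * prec * sens / (prec + sens)
  auc <- tryCatch(auc_roc(y_true, scores), error = function(e) NA_real_)
  structure(list(sensitivity = sens, specificity = spec,
                 accuracy = safe(accuracy), f1 = f1, precision = prec,
                 recall = sens, fpi = fpi(cc), auc = auc, counts = cc),
            class = "metrics_report")
}

#' Choose a sensitivity-first operating threshold
#'
#' Screening CAD systems run at an operating point that favours
#' sensitivity (missing a cancer costs far more than a recall). This
#' returns the highest decision threshold whose sensitivity on the given
#' (typically training) scores reaches `target_sensitivity`; applying it
#' to held-out data gives the deployed operating point. Falls back to 0.5
#' when no threshold reaches the target.
#'
#' @param y_true 0/1 labels of the calibration scores.
#' @param scores class-1 probabilities of the calibration set.
#' @param target_sensitivity sensitivity to reach on the calibration set.
#' @return A threshold in (0, 1).
#' @export
choose_threshold <- function(y_true, scores, target_sensitivity = 0.95) {
  stopifnot(length(y_true) == length(scores), any(y_true == 1))
  cand <- sort(unique(scores), decreasing = TRUE)
  pos <- scores[y_true == 1]
  for (t in cand) if (mean(pos > t) >= target_sensitivity)
    return(min(max(t, 1e-6), 1 - 1e-6))
  0.5
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report>\n")
  for (nm in c("sensitivity", "specificity", "accuracy", "f1", "precision",
               "recall", "fpi", "auc"))
    cat(sprintf("  %-12s %s\n", nm, format(x[[nm]], digits = 4)))
  invisible(x)
}
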