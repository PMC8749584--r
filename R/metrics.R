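#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a randomly chosen positive
#' outscores a randomly chosen negative, with ties counted half. Computed
#' via mid-ranks, which equals the trapezoidal area under the empirical ROC
#' curve.
#'
#' @param labels Integer/logical vector of 0/1 outcomes.
#' @param scores Numeric scores, higher = more positive.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(labels, scores) {
  labels <- as.integer(labels)
  stopifnot(length(labels) == length(scores), all(labels %in% c(0L, 1L)))
  if (any(!is.finite(scores))) stop("auroc: scores must be finite")
  n1 <- as.numeric(sum(labels == 1L))
  n0 <- as.numeric(sum(labels == 0L))
  if (n1 == 0L || n0 == 0L)
    stop("auroc: both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Threshold metrics plus AUROC for one model on one split
#'
#' Predicts positive iff `score >= threshold`, then reports the confusion
#' counts and the six headline metrics. When no positives are predicted,
#' precision is reported as 0 with `precision_undefined = TRUE`.
#'
#' @param labels Integer/logical 0/1 outcomes.
#' @param scores Numeric scores in `[0, 1]`.
#' @param threshold Decision threshold in `[0, 1]` (default 0.5).
#' @return An object of class `triage_metrics` with `sensitivity`,
#'   `specificity`, `precision`, `f1`, `accuracy`, `auroc`, `threshold`, the
#'   counts `tp`/`fp`/`tn`/`fn`, and `precision_undefined`.
#' @export
confusion_metrics <- function(labels, scores, threshold = 0.5) {
  labels <- as.integer(labels)
  stopifnot(length(labels) == length(scores), all(labels %in% c(0L, 1L)),
            threshold >= 0, threshold <= 1)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & labels == 1L)
  fp <- sum(pred == 1L & labels == 0L)
  tn <- sum(pred == 0L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  sens <- if (tp + fn > 0L) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0L) tn / (tn + fp) else NA_real_
  prec_undef <- (tp + fp) == 0L
  prec <- if (prec_undef) 0 else tp / (tp + fp)
  f1 <- if (!is.na(sens) && (prec + sens) > 0) 2 * prec * sens / (prec + sens) else 0
  acc <- (tp + tn) / length(labels)
  structure(list(sensitivity = sens, specificity = spec, precision = prec,
                 f1 = f1, accuracy = acc, auroc = auroc(labels, scores),
                 threshold = threshold, tp = tp, fp = fp, tn = tn, fn = fn,
                 precision_undefined = prec_undef),
            class = "triage_metrics")
}

#' @export
print.triage_metrics <- function(x, ...) {
  cat(sprintf(
    "triage_metrics (threshold %.3f)\n  sensitivity %.3f  specificity %.3f  precision %.3f%s\n  F1 %.3f  accuracy %.3f  AUROC %.3f\n  counts: TP %d  FP %d  TN %d  FN %d\n",
    x$threshold, x$sensitivity, x$specificity, x$precision,
    if (x$precision_undefined) " (no predicted positives)" else "",
    x$f1, x$accuracy, x$auroc, x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' Youden-optimal threshold
#'
#' Threshold maximizing sensitivity + specificity - 1 over the observed
#' scores; used when model selection asks for a validation-tuned operating
#' point instead of the default 0.5.
#'
#' @inheritParams auroc
#' @return A threshold value.
#' @export
youden_threshold <- function(labels, scores) {
  labels <- as.integer(labels)
  cand <- sort(unique(scores))
  j <- vapply(cand, function(th) {
    pred <- scores >= th
    sens <- sum(pred & labels == 1L) / sum(labels == 1L)
    spec <- sum(!pred & labels == 0L) / sum(labels == 0L)
    sens + spec - 1
  }, numeric(1))
  cand[which.max(j)]
}
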