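# Nine-metric evaluation suite for binary synergy classification.
#
# ACC, BACC, Prec, Rec, F1, MCC and Cohen's kappa come from the 2x2
# confusion table; ROC-AUC is the rank (Mann-Whitney) statistic; AP is the
# uninterpolated threshold-sweep sum. Degenerate denominators follow the
# package convention: 0 for Prec/Rec/F1/TPR/TNR/MCC/Kappa when undefined,
# which keeps skewed leave-one-out folds evaluable.

#' Confusion counts
#'
#' @param yTrue,yPred binary 0/1 label vectors of equal length.
#' @return Named integer vector `TP`, `TN`, `FP`, `FN`.
#' @export
confusionCounts <- function(yTrue, yPred) {
  if (length(yTrue) != length(yPred)) {
    stop("yTrue and yPred differ in length", call. = FALSE)
  }
  if (length(yTrue) < 1L) stop("empty input", call. = FALSE)
  if (!all(yTrue %in% c(0, 1)) || !all(yPred %in% c(0, 1))) {
    stop("labels must be 0 or 1", call. = FALSE)
  }
  c(TP = sum(yTrue == 1 & yPred == 1),
    TN = sum(yTrue == 0 & yPred == 0),
    FP = sum(yTrue == 0 & yPred == 1),
    FN = sum(yTrue == 1 & yPred == 0))
}

safe_div <- function(num, den) if (den == 0) 0 else num / den

#' Threshold metrics from confusion counts
#'
#' Computes ACC, BACC = (TPR + TNR)/2, precision, recall, F1, MCC and
#' Cohen's kappa. Kappa's chance agreement uses the actual class counts
#' a_c and predicted class counts b_c: P_e = (a1*b1 + a0*b0) / n^2.
#'
#' @param counts named vector with `TP`, `TN`, `FP`, `FN`.
#' @return Named numeric vector `ACC`, `BACC`, `Prec`, `Rec`, `F1`, `MCC`,
#'   `Kappa`.
#' @examples
#' thresholdMetrics(c(TP = 6, TN = 3, FP = 1, FN = 2))
#' @export
thresholdMetrics <- function(counts) {
  tp <- as.numeric(counts[["TP"]]); tn <- as.numeric(counts[["TN"]])
  fp <- as.numeric(counts[["FP"]]); fn <- as.numeric(counts[["FN"]])
  n <- tp + tn + fp + fn
  if (n < 1) stop("empty confusion table", call. = FALSE)
  acc <- (tp + tn) / n
  tpr <- safe_div(tp, tp + fn)
  tnr <- safe_div(tn, tn + fp)
  prec <- safe_div(tp, tp + fp)
  rec <- tpr
  f1 <- safe_div(2 * tp, 2 * tp + fp + fn)
  mcc_den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (mcc_den == 0) 0 else (tp * tn - fp * fn) / sqrt(mcc_den)
  pe <- ((tp + fn) * (tp + fp) + (tn + fp) * (tn + fn)) / (n * n)
  kappa <- if (pe == 1) 0 else (acc - pe) / (1 - pe)
  c(ACC = acc, BACC = (tpr + tnr) / 2, Prec = prec, Rec = rec, F1 = f1,
    MCC = mcc, Kappa = kappa)
}

#' ROC-AUC by the rank statistic
#'
#' The fraction of (positive, negative) pairs whose scores are correctly
#' ordered, counting ties as 1/2 — computed via midranks, which is exact and
#' tie-robust.
#'
#' @param yTrue binary labels; both classes must be present.
#' @param probs numeric scores.
#' @return AUC in \[0, 1\].
#' @export
rocAuc <- function(yTrue, probs) {
  stopifnot(length(yTrue) == length(probs))
  npos <- sum(yTrue == 1); nneg <- sum(yTrue == 0)
  if (npos == 0L || nneg == 0L) {
    stop("ROC-AUC undefined with a single class", call. = FALSE)
  }
  r <- rank(probs, ties.method = "average")
  (sum(r[yTrue == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Average precision (uninterpolated)
#'
#' Sum over descending-score thresholds of (R_n - R_{n-1}) * P_n, with
#' precision and recall evaluated after each distinct score value; no
#' interpolation is applied.
#'
#' @param yTrue binary labels; at least one positive required.
#' @param probs numeric scores.
#' @return AP in \[0, 1\].
#' @export
averagePrecision <- function(yTrue, probs) {
  stopifnot(length(yTrue) == length(probs))
  npos <- sum(yTrue == 1)
  if (npos == 0L) stop("average precision undefined without positives",
                       call. = FALSE)
  o <- order(probs, decreasing = TRUE)
  y <- yTrue[o]; p <- probs[o]
  cum_tp <- cumsum(y == 1)
  k <- seq_along(y)
  # evaluate only at the last index of each distinct score (tie groups)
  last <- which(c(p[-1] != p[-length(p)], TRUE))
  recall <- cum_tp[last] / npos
  precision <- cum_tp[last] / k[last]
  sum(diff(c(0, recall)) * precision)
}

#' Full nine-metric report from probabilities
#'
#' Binarizes at `threshold` (boundary assigned to the positive class),
#' computes the confusion-derived metrics plus ROC-AUC and AP, and returns a
#' [MetricReport-class].
#'
#' @param yTrue binary labels.
#' @param prob predicted synergy probabilities.
#' @param threshold decision threshold (default 0.5).
#' @return A `MetricReport`.
#' @export
metricReport <- function(yTrue, prob, threshold = 0.5) {
  pred <- binarize(prob, threshold)
  cc <- confusionCounts(yTrue, pred)
  tm <- thresholdMetrics(cc)
  auc <- if (length(unique(yTrue)) < 2L) NA_real_ else rocAuc(yTrue, prob)
  ap <- if (sum(yTrue == 1) == 0L) NA_real_ else averagePrecision(yTrue, prob)
  new("MetricReport",
      metrics = c(tm[c("ACC", "BACC", "Prec", "Rec", "F1")],
                  ROC_AUC = auc, MCC = unname(tm["MCC"]),
                  Kappa = unname(tm["Kappa"]), AP = ap),
      counts = cc)
}

#' Serialize a MetricReport to JSON
#'
#' @param report A [MetricReport-class].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeMetricReport <- function(report, path) {
  jsonlite::write_json(
    list(metrics = as.list(metrics(report)),
         counts = as.list(confusion(report))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
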