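#' @include AllClasses.R
NULL

#' Confusion counts for binary predictions
#'
#' @param yTrue,yPred Equal-length binary (0/1) vectors; positive class = 1.
#' @return A [ConfusionCounts-class].
#' @examples
#' confusionCounts(c(1, 1, 0, 0), c(1, 0, 0, 1))
#' @export
confusionCounts <- function(yTrue, yPred) {
  stopIfNot(length(yTrue) == length(yPred),
            "yTrue and yPred must have equal length")
  stopIfNot(all(yTrue %in% c(0, 1)) && all(yPred %in% c(0, 1)),
            "labels must be binary 0/1")
  methods::new("ConfusionCounts",
               tp = sum(yTrue == 1 & yPred == 1),
               fp = sum(yTrue == 0 & yPred == 1),
               fn = sum(yTrue == 1 & yPred == 0),
               tn = sum(yTrue == 0 & yPred == 0))
}

# ratio with the zero-denominator convention: 0, plus a record of which
# metric degenerated
.safeRatio <- function(num, den) if (den == 0) 0 else num / den

#' Classification metrics from confusion counts
#'
#' Computes accuracy, sensitivity (TPR), precision (PPV), F1, false
#' positive rate, Cohen's kappa and the Matthews correlation coefficient:
#' \deqn{ACC = (TP+TN)/N,\ TPR = TP/(TP+FN),\ PPV = TP/(TP+FP),}
#' \deqn{F1 = 2TP/(2TP+FP+FN),\ FPR = FP/(FP+TN),}
#' \deqn{\kappa = (P_o - P_e)/(1 - P_e)} with \eqn{P_o = (TP+TN)/N},
#' \eqn{P_e = [(TP+FP)(TP+FN) + (FN+TN)(FP+TN)]/N^2}, and
#' \deqn{MCC = (TP\,TN - FP\,FN)/\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}.}
#' Any ratio whose denominator is 0 (including kappa at \eqn{P_e = 1} and
#' MCC with a zero factor) is reported as 0 and flagged in `degenerate`.
#'
#' @param counts A [ConfusionCounts-class].
#' @param auc Optional AUC to carry into the report.
#' @return A [MetricReport-class].
#' @examples
#' computeMetrics(confusionCounts(rep(1:0, c(55, 45)),
#'                                rep(c(1, 0, 1, 0), c(50, 5, 10, 35))))
#' @export
computeMetrics <- function(counts, auc = NA_real_) {
  tp <- as.numeric(counts@tp); fp <- as.numeric(counts@fp)
  fn <- as.numeric(counts@fn); tn <- as.numeric(counts@tn)
  n <- tp + fp + fn + tn
  degenerate <- character(0)

  acc <- (tp + tn) / n
  recall <- .safeRatio(tp, tp + fn)
  if (tp + fn == 0) degenerate <- c(degenerate, "recall")
  precision <- .safeRatio(tp, tp + fp)
  if (tp + fp == 0) degenerate <- c(degenerate, "precision")
  f1 <- .safeRatio(2 * tp, 2 * tp + fp + fn)
  if (2 * tp + fp + fn == 0) degenerate <- c(degenerate, "f1")
  fpr <- .safeRatio(fp, fp + tn)
  if (fp + tn == 0) degenerate <- c(degenerate, "fpr")

  po <- (tp + tn) / n
  pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  if (abs(1 - pe) < .Machine$double.eps * 4) {
    kappa <- 0
    degenerate <- c(degenerate, "kappa")
  } else kappa <- (po - pe) / (1 - pe)

  mccDen <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (mccDen == 0) {
    mcc <- 0
    degenerate <- c(degenerate, "mcc")
  } else mcc <- (tp * tn - fp * fn) / sqrt(mccDen)

  methods::new("MetricReport", acc = acc, recall = recall,
               precision = precision, f1 = f1, kappa = kappa, mcc = mcc,
               fpr = fpr, auc = auc, degenerate = degenerate)
}

#' ROC curve and AUC
#'
#' The AUC is computed as the Mann-Whitney rank statistic (the probability
#' that a random positive outscores a random negative, ties counting 1/2),
#' which equals trapezoidal integration of the ROC curve over the full
#' threshold sweep and is exact under tied scores. The stepwise curve
#' points are also returned for plotting.
#'
#' @param scores Numeric scores (higher = more protamine-like).
#' @param yTrue Binary 0/1 truth; both classes must be present.
#' @return List with `auc` and `curve` (data.frame `threshold,fpr,tpr`).
#' @examples
#' rocAuc(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0))$auc  # 1
#' @export
rocAuc <- function(scores, yTrue) {
  stopIfNot(length(scores) == length(yTrue), "length mismatch")
  stopIfNot(all(yTrue %in% c(0, 1)), "labels must be binary 0/1")
  nPos <- sum(yTrue == 1); nNeg <- sum(yTrue == 0)
  stopIfNot(nPos > 0 && nNeg > 0, "both classes must be present")
  r <- rank(scores)  # midranks under ties
  auc <- (sum(r[yTrue == 1]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)

  thr <- sort(unique(scores), decreasing = TRUE)
  curve <- data.frame(
    threshold = c(Inf, thr),
    fpr = c(0, vapply(thr, function(t) sum(scores >= t & yTrue == 0), numeric(1)) / nNeg),
    tpr = c(0, vapply(thr, function(t) sum(scores >= t & yTrue == 1), numeric(1)) / nPos))
  list(auc = auc, curve = curve)
}

#' Evaluate predictions in one call
#'
#' Convenience wrapper: confusion counts from the hard labels, the metric
#' bundle, and the AUC when scores are given.
#'
#' @param yTrue Binary truth.
#' @param yPred Binary predictions.
#' @param scores Optional numeric scores for the AUC.
#' @return A [MetricReport-class].
#' @export
evaluatePredictions <- function(yTrue, yPred, scores = NULL) {
  auc <- if (!is.null(scores) && length(unique(yTrue)) == 2L)
    rocAuc(scores, yTrue)$auc else NA_real_
  computeMetrics(confusionCounts(yTrue, yPred), auc = auc)
}
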