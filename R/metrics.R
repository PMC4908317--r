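#' Area under the ROC curve
#'
#' Rank-statistic (Mann-Whitney) formulation with mid-rank tie handling:
#' the probability that a random positive outscores a random negative,
#' counting ties as one half.
#'
#' @param labels 0/1 (or logical) class labels.
#' @param scores numeric scores, higher = more positive.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(labels, scores) {
  y <- as.integer(labels)
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) {
    slimppi_abort("slimppi_undefined_metric",
                  "AUROC needs both classes present")
  }
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Average-precision formulation: records are sorted by score (descending,
#' index-stable on ties) and precision is averaged at the rank of each
#' positive.
#'
#' @inheritParams auroc
#' @return AUPRC in `[0, 1]`.
#' @export
auprc <- function(labels, scores) {
  y <- as.integer(labels)
  if (sum(y == 1) == 0 || sum(y == 0) == 0) {
    slimppi_abort("slimppi_undefined_metric",
                  "AUPRC needs both classes present")
  }
  ord <- order(-scores, seq_along(scores))
  y <- y[ord]
  tp <- cumsum(y)
  precision <- tp / seq_along(y)
  sum(precision[y == 1]) / sum(y)
}

#' Evaluate scored predictions with the standard classifier metrics
#'
#' Computes AUROC and AUPRC from the score ranking, the Brier score (mean
#' squared error of the probability), and the thresholded metrics F1,
#' Matthews correlation coefficient and accuracy at `decision = score >=
#' threshold`. Degenerate thresholded cases follow the usual conventions:
#' F1 is 0 when no true positive exists, MCC is 0 when a confusion-matrix
#' margin is empty.
#'
#' @param labels 0/1 (or logical) class labels.
#' @param scores predicted interaction probabilities.
#' @param threshold decision threshold (default 0.9).
#' @return an object of class `slimppi_metrics`: a list with `auroc`,
#'   `auprc`, `brier`, `f1`, `mcc`, `acc`, `threshold` and the confusion
#'   counts.
#' @export
evaluate <- function(labels, scores, threshold = 0.9) {
  y <- as.integer(labels)
  if (length(y) != length(scores)) {
    slimppi_abort("slimppi_length_mismatch",
                  "labels and scores differ in length")
  }
  if (sum(y == 1) == 0 || sum(y == 0) == 0) {
    slimppi_abort("slimppi_undefined_metric",
                  "evaluation needs both classes present")
  }
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & y == 1)
  fp <- sum(pred == 1 & y == 0)
  tn <- sum(pred == 0 & y == 0)
  fn <- sum(pred == 0 & y == 1)
  f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  mcc_den <- sqrt(as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  mcc <- if (mcc_den == 0) 0 else (as.numeric(tp) * tn - as.numeric(fp) * fn) / mcc_den
  structure(list(
    auroc = auroc(y, scores),
    auprc = auprc(y, scores),
    brier = mean((scores - y)^2),
    f1 = f1, mcc = mcc, acc = (tp + tn) / length(y),
    threshold = threshold,
    confusion = c(tp = tp, fp = fp, tn = tn, fn = fn)
  ), class = "slimppi_metrics")
}

#' @export
print.slimppi_metrics <- function(x, ...) {
  cat(sprintf(
    "AUROC %.4f | AUPRC %.4f | Brier %.4f | F1 %.4f | MCC %.4f | ACC %.4f (threshold %.2f)\n",
    x$auroc, x$auprc, x$brier, x$f1, x$mcc, x$acc, x$threshold))
  invisible(x)
}
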