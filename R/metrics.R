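# Threshold and threshold-free classification metrics.

#' Confusion counts at a probability threshold
#'
#' Predicts positive when `p_positive >= threshold` (ties go to the
#' positive class).
#'
#' @param y_true binary labels in \{0, 1\}.
#' @param p_positive predicted positive-class probabilities.
#' @param threshold decision threshold (default 0.5).
#' @return named list with integer `TP`, `FN`, `TN`, `FP`.
#' @export
confusion_at_threshold <- function(y_true, p_positive, threshold = 0.5) {
  if (length(y_true) != length(p_positive)) {
    stop("y_true and p_positive lengths differ", call. = FALSE)
  }
  if (!length(y_true)) stop("empty input", call. = FALSE)
  if (!all(y_true %in% c(0, 1))) stop("labels must be 0/1", call. = FALSE)
  pred <- as.integer(p_positive >= threshold)
  list(TP = sum(pred == 1L & y_true == 1),
       FN = sum(pred == 0L & y_true == 1),
       TN = sum(pred == 0L & y_true == 0),
       FP = sum(pred == 1L & y_true == 0))
}

#' Threshold metrics from confusion counts
#'
#' Sn = TP/(TP+FN), Sp = TN/(TN+FP), ACC = (TP+TN)/total and the Matthews
#' correlation coefficient
#' MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)).
#' MCC is defined as 0 whenever a denominator factor is 0 (e.g. all
#' predictions in one class); Sn/Sp are NA when their class is absent.
#'
#' @param counts list with `TP`, `FN`, `TN`, `FP` (see
#'   [confusion_at_threshold()]).
#' @return named list with `Sn`, `Sp`, `ACC`, `MCC`.
#' @export
compute_metrics <- function(counts) {
  TP <- counts$TP; FN <- counts$FN; TN <- counts$TN; FP <- counts$FP
  total <- TP + FN + TN + FP
  if (total <= 0) stop("empty confusion table", call. = FALSE)
  sn <- if (TP + FN > 0) TP / (TP + FN) else NA_real_
  sp <- if (TN + FP > 0) TN / (TN + FP) else NA_real_
  den <- as.numeric(TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
  mcc <- if (den > 0) (as.numeric(TP) * TN - as.numeric(FP) * FN) / sqrt(den)
         else 0
  list(Sn = sn, Sp = sp, ACC = (TP + TN) / total, MCC = mcc)
}

#' Area under the ROC curve
#'
#' Computed from the Wilcoxon rank statistic with midranks for ties —
#' equivalent to the trapezoidal area under the empirical ROC curve.
#'
#' @inheritParams confusion_at_threshold
#' @return AUROC in \[0, 1\].
#' @export
roc_auc <- function(y_true, p_positive) {
  .check_two_class(y_true, p_positive)
  n1 <- sum(y_true == 1)
  n0 <- sum(y_true == 0)
  r <- rank(p_positive, ties.method = "average")
  (sum(r[y_true == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-wise average precision: records are sorted by decreasing score
#' (stable for ties) and the precision at each recalled positive is
#' averaged. This is the conservative standard, with no trapezoidal
#' interpolation on the PR curve.
#'
#' @inheritParams confusion_at_threshold
#' @return AUPR in (0, 1\].
#' @export
pr_auc <- function(y_true, p_positive) {
  .check_two_class(y_true, p_positive)
  o <- order(-p_positive)
  y <- y_true[o]
  tp <- cumsum(y)
  prec <- tp / seq_along(y)
  sum(prec[y == 1]) / sum(y)
}

.check_two_class <- function(y_true, p_positive) {
  if (length(y_true) != length(p_positive)) {
    stop("y_true and p_positive lengths differ", call. = FALSE)
  }
  if (!all(y_true %in% c(0, 1))) stop("labels must be 0/1", call. = FALSE)
  if (length(unique(y_true)) < 2) {
    stop("both classes must be present for a threshold-free curve",
         call. = FALSE)
  }
}

#' Full metrics report for scored predictions
#'
#' @inheritParams confusion_at_threshold
#' @param auc also compute AUROC/AUPR (requires both classes; they are NA
#'   otherwise when `auc = NA` is allowed via `strict = FALSE`).
#' @param strict error on single-class input when computing AUCs.
#' @return named list `Sn, Sp, ACC, MCC, AUROC, AUPR`.
#' @export
metrics_report <- function(y_true, p_positive, threshold = 0.5, auc = TRUE,
                           strict = TRUE) {
  m <- compute_metrics(confusion_at_threshold(y_true, p_positive, threshold))
  if (auc) {
    single <- length(unique(y_true)) < 2
    if (single && strict) .check_two_class(y_true, p_positive)
    m$AUROC <- if (single) NA_real_ else roc_auc(y_true, p_positive)
    m$AUPR <- if (single) NA_real_ else pr_auc(y_true, p_positive)
  }
  m
}

#' ROC and PR curve points for plotting/export
#'
#' @inheritParams confusion_at_threshold
#' @return list of two data.frames: `roc` (fpr, tpr, threshold) and
#'   `pr` (recall, precision, threshold).
#' @export
curve_points <- function(y_true, p_positive) {
  .check_two_class(y_true, p_positive)
  o <- order(-p_positive)
  y <- y_true[o]; p <- p_positive[o]
  tp <- cumsum(y); fp <- cumsum(1 - y)
  keep <- c(diff(p) != 0, TRUE)  # one point per distinct threshold
  n1 <- sum(y); n0 <- length(y) - n1
  list(
    roc = data.frame(fpr = c(0, fp[keep] / n0), tpr = c(0, tp[keep] / n1),
                     threshold = c(Inf, p[keep])),
    pr = data.frame(recall = tp[keep] / n1,
                    precision = tp[keep] / (tp[keep] + fp[keep]),
                    threshold = p[keep])
  )
}
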