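#' Regression evaluation metrics
#'
#' Computes the four activity-regression metrics from paired observed and
#' predicted values:
#' \deqn{MRE = \frac{1}{n}\sum_i \frac{|y_i - \hat y_i|}{|y_i|}, \quad
#'       MSE = \frac{1}{n}\sum_i (y_i - \hat y_i)^2,}
#' \deqn{MAE = \frac{1}{n}\sum_i |y_i - \hat y_i|, \quad
#'       R^2 = 1 - \frac{\sum_i (y_i-\hat y_i)^2}{\sum_i (y_i - \bar y)^2}.}
#' MRE is undefined when any observed value is zero; this errors rather
#' than fudging the denominator, since pIC50 values are bounded away from
#' zero in practice.
#'
#' @param y_true observed values.
#' @param y_pred predicted values.
#' @return list of class `regression_metrics` with `mre`, `mse`, `mae`,
#'   `r2`.
#' @export
evaluate_regression <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (length(y_true) < 2L) stop("need at least 2 observations")
  if (any(!is.finite(y_true)) || any(!is.finite(y_pred))) stop("non-finite values")
  if (any(y_true == 0)) stop("MRE undefined: observed value of 0")
  err <- y_true - y_pred
  structure(list(mre = mean(abs(err) / abs(y_true)),
                 mse = mean(err^2),
                 mae = mean(abs(err)),
                 r2 = 1 - sum(err^2) / sum((y_true - mean(y_true))^2)),
            class = "regression_metrics")
}

#' @export
print.regression_metrics <- function(x, ...) {
  cat(sprintf("MRE %.4f  MSE %.4f  MAE %.4f  R2 %.4f\n",
              x$mre, x$mse, x$mae, x$r2))
  invisible(x)
}

#' Relative-error histogram
#'
#' Bins per-sample relative errors `|y_i - yhat_i| / |y_i|` into half-open
#' intervals `[a, b)`; the final bin is open-ended. The default edges give
#' 5-percentage-point bands up to 30% plus an overflow band.
#'
#' @param y_true observed values (nonzero).
#' @param y_pred predicted values.
#' @param bin_edges increasing vector of relative-error edges; an implicit
#'   `Inf` closes the last bin.
#' @return data.frame with `lower`, `upper`, `count`, `proportion`.
#' @export
relative_error_histogram <- function(y_true, y_pred,
                                     bin_edges = seq(0, 0.30, by = 0.05)) {
  if (any(y_true == 0)) stop("relative error undefined: observed value of 0")
  if (is.unsorted(bin_edges, strictly = TRUE)) stop("bin_edges must be increasing")
  rel <- abs(y_true - y_pred) / abs(y_true)
  edges <- c(bin_edges, Inf)
  idx <- findInterval(rel, edges, rightmost.closed = FALSE)
  idx[idx == 0L] <- 1L  # errors below the first edge count in the first bin
  counts <- tabulate(idx, nbins = length(edges) - 1L)
  data.frame(lower = edges[-length(edges)], upper = edges[-1L],
             count = counts, proportion = counts / length(rel))
}

#' Classification evaluation metrics
#'
#' Confusion-matrix metrics for a binary endpoint:
#' accuracy `(TP+TN)/n`, precision `TP/(TP+FP)`, recall `TP/(TP+FN)`,
#' F1 (harmonic mean of precision and recall), and false positive rate
#' `FP/(TN+FP)`, plus the ROC AUC from the continuous scores when
#' supplied. Metrics with a zero denominator are reported as 0 with a
#' warning so report tables stay machine-readable.
#'
#' @param y_true 0/1 vector of observed labels.
#' @param y_pred 0/1 vector of predicted labels.
#' @param scores optional continuous scores for AUC.
#' @return list of class `classification_metrics` with `accuracy`,
#'   `precision`, `recall`, `f1`, `fpr`, `auc` (NA without scores) and the
#'   confusion counts `tp`, `fp`, `tn`, `fn`.
#' @export
evaluate_classification <- function(y_true, y_pred, scores = NULL) {
  if (length(y_true) == 0L) stop("empty input")
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (!all(y_true %in% c(0, 1)) || !all(y_pred %in% c(0, 1)))
    stop("labels must be 0/1")
  tp <- sum(y_true == 1 & y_pred == 1)
  fp <- sum(y_true == 0 & y_pred == 1)
  tn <- sum(y_true == 0 & y_pred == 0)
  fn <- sum(y_true == 1 & y_pred == 0)
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning(what, " has zero denominator; reporting 0")
      0
    } else num / den
  }
  precision <- safe_div(tp, tp + fp, "precision")
  recall <- safe_div(tp, tp + fn, "recall")
  f1 <- if (precision + recall == 0) {
    warning("F1 has zero denominator; reporting 0")
    0
  } else 2 * precision * recall / (precision + recall)
  structure(list(accuracy = (tp + tn) / length(y_true),
                 precision = precision, recall = recall, f1 = f1,
                 fpr = safe_div(fp, tn + fp, "FPR"),
                 auc = if (is.null(scores)) NA_real_ else
                   compute_auc(y_true, scores),
                 tp = tp, fp = fp, tn = tn, fn = fn),
            class = "classification_metrics")
}

#' @export
print.classification_metrics <- function(x, ...) {
  cat(sprintf("acc %.4f  prec %.4f  rec %.4f  F1 %.4f  FPR %.4f  AUC %s\n",
              x$accuracy, x$precision, x$recall, x$f1, x$fpr,
              ifelse(is.na(x$auc), "-", sprintf("%.4f", x$auc))))
  invisible(x)
}

#' ROC curve points
#'
#' The (FPR, TPR) path traced over all score thresholds, one row per
#' tied-score block plus the origin; trapezoidal integration of these
#' points gives [compute_auc()].
#'
#' @inheritParams compute_auc
#' @return data.frame with `threshold`, `fpr`, `tpr`.
#' @export
roc_points <- function(y_true, scores) {
  if (!all(y_true %in% c(0, 1))) stop("labels must be 0/1")
  n_pos <- sum(y_true == 1); n_neg <- sum(y_true == 0)
  if (n_pos == 0L || n_neg == 0L) stop("both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  y <- y_true[ord]; s <- scores[ord]
  block_end <- c(which(diff(s) != 0), length(s))
  data.frame(threshold = c(Inf, s[block_end]),
             fpr = c(0, cumsum(1 - y)[block_end] / n_neg),
             tpr = c(0, cumsum(y)[block_end] / n_pos))
}

#' Area under the ROC curve
#'
#' Trapezoidal area under the ROC curve traced over all score thresholds.
#' With ties handled by the trapezoid through each tied block, this equals
#' the Mann-Whitney probability that a random positive outscores a random
#' negative, counting ties as 1/2.
#'
#' @param y_true 0/1 labels (both classes must be present).
#' @param scores continuous classifier scores (higher = more positive).
#' @return AUC in \[0, 1\].
#' @export
compute_auc <- function(y_true, scores) {
  if (length(y_true) != length(scores)) stop("length mismatch")
  if (!all(y_true %in% c(0, 1))) stop("labels must be 0/1")
  n_pos <- sum(y_true == 1)
  n_neg <- sum(y_true == 0)
  if (n_pos == 0L || n_neg == 0L) stop("both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  y <- y_true[ord]
  s <- scores[ord]
  # cumulative counts at the end of each tied-score block
  block_end <- c(which(diff(s) != 0), length(s))
  tpr <- c(0, cumsum(y)[block_end] / n_pos)
  fpr <- c(0, cumsum(1 - y)[block_end] / n_neg)
  sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
}
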