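#' ROC area under the curve
#'
#' Computed as the tie-adjusted Mann-Whitney rank statistic: the
#' probability that a random positive outranks a random negative, with
#' half credit for ties. Invariant under any strictly increasing
#' transform of the scores.
#'
#' @param p_positive Numeric scores (higher = more positive).
#' @param labels Binary 0/1 labels.
#' @return The ROC-AUC.
#' @export
roc_auc <- function(p_positive, labels) {
  check_metric_input(p_positive, labels)
  n1 <- as.numeric(sum(labels == 1))
  n0 <- as.numeric(sum(labels == 0))
  if (n1 == 0 || n0 == 0)
    stop("ROC-AUC undefined: only one class present", call. = FALSE)
  r <- rank(p_positive, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Noninterpolated average precision
#'
#' The precision-weighted sum of recall increments over the ranked list,
#' `sum_k (R_k - R_{k-1}) * P_k`, with tied scores collapsed into a single
#' threshold step. No trapezoidal interpolation is applied, avoiding the
#' optimistic bias it introduces in imbalanced settings.
#'
#' @inheritParams roc_auc
#' @return The average precision.
#' @export
average_precision <- function(p_positive, labels) {
  check_metric_input(p_positive, labels)
  n_pos <- sum(labels == 1)
  if (n_pos == 0)
    stop("average precision undefined: no positives", call. = FALSE)
  o <- order(p_positive, decreasing = TRUE)
  y <- labels[o]
  s <- p_positive[o]
  # group tied scores: threshold steps at the last index of each tie group
  last_of_group <- which(!duplicated(s, fromLast = TRUE))
  tp <- cumsum(y)[last_of_group]
  fp <- cumsum(1 - y)[last_of_group]
  prec <- tp / (tp + fp)
  rec <- tp / n_pos
  sum(diff(c(0, rec)) * prec)
}

#' F1-score and balanced accuracy from hard labels
#'
#' F1 is the harmonic mean of precision and recall on the positive class;
#' balanced accuracy is the mean of sensitivity and specificity. Zero
#' denominators yield 0 (with a warning), the conventional degenerate
#' value.
#'
#' @param predicted_labels Binary 0/1 predictions.
#' @param labels Binary 0/1 truth.
#' @return Named numeric vector `c(f1 = , balanced_accuracy = )`.
#' @export
f1_and_balanced_accuracy <- function(predicted_labels, labels) {
  check_metric_input(predicted_labels, labels)
  tp <- sum(predicted_labels == 1 & labels == 1)
  fp <- sum(predicted_labels == 1 & labels == 0)
  fn <- sum(predicted_labels == 0 & labels == 1)
  tn <- sum(predicted_labels == 0 & labels == 0)
  f1 <- if (2 * tp + fp + fn == 0) {
    warning("F1 undefined (no positives predicted or present); returning 0",
            call. = FALSE)
    0
  } else 2 * tp / (2 * tp + fp + fn)
  sens <- if (tp + fn == 0) {
    warning("sensitivity undefined; returning 0", call. = FALSE); 0
  } else tp / (tp + fn)
  spec <- if (tn + fp == 0) {
    warning("specificity undefined; returning 0", call. = FALSE); 0
  } else tn / (tn + fp)
  c(f1 = f1, balanced_accuracy = (sens + spec) / 2)
}

check_metric_input <- function(scores, labels) {
  if (length(scores) != length(labels))
    stop("scores and labels have different lengths", call. = FALSE)
  if (length(scores) == 0) stop("empty input", call. = FALSE)
  if (anyNA(scores) || anyNA(labels)) stop("NA in metric input", call. = FALSE)
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1", call. = FALSE)
  invisible(TRUE)
}

#' Decision-curve net benefit over a threshold grid
#'
#' Net benefit at decision threshold `t` is `TP/n - (FP/n) * t/(1-t)`,
#' classifying positive when `p >= t` (closed on the left). The curve is
#' evaluated on a uniform grid and summarized by the arithmetic mean over
#' the grid points falling inside the closed clinically relevant interval.
#' Treat-all and treat-none reference curves are included; treat-all
#' crosses zero exactly at the prevalence.
#'
#' @param p_positive Predicted probabilities.
#' @param labels Binary 0/1 labels.
#' @param interval Length-2 probability interval `(lo, hi)` within (0,1).
#' @param grid_step Grid spacing (default 0.01).
#' @return A `net_benefit_curve`: list with `thresholds`, `nb_model`,
#'   `nb_all`, `nb_none`, `interval`, `mean_net_benefit`.
#' @export
net_benefit_curve <- function(p_positive, labels, interval, grid_step = 0.01) {
  check_metric_input(p_positive, labels)
  interval <- as.numeric(interval)
  if (length(interval) != 2 || !(interval[1] > 0 && interval[1] < interval[2] &&
                                 interval[2] < 1))
    stop("interval must satisfy 0 < lo < hi < 1", call. = FALSE)
  if (grid_step <= 0) stop("grid_step must be positive", call. = FALSE)
  thresholds <- seq(grid_step, 1 - grid_step, by = grid_step)
  n <- length(labels)
  prevalence <- mean(labels)
  nb_model <- vapply(thresholds, function(t) {
    pred <- p_positive >= t
    tp <- sum(pred & labels == 1)
    fp <- sum(pred & labels == 0)
    tp / n - (fp / n) * t / (1 - t)
  }, numeric(1))
  nb_all <- prevalence - (1 - prevalence) * thresholds / (1 - thresholds)
  inside <- thresholds >= interval[1] - 1e-12 & thresholds <= interval[2] + 1e-12
  if (!any(inside)) stop("no grid point inside the interval", call. = FALSE)
  structure(list(thresholds = thresholds, nb_model = nb_model,
                 nb_all = nb_all, nb_none = rep(0, length(thresholds)),
                 interval = interval, prevalence = prevalence,
                 mean_net_benefit = mean(nb_model[inside])),
            class = "net_benefit_curve")
}

#' @export
print.net_benefit_curve <- function(x, ...) {
  cat("<net_benefit_curve> prevalence ", signif(x$prevalence, 3),
      ", mean net benefit over [", x$interval[1], ", ", x$interval[2],
      "] = ", signif(x$mean_net_benefit, 4), "\n", sep = "")
  invisible(x)
}

#' Write a net-benefit curve as CSV
#' @param curve A `net_benefit_curve`.
#' @param path Output path.
#' @export
write_net_benefit_csv <- function(curve, path) {
  utils::write.csv(data.frame(t = curve$thresholds, nb_model = curve$nb_model,
                              nb_all = curve$nb_all, nb_none = curve$nb_none),
                   path, row.names = FALSE)
  invisible(path)
}

#' Brier score
#'
#' Mean squared difference between predicted probability and the binary
#' outcome; the calibration-sensitive counterpart to ROC-AUC.
#'
#' @inheritParams net_benefit_curve
#' @return The Brier score.
#' @export
brier_score <- function(p_positive, labels) {
  check_metric_input(p_positive, labels)
  mean((p_positive - labels)^2)
}
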