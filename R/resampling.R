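#' Bootstrap configuration
#'
#' @param n_ci Replicates for fold-mean confidence intervals (default 5000).
#' @param n_pi Replicates for single-split prediction intervals
#'   (default 20000).
#' @param level Coverage level (default 0.95).
#' @param seed Integer seed; identical config + seed gives identical
#'   intervals.
#' @return A `bootstrap_config`.
#' @export
bootstrap_config <- function(n_ci = 5000, n_pi = 20000, level = 0.95,
                             seed = 1L) {
  stopifnot(n_ci >= 1, n_pi >= 1, level > 0, level < 1)
  structure(list(n_ci = as.integer(n_ci), n_pi = as.integer(n_pi),
                 level = level, seed = as.integer(seed)),
            class = "bootstrap_config")
}

#' Bundle per-fold predictions over a common sample
#'
#' The inference procedures need the predictions of every inverted-CV
#' fold together with the labels of the full selected sample S (the union
#' of train and test sets, common to all folds), because patient
#' resampling is done on S and then masked to each fold's test members.
#'
#' @param predictions Data frame with columns `patient_id`, `split_id`
#'   and `p_positive` (one row per test patient per fold).
#' @param cohort_labels Named 0/1 vector: labels of every member of S,
#'   names are patient ids.
#' @param model_id Identifier carried into results.
#' @return A `fold_predictions` object.
#' @export
fold_predictions <- function(predictions, cohort_labels, model_id = "model") {
  stopifnot(all(c("patient_id", "split_id", "p_positive") %in%
                  names(predictions)))
  ids <- names(cohort_labels)
  if (is.null(ids)) stop("cohort_labels must be named by patient id", call. = FALSE)
  if (!all(cohort_labels %in% c(0, 1))) stop("labels must be 0/1", call. = FALSE)
  split_ids <- sort(unique(predictions$split_id))
  folds <- lapply(split_ids, function(s) {
    d <- predictions[predictions$split_id == s, ]
    idx <- match(d$patient_id, ids)
    if (anyNA(idx))
      stop("prediction for patient not in the cohort: ",
           d$patient_id[which(is.na(idx))[1]], call. = FALSE)
    if (anyDuplicated(idx))
      stop("duplicate prediction within split ", s, call. = FALSE)
    list(split_id = s, test_idx = idx, scores = d$p_positive)
  })
  structure(list(y = as.integer(unname(cohort_labels)), ids = ids,
                 folds = folds, model_id = model_id),
            class = "fold_predictions")
}

#' @export
print.fold_predictions <- function(x, ...) {
  cat("<fold_predictions> model=", x$model_id, ", ", length(x$folds),
      " folds over a sample of ", length(x$y), " patients\n", sep = "")
  invisible(x)
}

metric_code <- function(metric) {
  switch(metric, roc_auc = 1L, average_precision = 2L, brier = 3L,
         stop("supported metrics: roc_auc, average_precision, brier",
              call. = FALSE))
}

metric_fun <- function(metric) {
  switch(metric, roc_auc = roc_auc, average_precision = average_precision,
         brier = brier_score)
}

fold_point_values <- function(fp, metric) {
  f <- metric_fun(metric)
  vapply(fp$folds, function(fold)
    f(fold$scores, fp$y[fold$test_idx]), numeric(1))
}

check_same_geometry <- function(a, b) {
  same <- identical(a$ids, b$ids) && identical(a$y, b$y) &&
    length(a$folds) == length(b$folds) &&
    all(vapply(seq_along(a$folds), function(i)
      identical(a$folds[[i]]$test_idx, b$folds[[i]]$test_idx), logical(1)))
  if (!same)
    stop("paired inference requires identical fold/test geometry", call. = FALSE)
  invisible(TRUE)
}

boot_replicates <- function(fp_list, metric, n_rep, mode, seed) {
  fp1 <- fp_list[[1]]
  fold_idx <- lapply(fp1$folds, `[[`, "test_idx")
  scores <- lapply(fp_list, function(fp) lapply(fp$folds, `[[`, "scores"))
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  if (mode == "ci")
    cpp_boot_ci(fp1$y, fold_idx, scores, n_rep, metric_code(metric),
                length(fold_idx))
  else
    cpp_boot_pi(fp1$y, fold_idx, scores, n_rep, metric_code(metric))
}

percentile_interval <- function(reps, level) {
  alpha <- 1 - level
  stats::quantile(reps, c(alpha / 2, 1 - alpha / 2), na.rm = TRUE,
                  names = FALSE)
}

new_interval_result <- function(kind, metric, model_id, point, reps, raw,
                                level, seed) {
  q <- percentile_interval(reps, level)
  structure(list(kind = kind, metric = metric, model_id = model_id,
                 point = point, lower = q[1], upper = q[2],
                 level = level, n_replicates = length(reps),
                 skipped_fold_rate = sum(raw$skipped) / raw$total_draws /
                   max(length(model_id), 1),
                 seed = seed),
            class = "interval_result")
}

#' @export
print.interval_result <- function(x, ...) {
  cat(sprintf("<%s> %s [%s]: point %.4f, %.0f%% interval [%.4f, %.4f] (%d replicates)\n",
              x$kind, x$metric, paste(x$model_id, collapse = " - "),
              if (is.null(x$point)) NA_real_ else x$point,
              100 * x$level, x$lower, x$upper, x$n_replicates))
  invisible(x)
}

#' Overlap-aware confidence interval for the fold-mean metric
#'
#' Per replicate: (1) patients are resampled with replacement, stratified
#' by outcome, from the full selected sample S; (2) the resample is
#' masked to each fold's test members and the metric computed on the
#' masked multiset — this preserves the correlation induced by the heavy
#' overlap between test sets; (3) folds are resampled with replacement
#' (cluster bootstrap) to account for training-set choice, and the mean
#' of the drawn folds' estimates is stored. The CI is the percentile
#' interval of the replicate means. Fold draws whose masked test multiset
#' is single-class are skipped (the metric is undefined there); the skip
#' frequency is reported.
#'
#' @param fp A [fold_predictions()] object.
#' @param metric `"roc_auc"`, `"average_precision"` or `"brier"`.
#' @param config A [bootstrap_config()].
#' @param keep_replicates Attach the replicate stream as an attribute.
#' @return An `interval_result` with `point` (mean of per-fold metrics),
#'   `lower`, `upper`, `n_replicates`, `skipped_fold_rate`.
#' @export
ci_fold_mean <- function(fp, metric = "roc_auc",
                         config = bootstrap_config(),
                         keep_replicates = FALSE) {
  raw <- boot_replicates(list(fp), metric, config$n_ci, "ci", config$seed)
  out <- new_interval_result("ci", metric, fp$model_id,
                             mean(fold_point_values(fp, metric)),
                             raw$replicates[, 1], raw, config$level,
                             config$seed)
  if (keep_replicates) attr(out, "replicates") <- raw$replicates[, 1]
  out
}

#' Hierarchical prediction interval for a single realized split
#'
#' Per replicate one fold is drawn uniformly (representing the
#' training-set choice) and its test set resampled with replacement,
#' stratified by outcome; the metric on the resample is stored. The
#' percentile interval over replicates characterizes the dispersion of
#' performance expected for an individual training-test realization —
#' wider than the CI for the fold mean, by construction.
#'
#' @inheritParams ci_fold_mean
#' @return An `interval_result` (no point value: the interval describes a
#'   single random realization, not an estimator of a mean).
#' @export
prediction_interval <- function(fp, metric = "roc_auc",
                                config = bootstrap_config(),
                                keep_replicates = FALSE) {
  raw <- boot_replicates(list(fp), metric, config$n_pi, "pi", config$seed)
  out <- new_interval_result("pi", metric, fp$model_id, NULL,
                             raw$replicates[, 1], raw, config$level,
                             config$seed)
  if (keep_replicates) attr(out, "replicates") <- raw$replicates[, 1]
  out
}

#' Paired interval for a metric difference between two models
#'
#' Both models must share the identical fold/test geometry. Within every
#' replicate the same patient resample and the same fold draws are
#' applied to both models before differencing — the pairing contract that
#' makes the comparison exact rather than a difference of marginal
#' intervals.
#'
#' @param fp_a,fp_b [fold_predictions()] for the two models.
#' @param metric `"roc_auc"`, `"average_precision"` or `"brier"`.
#' @param mode `"ci"` (fold-mean difference) or `"pi"` (single-split
#'   difference).
#' @param config A [bootstrap_config()].
#' @param keep_replicates Attach the per-model replicate matrix.
#' @return An `interval_result` for the difference (model A minus B).
#' @export
paired_difference <- function(fp_a, fp_b, metric = "roc_auc",
                              mode = c("ci", "pi"),
                              config = bootstrap_config(),
                              keep_replicates = FALSE) {
  mode <- match.arg(mode)
  check_same_geometry(fp_a, fp_b)
  n_rep <- if (mode == "ci") config$n_ci else config$n_pi
  raw <- boot_replicates(list(fp_a, fp_b), metric, n_rep, mode, config$seed)
  diffs <- raw$replicates[, 1] - raw$replicates[, 2]
  point <- if (mode == "ci")
    mean(fold_point_values(fp_a, metric) - fold_point_values(fp_b, metric))
  else NULL
  out <- new_interval_result(paste0("paired_", mode), metric,
                             c(fp_a$model_id, fp_b$model_id),
                             point, diffs, raw, config$level, config$seed)
  if (keep_replicates) attr(out, "replicates") <- raw$replicates
  out
}

#' Serialize an interval result to JSON
#' @param result An `interval_result`.
#' @param path Output path.
#' @export
write_interval_json <- function(result, path) {
  jsonlite::write_json(unclass(result), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
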