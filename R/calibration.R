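PROB_CLIP_EPS <- 1e-6

clip_probs <- function(p, eps = PROB_CLIP_EPS) pmin(pmax(p, eps), 1 - eps)

#' Fit a post hoc probability calibrator
#'
#' Raw completion probabilities from in-context predictors pile up near 0
#' and 1; calibration maps them back onto the probability scale. Three
#' methods are supported: Platt scaling (logistic fit on the logit of the
#' score), isotonic regression (weighted pool-adjacent-violators), and
#' beta calibration, the three-parameter monotone map
#' `mu(s) = plogis(c + a*log(s) - b*log(1-s))` with `a, b >= 0`, fitted as
#' a logistic regression on the features `log(s)` and `-log(1-s)` (a
#' negative coefficient triggers a refit with that feature dropped).
#' Scores are clipped to `[1e-6, 1 - 1e-6]` before any log transform.
#'
#' @param train_probs Out-of-fold predicted probabilities (see
#'   [loocv_calibration_probs()]).
#' @param train_labels Binary 0/1 labels aligned with `train_probs`.
#' @param method `"platt"`, `"isotonic"`, `"beta"` or `"none"`.
#' @return A `calibration_model`.
#' @export
fit_calibrator <- function(train_probs, train_labels,
                           method = c("beta", "platt", "isotonic", "none")) {
  method <- match.arg(method)
  if (method == "none")
    return(structure(list(method = "none"), class = "calibration_model"))
  if (length(train_probs) < 2 || length(train_probs) != length(train_labels))
    stop("need >= 2 aligned training points", call. = FALSE)
  if (!all(train_labels %in% c(0, 1))) stop("labels must be 0/1", call. = FALSE)
  if (length(unique(train_labels)) < 2) {
    warning("one-class calibration set: degenerate model mapping to the ",
            "class rate", call. = FALSE)
    return(structure(list(method = "constant", value = mean(train_labels)),
                     class = "calibration_model"))
  }
  s <- clip_probs(train_probs)
  y <- train_labels
  model <- switch(method,
    platt = {
      fit <- stats::glm(y ~ stats::qlogis(s), family = stats::binomial())
      list(method = "platt", intercept = unname(stats::coef(fit)[1]),
           slope = unname(stats::coef(fit)[2]))
    },
    beta = {
      f1 <- log(s); f2 <- -log(1 - s)
      fit <- suppressWarnings(stats::glm(y ~ f1 + f2, family = stats::binomial()))
      a <- unname(stats::coef(fit)["f1"]); b <- unname(stats::coef(fit)["f2"])
      if (is.na(a) || a < 0) {
        fit <- suppressWarnings(stats::glm(y ~ f2, family = stats::binomial()))
        a <- 0; b <- unname(stats::coef(fit)["f2"])
      } else if (is.na(b) || b < 0) {
        fit <- suppressWarnings(stats::glm(y ~ f1, family = stats::binomial()))
        a <- unname(stats::coef(fit)["f1"]); b <- 0
      }
      if (is.na(b)) b <- 0
      if (is.na(a)) a <- 0
      list(method = "beta", a = a, b = b, c = unname(stats::coef(fit)[1]))
    },
    isotonic = {
      fit <- weighted_pava(s, y)
      list(method = "isotonic", x = fit$x, y = fit$y)
    })
  structure(model, class = "calibration_model")
}

# weighted pool-adjacent-violators on (x, y): tied x aggregated first,
# violating adjacent blocks pooled by weighted mean; returns the monotone
# fitted value at every distinct x knot
weighted_pava <- function(x, y) {
  ux <- sort(unique(x))
  idx <- match(x, ux)
  w <- tabulate(idx, length(ux))
  m <- vapply(seq_along(ux), function(k) mean(y[idx == k]), numeric(1))
  val <- numeric(0); wt <- numeric(0); cnt <- integer(0)
  for (k in seq_along(ux)) {
    val <- c(val, m[k]); wt <- c(wt, w[k]); cnt <- c(cnt, 1L)
    j <- length(val)
    while (j > 1 && val[j - 1] > val[j] + 1e-15) {
      nv <- (wt[j - 1] * val[j - 1] + wt[j] * val[j]) / (wt[j - 1] + wt[j])
      val[j - 1] <- nv
      wt[j - 1] <- wt[j - 1] + wt[j]
      cnt[j - 1] <- cnt[j - 1] + cnt[j]
      val <- val[-j]; wt <- wt[-j]; cnt <- cnt[-j]
      j <- j - 1L
    }
  }
  list(x = ux, y = rep(val, cnt))
}

#' @export
print.calibration_model <- function(x, ...) {
  cat("<calibration_model> method=", x$method, sep = "")
  if (x$method == "beta")
    cat(sprintf(" (a=%.3f, b=%.3f, c=%.3f)", x$a, x$b, x$c))
  if (x$method == "platt")
    cat(sprintf(" (slope=%.3f, intercept=%.3f)", x$slope, x$intercept))
  cat("\n")
  invisible(x)
}

#' Apply a fitted calibrator
#'
#' @param model A `calibration_model` from [fit_calibrator()].
#' @param probs Probabilities to calibrate.
#' @return Calibrated probabilities in `[0, 1]`; `method = "none"` is the
#'   identity; isotonic inputs outside the fitted range clamp to the
#'   boundary values.
#' @export
apply_calibrator <- function(model, probs) {
  stopifnot(inherits(model, "calibration_model"))
  switch(model$method,
    none = probs,
    constant = rep(model$value, length(probs)),
    platt = stats::plogis(model$intercept +
                            model$slope * stats::qlogis(clip_probs(probs))),
    beta = {
      s <- clip_probs(probs)
      stats::plogis(model$c + model$a * log(s) - model$b * log(1 - s))
    },
    isotonic = {
      if (length(model$x) == 1) rep(model$y, length(probs))
      else stats::approx(model$x, model$y, xout = clip_probs(probs),
                         rule = 2, ties = "ordered")$y
    },
    stop("unknown calibration method", call. = FALSE))
}

#' Out-of-fold calibration probabilities by inner LOOCV
#'
#' Calibration is fitted on the training set only, using leave-one-out:
#' for each training patient the predictor is refit (or re-prompted) on
#' the remaining patients and queried on the held-out one. When the
#' remaining training set contains a single class (a real possibility at
#' training size 10 in strongly imbalanced cohorts) the held-out
#' probability is set to 0.5 rather than calling the predictor.
#'
#' @param labels Binary 0/1 training labels.
#' @param predict_left_out Function of one argument `i` returning the
#'   predicted positive-class probability for patient `i` when trained on
#'   all others; only called when both classes remain.
#' @return Numeric vector of out-of-fold probabilities, aligned with
#'   `labels`; pair it with `labels` in [fit_calibrator()].
#' @export
loocv_calibration_probs <- function(labels, predict_left_out) {
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1", call. = FALSE)
  vapply(seq_along(labels), function(i) {
    if (length(unique(labels[-i])) < 2) 0.5 else predict_left_out(i)
  }, numeric(1))
}

#' Serialize a calibration model to JSON
#' @param model A `calibration_model`.
#' @param path Output path.
#' @export
write_calibration_json <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a calibration model from JSON
#' @param path Path written by [write_calibration_json()].
#' @return A `calibration_model`.
#' @export
read_calibration_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(obj, class = "calibration_model")
}
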