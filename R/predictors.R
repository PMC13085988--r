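#' Label vocabulary for a context variant
#'
#' Full-context prompts and the intermediate ablations use the schema's
#' clinical outcome texts; the no-context dialect uses `"0"`/`"1"`.
#'
#' @param schema A `dataset_schema`.
#' @param variant One of [context_variants()].
#' @return Character vector `c(negative, positive)`.
#' @export
labels_for_variant <- function(schema, variant) {
  if (identical(variant, "no_context")) c("0", "1")
  else c(schema$label_negative_text, schema$label_positive_text)
}

#' Wrap a chat-completion backend
#'
#' The backend contract is a single `send(prompt)` function returning,
#' atomically per request, the completion text and its per-token
#' log-probabilities: `list(completion = <chr>, token_logprobs = <num>)`.
#' Decoding settings are recorded as metadata only.
#'
#' @param send Function of one `prompt` argument.
#' @param model_id Identifier recorded in prediction records.
#' @param temperature,beam_width Decoding metadata.
#' @return A `chat_backend`.
#' @export
chat_backend <- function(send, model_id = "chat",
                         temperature = 0, beam_width = 1) {
  stopifnot(is.function(send))
  structure(list(send = send, model_id = model_id,
                 temperature = temperature, beam_width = beam_width),
            class = "chat_backend")
}

#' Deterministic mock chat backend driven by a logistic oracle
#'
#' Stands in for a live chat model in tests and offline runs: it resolves
#' the prompt's test patient in the reference table, scores it with the
#' logistic oracle over the encoded features, and answers with the
#' variant-appropriate label of the more probable class plus a single
#' token log-probability `log(max(p, 1-p))` — so the full response-parsing
#' path is exercised exactly as with a real backend.
#'
#' @param oracle An oracle spec (see [make_oracle()]): list with
#'   `coefficients` (named by encoded column) and `intercept`.
#' @param table The `patient_table` the prompts' patient ids refer to.
#' @param model_id Identifier recorded in prediction records.
#' @return A `chat_backend`.
#' @export
mock_chat_backend <- function(oracle, table, model_id = "mock") {
  enc <- encode_table(table)
  p_all <- oracle_probability(oracle, enc$x)
  names(p_all) <- rownames(enc$x)
  schema <- table$schema
  send <- function(prompt) {
    pid <- prompt$patient_id
    if (is.na(pid) || !pid %in% names(p_all))
      stop("mock backend cannot resolve patient '", pid, "'", call. = FALSE)
    p <- p_all[[pid]]
    labs <- labels_for_variant(schema, prompt$variant)
    positive <- p >= 0.5
    list(completion = if (positive) labs[2] else labs[1],
         token_logprobs = log(max(p, 1 - p)))
  }
  chat_backend(send, model_id = model_id)
}

oracle_probability <- function(oracle, x) {
  x <- as.matrix(x)
  cf <- oracle$coefficients
  miss <- setdiff(names(cf), colnames(x))
  if (length(miss))
    stop("oracle coefficients name unknown columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  eta <- drop(x[, names(cf), drop = FALSE] %*% cf) + oracle$intercept
  stats::plogis(eta)
}

#' Predict one test patient through a chat backend
#'
#' Sends the prompt, strictly parses the completion (surrounding
#' whitespace stripped, case-sensitive exact match against the variant's
#' two label texts — anything else is an error carrying the raw text),
#' sums the token log-probabilities, exponentiates into the completion
#' probability `P`, and assigns the complement `1 - P` to the other class.
#'
#' @param prompt A `prompt`.
#' @param backend A [chat_backend()].
#' @param labels Character vector `c(negative, positive)`; defaults from
#'   the prompt variant require passing a schema instead.
#' @param schema Optional `dataset_schema` used to derive `labels`.
#' @return A one-row data frame prediction record: `patient_id`,
#'   `model_id`, `variant`, `predicted_label`, `logprob_sum`, `P`,
#'   `p_positive`.
#' @export
predict_llm <- function(prompt, backend, labels = NULL, schema = NULL) {
  stopifnot(inherits(backend, "chat_backend"))
  if (is.null(labels)) {
    if (is.null(schema)) stop("supply labels or a schema", call. = FALSE)
    labels <- labels_for_variant(schema, prompt$variant)
  }
  stopifnot(length(labels) == 2)
  resp <- backend$send(prompt)
  if (is.null(resp$completion) || is.null(resp$token_logprobs))
    stop("backend returned no completion or no log-probabilities", call. = FALSE)
  completion <- trimws(resp$completion)
  if (!completion %in% labels)
    stop("completion is not exactly a label: '", resp$completion, "'",
         call. = FALSE)
  logprob_sum <- sum(resp$token_logprobs)
  P <- exp(logprob_sum)
  if (P > 1 + 1e-12) stop("completion probability exceeds 1", call. = FALSE)
  P <- min(P, 1)
  if (P <= 0) stop("completion probability must be positive", call. = FALSE)
  positive <- completion == labels[2]
  data.frame(patient_id = prompt$patient_id,
             model_id = backend$model_id,
             variant = prompt$variant,
             predicted_label = completion,
             logprob_sum = logprob_sum,
             P = P,
             p_positive = if (positive) P else 1 - P,
             stringsAsFactors = FALSE)
}

#' Predict a list of prompts
#'
#' @param prompts List of `prompt` objects (one test patient each).
#' @param backend A [chat_backend()].
#' @param schema The `dataset_schema` supplying label vocabularies.
#' @return Data frame of prediction records, one row per prompt.
#' @export
predict_prompts <- function(prompts, backend, schema) {
  do.call(rbind, lapply(prompts, predict_llm, backend = backend,
                        schema = schema))
}

#' Score a single record with the logistic mock oracle
#'
#' Emits the full prediction-record shape (label of the more probable
#' class, `logprob_sum = log(max(p, 1-p))`) so downstream probability
#' extraction is identical to the chat path.
#'
#' @param record Named numeric vector over encoded columns, or a raw
#'   feature map together with `schema`.
#' @param oracle Oracle spec with `coefficients` and `intercept`.
#' @param schema Optional `dataset_schema` for raw feature maps.
#' @param labels Label texts `c(negative, positive)`; default `c("0","1")`.
#' @return One-row prediction-record data frame.
#' @export
mock_oracle_predict <- function(record, oracle, schema = NULL,
                                labels = c("0", "1")) {
  if (is.numeric(record)) {
    x <- matrix(record, nrow = 1, dimnames = list(NULL, names(record)))
  } else {
    stopifnot(!is.null(schema))
    df <- as.data.frame(as.list(record), stringsAsFactors = FALSE,
                        check.names = FALSE)
    if (!schema$label_name %in% names(df)) df[[schema$label_name]] <- NA
    x <- encode_table(patient_table(df, schema))$x
  }
  p <- oracle_probability(oracle, x)
  positive <- p >= 0.5
  lp <- log(max(p, 1 - p))
  pid <- NA_character_
  if (!is.numeric(record) && !is.null(record[["patient_id"]]))
    pid <- as.character(record[["patient_id"]])
  data.frame(patient_id = pid,
             model_id = "mock_oracle",
             variant = NA_character_,
             predicted_label = if (positive) labels[2] else labels[1],
             logprob_sum = lp,
             P = exp(lp),
             p_positive = p,
             stringsAsFactors = FALSE)
}

# conventional ML baseline -----------------------------------------------------

#' Inner cross-validation configuration for the ML baseline
#'
#' The inner scheme is a pure function of the training size: leave-one-out
#' for `TR <= 20`, stratified 3-fold otherwise. Hyperparameters are scored
#' by inner ROC-AUC (pooled held-out predictions under LOOCV, mean of fold
#' AUCs under 3-fold). Inner folds whose training part lacks a class
#' contribute the degenerate probability 0.5.
#'
#' @param TR Training size.
#' @param grids Named list of per-family hyperparameter grids (data
#'   frames); defaults to [default_grids()].
#' @return A `nested_cv_config`.
#' @export
nested_cv_config <- function(TR, grids = default_grids()) {
  structure(list(TR = TR,
                 scheme = if (TR <= 20) "loocv" else "3fold",
                 grids = grids,
                 degenerate_probability = 0.5),
            class = "nested_cv_config")
}

#' Default hyperparameter grids for the conventional baselines
#'
#' Small grids appropriate for training sizes of a few tens of patients:
#' ridge-penalized logistic regression over inverse-regularization
#' strengths, random forests over depth and leaf-size, gradient-boosted
#' trees over learning rate, leaf count and rounds. Override by passing
#' your own data frames to [nested_cv_config()].
#'
#' @return Named list of data frames (`lr`, `rf`, `gbt`).
#' @export
default_grids <- function() {
  list(
    lr = data.frame(C = c(0.01, 0.1, 1, 10)),
    rf = expand.grid(num_trees = 100, max_depth = c(2, 4, 0),
                     min_node = c(1, 2)),
    gbt = expand.grid(eta = c(0.05, 0.1), leaves = c(3, 7),
                      nrounds = c(50, 100)))
}

balanced_weights <- function(y) {
  n <- length(y)
  w <- numeric(n)
  for (cls in c(0, 1)) {
    nc <- sum(y == cls)
    if (nc > 0) w[y == cls] <- n / (2 * nc)
  }
  w
}

# Ridge-penalized logistic regression by Newton/IRLS, with the
# inverse-regularization convention (loss + ||beta||^2 / (2C), intercept
# unpenalized) and observation weights. Unlike off-the-shelf fitters it
# tolerates a class with a single observation, which the inner LOOCV
# produces routinely at training size 10.
ridge_logistic <- function(x, y, weights, C, max_iter = 100L, tol = 1e-9) {
  X <- cbind(1, x)
  p <- ncol(X)
  pen <- c(0, rep(1 / C, p - 1))
  beta <- numeric(p)
  for (it in seq_len(max_iter)) {
    mu <- stats::plogis(drop(X %*% beta))
    grad <- drop(crossprod(X, weights * (mu - y))) + pen * beta
    wd <- weights * mu * (1 - mu)
    H <- crossprod(X, X * wd) + diag(pen, p)
    step <- tryCatch(solve(H + diag(1e-10, p), grad),
                     error = function(e) grad * 0)
    beta <- beta - step
    if (max(abs(step)) < tol) break
  }
  beta
}

predict_ridge_logistic <- function(beta, xtest) {
  stats::plogis(drop(cbind(1, xtest) %*% beta))
}

fit_predict_family <- function(family, x, y, w, params, xtest, seed) {
  switch(family,
    lr = {
      beta <- ridge_logistic(x, y, w, params$C)
      predict_ridge_logistic(beta, xtest)
    },
    rf = {
      fit <- ranger::ranger(
        x = as.data.frame(x), y = factor(y, levels = c(0, 1)),
        num.trees = params$num_trees,
        max.depth = params$max_depth,
        min.node.size = params$min_node,
        probability = TRUE,
        class.weights = c(`0` = length(y) / (2 * sum(y == 0)),
                          `1` = length(y) / (2 * sum(y == 1))),
        seed = seed, num.threads = 1)
      stats::predict(fit, data = as.data.frame(xtest),
                     num.threads = 1)$predictions[, "1"]
    },
    gbt = {
      dtrain <- xgboost::xgb.DMatrix(x, label = y, weight = w, nthread = 1)
      fit <- xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      eta = params$eta,
                      tree_method = "hist",
                      grow_policy = "lossguide",
                      max_leaves = params$leaves,
                      max_depth = 0,
                      nthread = 1,
                      seed = seed),
        data = dtrain, nrounds = params$nrounds, verbose = 0)
      stats::predict(fit, xgboost::xgb.DMatrix(xtest, nthread = 1))
    },
    stop("unknown model family '", family, "'", call. = FALSE))
}

inner_folds <- function(y, scheme, seed) {
  n <- length(y)
  if (scheme == "loocv") return(as.list(seq_len(n)))
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  fold_of <- integer(n)
  for (cls in c(0, 1)) {
    members <- which(y == cls)
    members <- members[sample.int(length(members))]
    fold_of[members] <- rep_len(1:3, length(members))
  }
  lapply(1:3, function(f) which(fold_of == f))
}

inner_score <- function(family, x, y, params, folds, scheme, seed) {
  held_p <- rep(NA_real_, length(y))
  fold_auc <- numeric(0)
  for (fold in folds) {
    ytr <- y[-fold]
    if (length(unique(ytr)) < 2) {
      held_p[fold] <- 0.5  # degenerate inner fold: one-class training part
      next
    }
    sc <- standard_scale(x[-fold, , drop = FALSE], x[fold, , drop = FALSE])
    w <- balanced_weights(ytr)
    held_p[fold] <- fit_predict_family(family, sc$train, ytr, w, params,
                                       sc$test, seed)
    if (scheme == "3fold" && length(unique(y[fold])) == 2)
      fold_auc <- c(fold_auc, roc_auc(held_p[fold], y[fold]))
  }
  if (scheme == "loocv") {
    if (length(unique(y)) < 2) return(NA_real_)
    roc_auc(held_p, y)
  } else {
    if (!length(fold_auc)) return(NA_real_)
    mean(fold_auc)
  }
}

#' Fit a conventional ML baseline with nested grid search and predict
#'
#' Runs the nested hyperparameter search inside the training set (inner
#' LOOCV for `TR <= 20`, stratified 3-fold otherwise; standard scaling
#' refit inside every inner training part to avoid leakage), selects the
#' grid point with the best inner ROC-AUC, refits on the full training
#' set with balanced class weights, and predicts the test set.
#'
#' @param train_x Numeric training matrix (rownames = patient ids).
#' @param train_y Binary 0/1 training labels.
#' @param test_x Numeric test matrix with the same columns.
#' @param family `"lr"`, `"rf"` or `"gbt"`.
#' @param config A [nested_cv_config()]; defaults to one derived from the
#'   training size.
#' @param seed Integer seed (inner fold assignment, tree models).
#' @return Data frame of prediction records (`patient_id`, `model_id`,
#'   `p_positive`, `predicted_label` at the 0.5 convention); the selected
#'   grid point is attached as attribute `"best_params"`.
#' @export
fit_predict_ml <- function(train_x, train_y, test_x,
                           family = c("lr", "rf", "gbt"),
                           config = nested_cv_config(nrow(train_x)),
                           seed = 1L) {
  family <- match.arg(family)
  train_x <- as.matrix(train_x); test_x <- as.matrix(test_x)
  grid <- config$grids[[family]]
  if (is.null(grid) || nrow(grid) == 0)
    stop("empty hyperparameter grid for family '", family, "'", call. = FALSE)
  ids <- rownames(test_x)
  if (is.null(ids)) ids <- paste0("t", seq_len(nrow(test_x)))
  if (length(unique(train_y)) < 2) {
    warning("one-class training set: all test probabilities set to ",
            config$degenerate_probability, call. = FALSE)
    p <- rep(config$degenerate_probability, nrow(test_x))
    return(ml_records(ids, p, family))
  }
  seeds <- derive_seeds(seed, 2)
  if (nrow(grid) == 1) {
    best <- grid[1, , drop = FALSE]
  } else {
    folds <- inner_folds(train_y, config$scheme, seeds[1])
    scores <- vapply(seq_len(nrow(grid)), function(g)
      inner_score(family, train_x, train_y, grid[g, , drop = FALSE],
                  folds, config$scheme, seeds[2]), numeric(1))
    scores[is.na(scores)] <- -Inf
    best <- grid[which.max(scores), , drop = FALSE]
  }
  sc <- standard_scale(train_x, test_x)
  p <- fit_predict_family(family, sc$train, train_y, balanced_weights(train_y),
                          best, sc$test, seeds[2])
  out <- ml_records(ids, p, family)
  attr(out, "best_params") <- best
  out
}

ml_records <- function(ids, p, family) {
  data.frame(patient_id = ids,
             model_id = family,
             variant = NA_character_,
             predicted_label = ifelse(p >= 0.5, "1", "0"),
             logprob_sum = log(pmax(p, 1 - p)),
             P = pmax(p, 1 - p),
             p_positive = p,
             stringsAsFactors = FALSE)
}

#' Write prediction records as CSV
#' @param records Data frame of prediction records.
#' @param path Output path.
#' @export
write_predictions_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}
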