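#' Plan an inverted cross-validation design
#'
#' In the inverted design the training folds are small and disjoint while
#' every test set is the large union of the remaining folds, so variance
#' across folds reflects training-set choice. The test size must be an
#' exact multiple of the training size, `TS = k * TR`, giving `k + 1`
#' folds; the number of selected training folds is fixed across training
#' sizes as `n_splits = (TR_max + TS) / TR_max`, the maximum number of
#' folds available at the largest training size.
#'
#' @param TR Training size for this plan.
#' @param TR_max Largest training size in the study (drives `n_splits`).
#' @param TS Fixed test size.
#' @return A `split_plan` with fields `TR`, `TS`, `k`, `n_folds`, `n_splits`.
#' @export
plan_splits <- function(TR, TR_max, TS) {
  stopifnot(TR >= 1, TR_max >= 1, TS >= 1)
  if (TS %% TR != 0)
    stop("TS (", TS, ") must be an exact multiple of TR (", TR, ")", call. = FALSE)
  if ((TR_max + TS) %% TR_max != 0)
    stop("TR_max + TS (", TR_max + TS, ") must be divisible by TR_max (",
         TR_max, "); n_splits would not be an integer", call. = FALSE)
  k <- TS %/% TR
  n_splits <- (TR_max + TS) %/% TR_max
  if (n_splits > k + 1)
    stop("n_splits (", n_splits, ") exceeds the number of folds (", k + 1,
         "); TR must not exceed TR_max", call. = FALSE)
  structure(list(TR = TR, TS = TS, k = k, n_folds = k + 1L,
                 n_splits = n_splits),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat("<split_plan> TR=", x$TR, " TS=", x$TS, " (k=", x$k, "), ",
      x$n_folds, " folds, ", x$n_splits, " training folds selected\n", sep = "")
  invisible(x)
}

#' Choose the fixed test size for a set of training sizes
#'
#' Returns the largest multiple `m` of every training size such that
#' `m + max(training_sizes)` still fits in the smallest cohort, so that a
#' single test size serves every plan.
#'
#' @param training_sizes Vector of training sizes (e.g. `c(10, 20, 50)`).
#' @param smallest_cohort Size of the smallest dataset in the study.
#' @return The fixed test size.
#' @export
choose_fixed_test_size <- function(training_sizes, smallest_cohort) {
  stopifnot(length(training_sizes) >= 1, all(training_sizes >= 1))
  l <- Reduce(lcm2, as.integer(training_sizes))
  m <- ((smallest_cohort - max(training_sizes)) %/% l) * l
  if (m < l)
    stop("no feasible test size: lcm(", paste(training_sizes, collapse = ","),
         ") = ", l, " plus the largest training size exceeds the cohort (",
         smallest_cohort, ")", call. = FALSE)
  as.integer(m)
}

gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)
lcm2 <- function(a, b) a %/% gcd2(a, b) * b

# Largest-remainder allocation of `count` items over bins with the given
# quotas; deterministic, ties broken by bin index.
largest_remainder <- function(count, quotas) {
  base <- floor(quotas)
  rem <- quotas - base
  left <- count - sum(base)
  if (left > 0) {
    extra <- order(rem, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

# Three deterministic sub-seeds from one root seed: cohort draw, fold
# assignment, training-fold selection. Fixing the consumption order
# guarantees that adding predictors never perturbs the splits.
derive_seeds <- function(seed, n = 3) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
}

#' Draw the stratified working sample S
#'
#' Randomly selects `(k + 1) * TR` patients from the full table, stratified
#' on the outcome by largest-remainder allocation so the class counts are
#' proportional to the full table's within integer rounding.
#'
#' @param table A labeled `patient_table` (no missing labels).
#' @param plan A [plan_splits()] result.
#' @param seed Integer seed for the draw.
#' @return A `sampled_cohort`: list with `ids`, `labels` (named 0/1 vector),
#'   `n_pos`, `n_neg`, and the source `table`.
#' @export
draw_sample <- function(table, plan, seed = 1L) {
  labs <- table_labels(table)
  if (anyNA(labs)) stop("draw_sample requires a fully labeled table", call. = FALSE)
  ids <- table$data$patient_id
  n_target <- (plan$k + 1L) * plan$TR
  if (length(ids) < n_target)
    stop("table has ", length(ids), " rows; plan needs (k+1)*TR = ",
         n_target, call. = FALSE)
  counts <- c(sum(labs == 0), sum(labs == 1))
  alloc <- largest_remainder(n_target, n_target * counts / sum(counts))
  if (any(alloc > counts))
    stop("stratified draw infeasible: a class is too small", call. = FALSE)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  take <- c(sample(ids[labs == 0], alloc[1]), sample(ids[labs == 1], alloc[2]))
  take <- take[order(match(take, ids))]  # keep source table order
  lab_take <- labs[match(take, ids)]
  structure(list(ids = take, labels = stats::setNames(lab_take, take),
                 n_pos = sum(lab_take == 1), n_neg = sum(lab_take == 0),
                 table = table, plan = plan, seed = seed),
            class = "sampled_cohort")
}

#' @export
print.sampled_cohort <- function(x, ...) {
  cat("<sampled_cohort> ", length(x$ids), " patients (", x$n_pos,
      " positive), plan TR=", x$plan$TR, " TS=", x$plan$TS, "\n", sep = "")
  invisible(x)
}

#' Materialize the inverted cross-validation splits
#'
#' Partitions the sampled cohort into `k + 1` disjoint stratified folds of
#' size `TR` (largest-remainder allocation of each class over folds, then a
#' random deal), selects `n_splits` folds without replacement as training
#' folds, and pairs each with the union of the remaining `k` folds as its
#' test set.
#'
#' @param cohort A [draw_sample()] result.
#' @param plan A [plan_splits()] result (defaults to the cohort's plan).
#' @param seed Integer seed driving fold assignment and fold selection.
#' @return A `split_set`: list of splits, each with `split_id`, `train_ids`
#'   (size TR), `test_ids` (size TS), plus `folds`, `plan` and `cohort`.
#' @export
make_splits <- function(cohort, plan = cohort$plan, seed = 1L) {
  n <- length(cohort$ids)
  if (n != (plan$k + 1L) * plan$TR)
    stop("cohort size ", n, " != (k+1)*TR = ", (plan$k + 1L) * plan$TR, call. = FALSE)
  n_folds <- plan$n_folds
  seeds <- derive_seeds(seed, 2)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))

  # stratified fold assignment: positives by largest-remainder allocation
  # (the +1 remainders spread over random folds), negatives fill each fold
  # to exactly TR
  set.seed(seeds[1])
  pos <- which(cohort$labels == 1)
  neg <- which(cohort$labels == 0)
  if (length(pos) < n_folds || length(neg) < n_folds)
    warning("a class has fewer members than folds; some folds lack it",
            call. = FALSE)
  pos_alloc <- largest_remainder(length(pos),
                                 rep(length(pos) / n_folds, n_folds))
  pos_alloc <- pos_alloc[sample.int(n_folds)]
  while (any(pos_alloc > plan$TR)) {  # extreme prevalence: best effort
    i <- which.max(pos_alloc); j <- which.min(pos_alloc)
    pos_alloc[i] <- pos_alloc[i] - 1L; pos_alloc[j] <- pos_alloc[j] + 1L
  }
  neg_alloc <- plan$TR - pos_alloc
  shuffle <- function(x) x[sample.int(length(x))]
  fold_of <- integer(n)
  fold_of[shuffle(pos)] <- rep.int(seq_len(n_folds), pos_alloc)
  fold_of[shuffle(neg)] <- rep.int(seq_len(n_folds), neg_alloc)

  set.seed(seeds[2])
  train_folds <- sort(sample.int(n_folds, plan$n_splits, replace = FALSE))

  folds <- split(cohort$ids, fold_of)
  splits <- lapply(seq_along(train_folds), function(i) {
    f <- train_folds[i]
    list(split_id = i,
         train_fold = f,
         train_ids = folds[[f]],
         test_ids = unlist(folds[-f], use.names = FALSE))
  })
  structure(list(splits = splits, folds = folds, train_folds = train_folds,
                 plan = plan, cohort = cohort, seed = seed),
            class = "split_set")
}

#' @export
print.split_set <- function(x, ...) {
  cat("<split_set> ", length(x$splits), " splits (train ", x$plan$TR,
      " / test ", x$plan$TS, "), ", x$plan$n_folds, " folds\n", sep = "")
  invisible(x)
}

#' Draw the sample and materialize splits in one call
#'
#' Runs [draw_sample()] and [make_splits()] under a single root seed with a
#' fixed sub-stream order (cohort draw, fold assignment, fold selection),
#' so the full geometry is bit-reproducible from `seed` alone.
#'
#' @inheritParams draw_sample
#' @return A `split_set`.
#' @export
sample_and_split <- function(table, plan, seed = 1L) {
  seeds <- derive_seeds(seed, 2)
  cohort <- draw_sample(table, plan, seed = seeds[1])
  make_splits(cohort, plan, seed = seeds[2])
}

#' Serialize a split set to JSON
#' @param splits A `split_set`.
#' @param path Output path.
#' @export
write_splits <- function(splits, path) {
  out <- list(
    plan = unclass(splits$plan),
    seed = splits$seed,
    splits = lapply(splits$splits, function(s)
      list(split_id = s$split_id, train_ids = s$train_ids,
           test_ids = s$test_ids)))
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
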