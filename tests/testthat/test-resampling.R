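# build fold predictions for a scenario through the package's own geometry
make_fp <- function(seed = 1, n = 600, prevalence = 0.3, TR = 10, TS = 100,
                    shift = 1.0, noise = 0, model_id = "m") {
  sc <- gaussian_scenario(n = n, prevalence = prevalence, n_features = 2,
                          shift = shift)
  gen <- generate_cohort(sc, seed = seed)
  oracle <- make_oracle(sc, effect_scale = 1, mc_n = 5000, seed = seed + 1)
  plan <- plan_splits(TR, TR, TS)
  ss <- sample_and_split(gen$table, plan, seed = seed + 2)
  enc <- encode_table(gen$table)
  p_all <- iclbench:::oracle_probability(oracle, enc$x)
  names(p_all) <- rownames(enc$x)
  if (noise > 0) {
    set.seed(seed + 3)
    p_all <- plogis(qlogis(p_all) + rnorm(length(p_all), 0, noise))
  }
  rec <- do.call(rbind, lapply(ss$splits, function(s)
    data.frame(patient_id = s$test_ids, split_id = s$split_id,
               p_positive = unname(p_all[s$test_ids]))))
  list(fp = fold_predictions(rec, ss$cohort$labels, model_id = model_id),
       splits = ss, rec = rec)
}

test_that("degenerate inputs give degenerate intervals", {
  y <- c(rep(1, 5), rep(0, 15))
  ids <- paste0("p", 1:20)
  rec <- data.frame(patient_id = rep(ids, 2),
                    split_id = rep(1:2, each = 20),
                    p_positive = rep(c(rep(0.9, 5), rep(0.1, 15)), 2))
  fp <- fold_predictions(rec, setNames(y, ids))
  cfg <- bootstrap_config(n_ci = 200, n_pi = 200, seed = 4)
  # metric constant across patients and folds: zero-width interval at 1
  ci <- ci_fold_mean(fp, "roc_auc", cfg)
  expect_equal(ci$point, 1)
  expect_equal(ci$lower, 1)
  expect_equal(ci$upper, 1)
  pi1 <- prediction_interval(fp, "roc_auc", cfg)
  expect_equal(pi1$lower, 1)
  expect_equal(pi1$upper, 1)
})

test_that("intervals are deterministic given config and seed", {
  r <- make_fp(seed = 5)
  cfg <- bootstrap_config(n_ci = 500, n_pi = 500, seed = 42)
  a <- ci_fold_mean(r$fp, "roc_auc", cfg)
  b <- ci_fold_mean(r$fp, "roc_auc", cfg)
  expect_identical(a, b)
  c <- ci_fold_mean(r$fp, "roc_auc", bootstrap_config(n_ci = 500, seed = 43))
  expect_false(identical(a$lower, c$lower))
  pa <- prediction_interval(r$fp, "average_precision", cfg)
  pb <- prediction_interval(r$fp, "average_precision", cfg)
  expect_identical(pa, pb)
})

test_that("weighted bootstrap metrics equal plain metrics on expanded multisets", {
  # single fold, forced resample weights reproduced by expansion
  set.seed(8)
  n <- 60
  y <- rbinom(n, 1, 0.4); y[1:2] <- c(0, 1)
  p <- runif(n)
  ids <- paste0("p", seq_len(n))
  rec <- data.frame(patient_id = ids, split_id = 1, p_positive = p)
  fp <- fold_predictions(rec, setNames(y, ids))
  for (metric in c("roc_auc", "average_precision", "brier")) {
    ci <- ci_fold_mean(fp, metric, bootstrap_config(n_ci = 50, seed = 2),
                       keep_replicates = TRUE)
    reps <- attr(ci, "replicates")
    # recompute replicate 1 by hand with the same uniform draws the
    # C++ stream consumes (floor(u * n) indexing)
    set.seed(2)
    pos <- which(y == 1); neg <- which(y == 0)
    take <- c(pos[floor(runif(length(pos)) * length(pos)) + 1],
              neg[floor(runif(length(neg)) * length(neg)) + 1])
    f <- switch(metric, roc_auc = roc_auc,
                average_precision = average_precision, brier = brier_score)
    expect_equal(reps[1], f(p[take], y[take]), tolerance = 1e-12)
  }
})

test_that("paired replicates difference equals difference of marginal replicates", {
  a <- make_fp(seed = 9, model_id = "A")
  b_rec <- a$rec
  set.seed(99)
  b_rec$p_positive <- plogis(qlogis(pmin(pmax(b_rec$p_positive, 1e-6),
                                         1 - 1e-6)) +
                               rnorm(nrow(b_rec), 0, 0.5))
  fp_b <- fold_predictions(b_rec, a$splits$cohort$labels, model_id = "B")
  cfg <- bootstrap_config(n_ci = 300, n_pi = 300, seed = 7)
  for (mode in c("ci", "pi")) {
    pd <- paired_difference(a$fp, fp_b, "roc_auc", mode, cfg,
                            keep_replicates = TRUE)
    reps <- attr(pd, "replicates")
    fa <- if (mode == "ci") ci_fold_mean(a$fp, "roc_auc", cfg,
                                         keep_replicates = TRUE)
          else prediction_interval(a$fp, "roc_auc", cfg, keep_replicates = TRUE)
    fb <- if (mode == "ci") ci_fold_mean(fp_b, "roc_auc", cfg,
                                         keep_replicates = TRUE)
          else prediction_interval(fp_b, "roc_auc", cfg, keep_replicates = TRUE)
    expect_equal(reps[, 1] - reps[, 2],
                 attr(fa, "replicates") - attr(fb, "replicates"),
                 tolerance = 1e-12)
  }
})

test_that("self-comparison and reflection identities hold for differences", {
  r <- make_fp(seed = 12)
  cfg <- bootstrap_config(n_ci = 400, seed = 3)
  self <- paired_difference(r$fp, r$fp, "roc_auc", "ci", cfg)
  expect_equal(self$point, 0)
  expect_equal(self$lower, 0)
  expect_equal(self$upper, 0)

  flipped <- r$rec
  flipped$p_positive <- 1 - flipped$p_positive
  fp_flip <- fold_predictions(flipped, r$splits$cohort$labels, "flip")
  pd <- paired_difference(r$fp, fp_flip, "roc_auc", "ci", cfg)
  expect_equal(pd$point,
               mean(2 * iclbench:::fold_point_values(r$fp, "roc_auc") - 1),
               tolerance = 1e-12)

  bad <- r$rec[r$rec$split_id != 1, ]
  fp_bad <- fold_predictions(bad, r$splits$cohort$labels, "short")
  expect_error(paired_difference(r$fp, fp_bad, "roc_auc", "ci", cfg),
               "identical fold/test geometry")
})

test_that("a constructed better model yields a strictly positive lower bound", {
  a <- make_fp(seed = 15, TS = 200, shift = 1.2, model_id = "good")
  worse <- a$rec
  set.seed(16)
  worse$p_positive <- plogis(0.3 * qlogis(pmin(pmax(worse$p_positive, 1e-6),
                                               1 - 1e-6)) +
                               rnorm(nrow(worse), 0, 1.5))
  fp_w <- fold_predictions(worse, a$splits$cohort$labels, "bad")
  pd <- paired_difference(a$fp, fp_w, "roc_auc", "ci",
                          bootstrap_config(n_ci = 1000, seed = 8))
  expect_gt(pd$point, 0)
  expect_gt(pd$lower, 0)
})

test_that("prediction intervals mix fold-level values as a two-point mixture", {
  # two folds with well-separated stable metric values and negligible
  # within-fold noise: the interval spans roughly [low, high]
  n_per <- 2000
  make_scores <- function(auc_target, y) {
    # scores = y with gaussian blur tuned to the target separation
    delta <- sqrt(2) * qnorm(auc_target)
    rnorm(length(y), mean = y * delta)
  }
  set.seed(21)
  y <- rep(c(0, 1), each = n_per / 2)
  ids <- paste0("p", seq_len(n_per))
  s1 <- make_scores(0.6, y)
  s2 <- make_scores(0.9, y)
  rec <- rbind(data.frame(patient_id = ids, split_id = 1, p_positive = plogis(s1)),
               data.frame(patient_id = ids, split_id = 2, p_positive = plogis(s2)))
  fp <- fold_predictions(rec, setNames(y, ids))
  pi2 <- prediction_interval(fp, "roc_auc",
                             bootstrap_config(n_pi = 4000, seed = 31))
  expect_lt(abs(pi2$lower - 0.6), 0.05)
  expect_lt(abs(pi2$upper - 0.9), 0.05)

  # identical folds: fold choice is irrelevant and the interval matches a
  # patient-resampling-only interval
  rec_same <- rbind(
    data.frame(patient_id = ids, split_id = 1, p_positive = plogis(s1)),
    data.frame(patient_id = ids, split_id = 2, p_positive = plogis(s1)))
  fp_same <- fold_predictions(rec_same, setNames(y, ids))
  rec_one <- data.frame(patient_id = ids, split_id = 1,
                        p_positive = plogis(s1))
  fp_one <- fold_predictions(rec_one, setNames(y, ids))
  cfgp <- bootstrap_config(n_pi = 4000, seed = 5)
  p_two <- prediction_interval(fp_same, "roc_auc", cfgp)
  p_one <- prediction_interval(fp_one, "roc_auc", cfgp)
  expect_equal(p_two$lower, p_one$lower, tolerance = 0.005)
  expect_equal(p_two$upper, p_one$upper, tolerance = 0.005)
})

test_that("masked resampling preserves between-fold correlation from overlap", {
  # three single-fold prediction sets over one cohort: two overlapping
  # test sets and one disjoint; replicate streams share the patient
  # resample via the common seed
  set.seed(44)
  n <- 900
  y <- rbinom(n, 1, 0.35); y[1:2] <- c(0, 1)
  ids <- paste0("p", seq_len(n))
  scores <- plogis(qlogis(0.35) + 1.4 * y + rnorm(n))
  cohort <- setNames(y, ids)
  idx_a <- 1:400
  idx_b <- 11:410   # 390 of 400 shared with a
  idx_c <- 501:900  # disjoint from a
  stream <- function(idx) {
    rec <- data.frame(patient_id = ids[idx], split_id = 1,
                      p_positive = scores[idx])
    fp <- fold_predictions(rec, cohort)
    attr(ci_fold_mean(fp, "roc_auc",
                      bootstrap_config(n_ci = 800, seed = 77),
                      keep_replicates = TRUE), "replicates")
  }
  ra <- stream(idx_a); rb <- stream(idx_b); rc <- stream(idx_c)
  expect_gt(stats::cor(ra, rb), stats::cor(ra, rc))
  expect_gt(stats::cor(ra, rb), 0.9)
})

test_that("interval results serialize to JSON", {
  r <- make_fp(seed = 18)
  ci <- ci_fold_mean(r$fp, "roc_auc", bootstrap_config(n_ci = 200, seed = 1))
  path <- withr::local_tempfile(fileext = ".json")
  write_interval_json(ci, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$metric, "roc_auc")
  expect_equal(back$n_replicates, 200)
  expect_equal(back$lower, ci$lower)
})
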