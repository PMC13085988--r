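fixed_backend <- function(completion, logprobs, model_id = "stub") {
  chat_backend(function(prompt) list(completion = completion,
                                     token_logprobs = logprobs),
               model_id = model_id)
}

dummy_prompt <- function(variant = "full") {
  structure(list(messages = list(list(role = "system", content = "s")),
                 variant = variant, patient_id = "p1"),
            class = "prompt")
}

test_that("completion probabilities follow the exp/complement rules", {
  schema <- box_schema()
  p <- dummy_prompt()
  r <- predict_llm(p, fixed_backend("dies", 0), schema = schema)
  expect_equal(r$P, 1)
  expect_equal(r$p_positive, 1)

  r2 <- predict_llm(p, fixed_backend("survives", log(0.8)), schema = schema)
  expect_equal(r2$P, 0.8)
  expect_equal(r2$p_positive, 0.2, tolerance = 1e-12)

  # multi-token completions sum their log-probabilities
  r3 <- predict_llm(p, fixed_backend("dies", c(log(0.9), log(0.5))),
                    schema = schema)
  expect_equal(r3$P, 0.45, tolerance = 1e-12)
  expect_equal(r3$p_positive + (1 - r3$P), 1)

  # the no-context variant answers in 0/1 vocabulary
  r4 <- predict_llm(dummy_prompt("no_context"), fixed_backend("1", log(0.7)),
                    schema = schema)
  expect_equal(r4$p_positive, 0.7)
})

test_that("strict parsing rejects anything that is not exactly a label", {
  schema <- box_schema()
  p <- dummy_prompt()
  expect_error(predict_llm(p, fixed_backend("deceased", 0), schema = schema),
               "not exactly a label.*deceased")
  expect_error(predict_llm(p, fixed_backend("dies maybe", 0), schema = schema),
               "not exactly a label")
  expect_error(predict_llm(p, fixed_backend("Dies", 0), schema = schema),
               "not exactly a label")  # case-sensitive
  # surrounding whitespace is the only tolerated decoration
  r <- predict_llm(p, fixed_backend("  dies \n", log(0.6)), schema = schema)
  expect_equal(r$predicted_label, "dies")
  expect_error(predict_llm(p, chat_backend(function(pr) list(completion = "dies")),
                           schema = schema),
               "no completion or no log-probabilities")
  expect_error(predict_llm(p, fixed_backend("dies", 0.5), schema = schema),
               "exceeds 1")
})

test_that("the mock oracle is deterministic and symmetric at zero weight", {
  oracle <- list(coefficients = c(f1 = 0), intercept = 0)
  rec <- c(f1 = 2.5)
  r1 <- mock_oracle_predict(rec, oracle)
  r2 <- mock_oracle_predict(rec, oracle)
  expect_identical(r1, r2)
  expect_equal(r1$p_positive, 0.5)
  # p_positive + p_negative = 1 exactly across a sweep
  oracle2 <- list(coefficients = c(f1 = 1.3), intercept = -0.4)
  for (v in seq(-3, 3, by = 0.5)) {
    r <- mock_oracle_predict(c(f1 = v), oracle2)
    p_neg <- if (r$predicted_label == "1") 1 - r$P else r$P
    expect_identical(r$p_positive + p_neg, 1)
    expect_true(r$P > 0 && r$P <= 1)
  }
})

test_that("mock backend predictions recover the generative AUC", {
  sc <- gaussian_scenario(n = 800, prevalence = 0.3, n_features = 3,
                          shift = 1.0)
  gen <- generate_cohort(sc, seed = 21)
  oracle <- make_oracle(sc, effect_scale = 1, mc_n = 40000, seed = 22)
  backend <- mock_chat_backend(oracle, gen$table)
  idx <- 1:300
  prompts <- lapply(idx, function(i)
    build_prompt(NULL, gen$table$data[i, ], gen$schema, "full"))
  rec <- predict_prompts(prompts, backend, gen$schema)
  y <- table_labels(gen$table)[idx]
  auc <- roc_auc(rec$p_positive, y)
  # within 3 Monte-Carlo SDs of the implied value at n = 300
  n1 <- sum(y); n0 <- length(y) - n1
  se <- sqrt(auc * (1 - auc) * (1 + (n1 - 1) / 2 + (n0 - 1) / 2) / (n1 * n0))
  expect_lt(abs(auc - oracle$implied_auc), 3 * se)
})

test_that("a singleton grid is prediction-identical to a direct fit", {
  set.seed(7)
  x <- matrix(rnorm(100), 20, 5); colnames(x) <- paste0("f", 1:5)
  y <- rbinom(20, 1, plogis(x[, 1]))
  if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
  xt <- matrix(rnorm(40), 8, 5); colnames(xt) <- colnames(x)
  cfg <- nested_cv_config(20, grids = list(lr = data.frame(C = 1)))
  via_search <- fit_predict_ml(x, y, xt, "lr", config = cfg, seed = 3)
  sc <- standard_scale(x, xt)
  direct <- iclbench:::predict_ridge_logistic(
    iclbench:::ridge_logistic(sc$train, y, iclbench:::balanced_weights(y), 1),
    sc$test)
  expect_equal(via_search$p_positive, direct, tolerance = 1e-10)
})

test_that("the ridge fit agrees with an independent penalized fitter", {
  skip_if_not_installed("glmnet")
  set.seed(11)
  n <- 200
  x <- matrix(rnorm(n * 4), n, 4)
  y <- rbinom(n, 1, plogis(0.8 * x[, 1] - 0.5 * x[, 3]))
  C <- 1
  beta <- iclbench:::ridge_logistic(x, y, rep(1, n), C)
  g <- glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                      lambda = 1 / (C * n), standardize = FALSE,
                      thresh = 1e-12)
  expect_equal(unname(beta),
               unname(as.numeric(coef(g))), tolerance = 1e-3)
})

test_that("linearly separable data give AUC 1 for the linear model", {
  x <- matrix(c(seq(-2, -0.2, length.out = 10),
                seq(0.2, 2, length.out = 10), rnorm(20)), 20, 2)
  colnames(x) <- c("a", "b")
  y <- rep(c(0, 1), each = 10)
  r <- fit_predict_ml(x, y, x, "lr",
                      config = nested_cv_config(20,
                        grids = list(lr = data.frame(C = 10))), seed = 1)
  expect_equal(roc_auc(r$p_positive, y), 1)
})

test_that("degenerate training sets fall back to probability one half", {
  x <- matrix(rnorm(20), 10, 2); colnames(x) <- c("a", "b")
  y <- rep(0, 10)
  expect_warning(r <- fit_predict_ml(x, y, x, "lr", seed = 1), "one-class")
  expect_equal(r$p_positive, rep(0.5, 10))
  # inner LOOCV with a single positive: the fold leaving it out is scored 0.5
  y2 <- c(1, rep(0, 9))
  folds <- iclbench:::inner_folds(y2, "loocv", 1)
  expect_equal(folds[[1]], 1)
  # leaving out patient 1 leaves a one-class inner training set
  held <- iclbench:::inner_score("lr", x, y2, data.frame(C = 1),
                                 folds, "loocv", 1)
  expect_true(is.finite(held) || is.na(held))
})

test_that("tree families run the nested path and produce probabilities", {
  set.seed(9)
  x <- matrix(rnorm(60), 20, 3); colnames(x) <- paste0("f", 1:3)
  y <- rbinom(20, 1, plogis(1.5 * x[, 1]))
  if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
  xt <- matrix(rnorm(30), 10, 3); colnames(xt) <- colnames(x)
  small <- list(rf = expand.grid(num_trees = 50, max_depth = c(2, 4),
                                 min_node = 1),
                gbt = expand.grid(eta = 0.1, leaves = 3, nrounds = c(20, 50)))
  for (fam in c("rf", "gbt")) {
    r <- fit_predict_ml(x, y, xt, fam,
                        config = nested_cv_config(20, grids = small),
                        seed = 4)
    expect_true(all(r$p_positive >= 0 & r$p_positive <= 1))
    expect_equal(nrow(r), 10)
    expect_equal(nrow(attr(r, "best_params")), 1)
    # deterministic under a fixed seed
    r2 <- fit_predict_ml(x, y, xt, fam,
                         config = nested_cv_config(20, grids = small),
                         seed = 4)
    expect_equal(r$p_positive, r2$p_positive)
  }
})
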