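test_that("schema constructors enforce their invariants", {
  expect_error(feature_spec("g", "ordinal"), "ordinal_levels")
  expect_error(feature_spec("g", "categorical",
                            categorical_levels = c("a", "b"),
                            ordinal_levels = c("x", "y")),
               "ordinal_levels only")
  expect_error(feature_spec("s", "categorical",
                            categorical_levels = c("a", "b"),
                            rounding = "integer"),
               "rounding")
  expect_error(dataset_schema(list(feature_spec("x", "numerical")),
                              "y", "same", "same"),
               "label texts")
  expect_error(dataset_schema(list(feature_spec("x", "numerical")),
                              "y", "no", "yes",
                              threshold_interval = c(0.4, 0.2)),
               "threshold_interval")
})

test_that("CSV round trip preserves rows, types and missing markers", {
  tab <- toy_table(5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_table_csv(tab, path)
  back <- load_table(path, toy_schema())
  expect_equal(back$data, tab$data)

  # missing cells preserved as NA
  tab$data$crp[2] <- NA
  write_table_csv(tab, path)
  back <- load_table(path, toy_schema())
  expect_true(is.na(back$data$crp[2]))
})

test_that("unknown levels and non-numeric text are schema violations", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("patient_id,age,crp,stage,sex,y",
               "p1,40,12.3,IX,m,0"), path)
  expect_error(load_table(path, toy_schema()), "unknown level 'IX'")
  writeLines(c("patient_id,age,crp,stage,sex,y",
               "p1,forty,12.3,II,m,0"), path)
  expect_error(load_table(path, toy_schema()), "non-numeric value 'forty'")
})

test_that("the worked-example fixture loads with its printed raw values", {
  tab <- box_table()
  expect_equal(n_patients(tab), 11)
  expect_equal(tab$data$age[1], 38)
  expect_equal(tab$data$creatinine[1], 352)
  expect_equal(tab$data$gcs[1], 14)
  expect_true(is.na(tab$data$outcome[11]))
})

test_that("rounding follows the per-feature spec, half away from zero", {
  expect_equal(round_half_away(2.491, 1), 2.5)
  expect_equal(round_half_away(-2.45, 1), -2.5)
  expect_equal(round_half_away(0.125, 2), 0.13)
  tab <- toy_table(3)
  tab$data$crp <- c(1.24, 99.95, 0.05)
  tab <- apply_rounding(tab)
  expect_equal(tab$data$crp, c(1.2, 100.0, 0.1))
  tab$data$age <- c(38.0, 21.5, 77.49)
  tab <- apply_rounding(tab)
  expect_equal(tab$data$age, c(38, 22, 77))
})

test_that("near-duplicate screening matches the exhaustive pairwise oracle", {
  # identical feature rows -> one pair at distance zero; the toy labels
  # alternate, so the pair is label-discordant
  feats <- c("age", "crp", "stage", "sex")
  tab <- toy_table(4)
  tab$data[2, feats] <- tab$data[1, feats]
  rep <- detect_near_duplicates(tab)
  expect_equal(nrow(rep), 1)
  expect_equal(rep$max_scaled_abs_diff, 0)
  expect_false(rep$labels_concordant)

  # a 10% of SD difference is outside the 5% radius
  tab <- toy_table(4)
  tab$data[2, feats] <- tab$data[1, feats]
  s <- sqrt(mean((tab$data$crp - mean(tab$data$crp))^2))
  tab$data$crp[2] <- tab$data$crp[1] + 0.10 * s
  expect_equal(nrow(detect_near_duplicates(tab)), 0)

  # randomized tables up to 200 rows, with planted pairs, equal the oracle
  for (seed in 1:5) {
    sc <- gaussian_scenario(n = 50 + 30 * seed, n_features = 3,
                            defects = list(n_near_duplicate = 3))
    gen <- generate_cohort(sc, seed = seed)
    got <- detect_near_duplicates(gen$table)
    want <- near_dup_oracle(gen$table)
    expect_equal(got[c("id_a", "id_b")], want[c("id_a", "id_b")],
                 ignore_attr = TRUE)
    expect_equal(got$max_scaled_abs_diff, want$max_scaled_abs_diff,
                 tolerance = 1e-12)
  }
})

test_that("cleaning removes rows in policy order and logs every removal", {
  sc <- gaussian_scenario(n = 100, n_features = 3,
                          defects = list(n_missing = 5, n_duplicate = 2))
  gen <- generate_cohort(sc, seed = 11)
  cleaned <- clean_table(gen$table, cleaning_policy())
  expect_equal(n_patients(cleaned), 93)
  log <- attr(cleaned, "cleaning_log")
  expect_equal(sum(log$rule == "missing"), 5)
  expect_equal(sum(log$rule == "exact_duplicate"), 2)
  expect_setequal(log$patient_id[log$rule == "missing"],
                  gen$manifest$missing_rows)

  # drop-both near-duplicate policy leaves an empty report behind;
  # 6 continuous features make accidental extra pairs vanishingly rare,
  # so exactly the planted pairs are dropped
  sc2 <- gaussian_scenario(n = 80, n_features = 6,
                           defects = list(n_near_duplicate = 4))
  gen2 <- generate_cohort(sc2, seed = 12)
  cleaned2 <- clean_table(gen2$table,
                          cleaning_policy(near_duplicates = "drop_both"))
  expect_equal(nrow(detect_near_duplicates(cleaned2)), 0)
  expect_equal(n_patients(cleaned2), 80 - 8)
})

test_that("near-duplicate pairs differing in precision keep the finer row", {
  schema <- dataset_schema(
    list(feature_spec("ldh", "numerical", rounding = "one_decimal"),
         feature_spec("age", "numerical", rounding = "integer")),
    "y", "no", "yes")
  dat <- data.frame(patient_id = c("a", "b", "c", "d"),
                    ldh = c(231.4, 231, 500, 900),
                    age = c(60, 60, 40, 20),
                    y = c(1, 1, 0, 0))
  tab <- patient_table(dat, schema)
  cleaned <- clean_table(tab, cleaning_policy(
    near_duplicates = "keep_finer_precision", tolerance = 0.05))
  # "b" carries the coarser ldh value and is dropped
  expect_setequal(cleaned$data$patient_id, c("a", "c", "d"))
  expect_error(clean_table(tab, cleaning_policy(
    zero_biomarker_features = "nope")), "unknown features")
})

test_that("encoding maps kinds to columns as declared", {
  tab <- toy_table(6)
  enc <- encode_table(tab)
  expect_equal(colnames(enc$x), c("age", "crp", "stage", "sex"))
  expect_equal(enc$x[, "stage"],
               setNames(match(tab$data$stage, c("I", "II", "III")) - 1,
                        tab$data$patient_id))
  expect_equal(unname(enc$x[, "sex"]), as.numeric(tab$data$sex == "f"))

  # binary gender over the worked-example training rows: one column,
  # five ones (female) and five zeros
  enc_box <- encode_table(box_train())
  expect_equal(sum(enc_box$x[, "gender"]), 5)
  expect_equal(ncol(enc_box$x), 20)

  # 3-level categoricals expand to one-hot summing to 1
  schema3 <- dataset_schema(
    list(feature_spec("site", "categorical",
                      categorical_levels = c("a", "b", "c"))),
    "y", "no", "yes")
  tab3 <- patient_table(
    data.frame(patient_id = c("x", "y", "z"), site = c("a", "c", "b"),
               y = c(0, 1, 0)), schema3)
  enc3 <- encode_table(tab3)
  expect_equal(ncol(enc3$x), 3)
  expect_equal(unname(rowSums(enc3$x)), rep(1, 3))

  tab$data$crp[1] <- NA
  expect_error(encode_table(tab), "missing")
})

test_that("standard scaling uses the population SD and handles degeneracy", {
  x <- matrix(rnorm(60), 20, 3)
  sc <- standard_scale(x, x[1:5, , drop = FALSE])
  expect_true(all(abs(colMeans(sc$train)) < 1e-9))
  expect_true(all(abs(apply(sc$train, 2, function(c)
    sqrt(mean((c - mean(c))^2))) - 1) < 1e-9))
  # test transformed with train parameters
  expect_equal(sc$test, sc$train[1:5, , drop = FALSE])

  const <- matrix(c(1, 1, 1, 2, 3, 4), 3, 2)
  sc2 <- standard_scale(const, matrix(c(9, 5), 1, 2))
  expect_equal(unname(sc2$train[, 1]), rep(0, 3))
  expect_equal(unname(sc2$test[1, 1]), 0)
})

test_that("scaling the worked example reproduces every printed value", {
  enc_train <- encode_table(box_train())
  test_tab <- box_table()
  test_tab$data <- test_tab$data[11, ]
  enc_test <- encode_table(test_tab)
  sc <- standard_scale(enc_train$x, enc_test$x)
  train_rounded <- round_half_away(sc$train, 2)
  test_rounded <- round_half_away(sc$test[1, ], 2)

  # all 20 columns of the first training patient, as printed
  expect_equal(unname(train_rounded[1, ]),
               c(-0.26, 2.14, 0.15, 1.96, 1.5, 0.15, 0.43, -1.8, -1.22,
                 0.5, -0.93, -1.29, 0.95, 1.74, -1.13, -1.08, 0.41, -0.86,
                 0.07, 1.0))
  # all 20 columns of the test patient, as printed
  expect_equal(unname(test_rounded),
               c(-2.65, 0.2, -0.6, -0.23, -0.74, 0.15, 1.39, 0.95, 0.88,
                 -1.67, -0.93, -0.81, 2.06, -0.47, 0.95, -0.75, -0.61,
                 -0.76, 0.73, -1.0))
  # the sample-SD convention would print a different first-age value;
  # the population convention is the one the pipeline commits to
  ages <- box_train()$data$age
  expect_equal(round_half_away((ages[1] - mean(ages)) /
                                 stats::sd(ages), 2), -1.07)
  expect_equal(unname(train_rounded[1, "age"]), -1.13)
})
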