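#' Class-conditional feature generators
#'
#' Building blocks for [scenario_spec()]: each generator couples the
#' schema-facing description of a feature (display name, unit, rounding,
#' levels) with its class-conditional sampling distribution. Numerical
#' features are Gaussian per class with a location shift between classes
#' (optionally lognormal, to mimic right-skewed labs); categorical and
#' ordinal features draw levels from per-class probability vectors.
#'
#' @param name Feature name.
#' @param mean0,mean1 Class-conditional means (meanlog for lognormal).
#' @param sd Common within-class SD (sdlog for lognormal).
#' @param unit Optional display unit.
#' @param rounding Rounding rule (see [feature_spec()]).
#' @param dist `"gaussian"` or `"lognormal"`.
#' @param display_name Display name (defaults to `name`).
#' @return A `feature_gen` object.
#' @export
num_feature <- function(name, mean0, mean1, sd = 1, unit = NULL,
                        rounding = "one_decimal",
                        dist = c("gaussian", "lognormal"),
                        display_name = name) {
  dist <- match.arg(dist)
  stopifnot(sd > 0)
  structure(list(kind = "numerical", name = name, mean0 = mean0,
                 mean1 = mean1, sd = sd, unit = unit, rounding = rounding,
                 dist = dist, display_name = display_name),
            class = "feature_gen")
}

#' @rdname num_feature
#' @param levels Level texts (ordered for ordinal features).
#' @param p0,p1 Class-conditional level probabilities.
#' @export
cat_feature <- function(name, levels, p0, p1, display_name = name) {
  stopifnot(length(levels) >= 2, length(p0) == length(levels),
            length(p1) == length(levels))
  structure(list(kind = "categorical", name = name, levels = levels,
                 p0 = p0 / sum(p0), p1 = p1 / sum(p1),
                 display_name = display_name),
            class = "feature_gen")
}

#' @rdname num_feature
#' @export
ord_feature <- function(name, levels, p0, p1, display_name = name) {
  f <- cat_feature(name, levels, p0, p1, display_name)
  f$kind <- "ordinal"
  f
}

#' Define a synthetic cohort scenario
#'
#' A scenario fixes everything needed to generate a cohort with the
#' statistical structure the analysis assumes: size, outcome prevalence,
#' class-conditional feature distributions, the prompt texts, and a
#' defect plan (missing cells, exact duplicates, near duplicates) whose
#' ground truth is recorded in a manifest so cleaning tests are exact.
#'
#' @param n Cohort size (defect rows included).
#' @param prevalence Positive-outcome fraction, in (0, 1).
#' @param features List of feature generators ([num_feature()] etc.).
#' @param defects List with `n_missing`, `n_duplicate`, `n_near_duplicate`
#'   (counts of planted defect rows).
#' @param label_name,label_negative_text,label_positive_text Outcome
#'   naming (defaults `outcome`, `negative`, `positive`).
#' @param system_message,entity_phrase Prompt texts for the schema.
#' @param threshold_interval Clinically relevant interval for the schema.
#' @return A `scenario_spec`.
#' @export
scenario_spec <- function(n, prevalence, features,
                          defects = list(n_missing = 0, n_duplicate = 0,
                                         n_near_duplicate = 0),
                          label_name = "outcome",
                          label_negative_text = "negative",
                          label_positive_text = "positive",
                          system_message = "Classify the sample.",
                          entity_phrase = "Sample ->",
                          threshold_interval = c(0.05, 0.30)) {
  stopifnot(n >= 2, prevalence > 0, prevalence < 1, length(features) >= 1)
  defects <- utils::modifyList(
    list(n_missing = 0, n_duplicate = 0, n_near_duplicate = 0), defects)
  n_defect <- defects$n_duplicate + defects$n_near_duplicate
  if (n_defect >= n)
    stop("defect plan infeasible: more planted rows than the cohort", call. = FALSE)
  structure(list(n = n, prevalence = prevalence, features = features,
                 defects = defects, label_name = label_name,
                 label_negative_text = label_negative_text,
                 label_positive_text = label_positive_text,
                 system_message = system_message,
                 entity_phrase = entity_phrase,
                 threshold_interval = threshold_interval),
            class = "scenario_spec")
}

scenario_schema <- function(scenario) {
  feats <- lapply(scenario$features, function(g) {
    if (g$kind == "numerical")
      feature_spec(g$name, "numerical", display_name = g$display_name,
                   unit = g$unit, rounding = g$rounding)
    else if (g$kind == "ordinal")
      feature_spec(g$name, "ordinal", display_name = g$display_name,
                   ordinal_levels = g$levels)
    else
      feature_spec(g$name, "categorical", display_name = g$display_name,
                   categorical_levels = g$levels)
  })
  dataset_schema(feats,
                 label_name = scenario$label_name,
                 label_negative_text = scenario$label_negative_text,
                 label_positive_text = scenario$label_positive_text,
                 system_message = scenario$system_message,
                 entity_phrase = scenario$entity_phrase,
                 threshold_interval = scenario$threshold_interval)
}

draw_features <- function(scenario, y) {
  n <- length(y)
  out <- list()
  for (g in scenario$features) {
    if (g$kind == "numerical") {
      mu <- ifelse(y == 1, g$mean1, g$mean0)
      v <- stats::rnorm(n, mean = mu, sd = g$sd)
      if (g$dist == "lognormal") v <- exp(v)
      out[[g$name]] <- v
    } else {
      v <- character(n)
      for (cls in c(0, 1)) {
        idx <- which(y == cls)
        if (length(idx))
          v[idx] <- sample(g$levels, length(idx), replace = TRUE,
                           prob = if (cls == 1) g$p1 else g$p0)
      }
      out[[g$name]] <- v
    }
  }
  as.data.frame(out, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Generate a synthetic cohort
#'
#' Draws labels as independent Bernoulli trials at the scenario
#' prevalence (so the realized rate matches in expectation), samples
#' features class-conditionally, then plants the defect plan: exact
#' duplicate rows, near-duplicate rows (numerical values perturbed by at
#' most 1% of the feature SD, far inside the 5% screening radius;
#' categorical values copied), and missing cells (one blanked feature in
#' each affected base row). The ground truth of every planted defect is
#' returned in the manifest.
#'
#' @param scenario A [scenario_spec()].
#' @param seed Integer seed; same seed, same cohort.
#' @param exact_prevalence Draw exactly `round(n * prevalence)` positives
#'   in a random order instead of independent Bernoulli labels — emulates
#'   a cohort obtained by outcome-stratified sampling, where the class
#'   counts are fixed by design.
#' @return List with `table` (a `patient_table`), `schema`, and
#'   `manifest` (`missing_rows`, `duplicate_pairs`, `near_duplicate_pairs`).
#' @export
generate_cohort <- function(scenario, seed = 1L, exact_prevalence = FALSE) {
  schema <- scenario_schema(scenario)
  d <- scenario$defects
  n_base <- scenario$n - d$n_duplicate - d$n_near_duplicate
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  if (exact_prevalence) {
    n_pos <- max(1L, min(n_base - 1L, round(n_base * scenario$prevalence)))
    y <- sample(c(rep(1L, n_pos), rep(0L, n_base - n_pos)))
  } else {
    y <- stats::rbinom(n_base, 1, scenario$prevalence)
    if (length(unique(y)) < 2) {  # tiny n can give a one-class draw
      y[sample.int(n_base, 1)] <- 1 - y[1]
    }
  }
  dat <- draw_features(scenario, y)
  dat$patient_id <- sprintf("s%04d", seq_len(n_base))
  dat[[scenario$label_name]] <- y

  num <- vapply(scenario$features, function(g) g$kind == "numerical", logical(1))
  num_names <- vapply(scenario$features[num], `[[`, "", "name")
  sds <- vapply(num_names, function(nm) pop_sd(dat[[nm]]), numeric(1))

  manifest <- list(missing_rows = character(0),
                   duplicate_pairs = NULL, near_duplicate_pairs = NULL)
  next_id <- n_base
  add_row <- function(row) {
    next_id <<- next_id + 1L
    row$patient_id <- sprintf("s%04d", next_id)
    dat <<- rbind(dat, row)
    row$patient_id
  }
  protected <- character(0)
  if (d$n_duplicate > 0) {
    src <- sample(dat$patient_id[seq_len(n_base)], d$n_duplicate)
    pairs <- data.frame(original = src, copy = NA_character_)
    for (i in seq_len(d$n_duplicate))
      pairs$copy[i] <- add_row(dat[dat$patient_id == src[i], ])
    manifest$duplicate_pairs <- pairs
    protected <- c(protected, src, pairs$copy)
  }
  if (d$n_near_duplicate > 0) {
    pool <- setdiff(dat$patient_id[seq_len(n_base)], protected)
    src <- sample(pool, d$n_near_duplicate)
    pairs <- data.frame(original = src, copy = NA_character_)
    for (i in seq_len(d$n_near_duplicate)) {
      row <- dat[dat$patient_id == src[i], ]
      for (j in seq_along(num_names)) {
        nm <- num_names[j]
        row[[nm]] <- row[[nm]] + stats::runif(1, -0.01, 0.01) * sds[j]
      }
      pairs$copy[i] <- add_row(row)
    }
    manifest$near_duplicate_pairs <- pairs
    protected <- c(protected, src, pairs$copy)
  }
  if (d$n_missing > 0) {
    pool <- setdiff(dat$patient_id, protected)
    if (length(pool) < d$n_missing)
      stop("defect plan infeasible: not enough rows for missing cells", call. = FALSE)
    rows <- sample(pool, d$n_missing)
    feat_names <- vapply(scenario$features, `[[`, "", "name")
    for (r in rows) {
      nm <- sample(feat_names, 1)
      dat[dat$patient_id == r, nm] <- NA
    }
    manifest$missing_rows <- sort(rows)
  }
  list(table = patient_table(dat, schema), schema = schema,
       manifest = manifest)
}

#' Build a logistic oracle matched to a scenario
#'
#' The oracle is a logistic model over the encoded design-matrix columns
#' whose coefficients are proportional to the standardized class-mean
#' difference of each column (scaled by `effect_scale`), with the
#' intercept anchored at the prevalence log-odds. Its implied
#' Bayes-level ROC-AUC is estimated once by Monte Carlo on a large
#' defect-free cohort and cached in the spec.
#'
#' @param scenario A [scenario_spec()].
#' @param effect_scale Multiplier on the standardized-difference
#'   coefficients; 0 gives an uninformative oracle (implied AUC 0.5).
#' @param mc_n Monte-Carlo cohort size for the implied-AUC estimate.
#' @param seed Seed for the Monte-Carlo estimate.
#' @return An `oracle_spec`: `coefficients` (named), `intercept`,
#'   `implied_auc`, `implied_auc_se`.
#' @export
make_oracle <- function(scenario, effect_scale = 1, mc_n = 100000L,
                        seed = 1L) {
  clean <- scenario
  clean$defects <- list(n_missing = 0, n_duplicate = 0, n_near_duplicate = 0)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  y <- stats::rbinom(mc_n, 1, scenario$prevalence)
  dat <- draw_features(clean, y)
  dat[[scenario$label_name]] <- y
  schema <- scenario_schema(scenario)
  enc <- encode_table(patient_table(dat, schema))
  x <- enc$x
  cf <- vapply(seq_len(ncol(x)), function(j) {
    m1 <- mean(x[y == 1, j]); m0 <- mean(x[y == 0, j])
    s <- pop_sd(x[, j])
    if (s == 0) 0 else effect_scale * (m1 - m0) / s
  }, numeric(1))
  names(cf) <- colnames(x)
  intercept <- stats::qlogis(scenario$prevalence) -
    sum(cf * colMeans(x))
  oracle <- list(coefficients = cf, intercept = intercept)
  p <- oracle_probability(oracle, x)
  auc <- if (effect_scale == 0) 0.5 else roc_auc(p, y)
  n1 <- as.numeric(sum(y == 1)); n0 <- as.numeric(mc_n) - n1
  # Hanley-McNeil standard error of the Monte-Carlo AUC estimate
  q1 <- auc / (2 - auc); q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
                (n0 - 1) * (q2 - auc^2)) / (n1 * n0))
  structure(c(oracle, list(implied_auc = auc, implied_auc_se = se,
                           effect_scale = effect_scale)),
            class = "oracle_spec")
}

#' @export
print.oracle_spec <- function(x, ...) {
  cat("<oracle_spec> ", length(x$coefficients), " coefficients, implied AUC ",
      sprintf("%.3f (MC se %.4f)", x$implied_auc, x$implied_auc_se),
      "\n", sep = "")
  invisible(x)
}

#' Shipped scenario presets
#'
#' Three presets mirroring the shapes of published small-cohort tasks:
#' a sepsis-mortality-like cohort (n = 1205, prevalence 191/1205, 19
#' numerical features plus binary gender, a handful informative), a
#' gastric-cancer nodal-status-like cohort (n = 462, prevalence 258/462,
#' 2 numerical, 4 categorical, 2 ordinal features), and an acute-leukemia
#' subtype-like cohort (n = 584, prevalence 72/584, 10 numerical
#' features). Class separations are moderate, in the range where tens of
#' training patients carry usable but noisy signal.
#'
#' @return A `scenario_spec`.
#' @export
scenario_sepsis_like <- function() {
  shifts <- c(0.9, 0.7, 0.6, 0.5, 0.4, 0.3, 0.3, 0.2, 0.2, 0.1,
              rep(0, 9))
  feats <- lapply(seq_along(shifts), function(i)
    num_feature(paste0("lab", i), mean0 = 0, mean1 = shifts[i], sd = 1,
                unit = if (i <= 5) "mg/L" else NULL,
                rounding = "one_decimal"))
  feats[[length(feats) + 1L]] <-
    cat_feature("gender", c("male", "female"), p0 = c(0.5, 0.5),
                p1 = c(0.55, 0.45))
  scenario_spec(n = 1205, prevalence = 191 / 1205, features = feats,
                label_negative_text = "survives",
                label_positive_text = "dies",
                system_message = "Classify the patient outcome.",
                entity_phrase = "Patient ->",
                threshold_interval = c(0.05, 0.30))
}

#' @rdname scenario_sepsis_like
#' @export
scenario_gastric_like <- function() {
  feats <- list(
    num_feature("age", 60, 61, sd = 11, rounding = "integer"),
    num_feature("tumor_size", 3.0, 4.1, sd = 1.8, unit = "cm",
                rounding = "integer"),
    cat_feature("gender", c("male", "female"), c(0.6, 0.4), c(0.6, 0.4)),
    cat_feature("location", c("upper", "middle", "lower"),
                c(0.25, 0.3, 0.45), c(0.3, 0.3, 0.4)),
    cat_feature("histology", c("intestinal", "diffuse", "mixed"),
                c(0.5, 0.3, 0.2), c(0.35, 0.45, 0.2)),
    cat_feature("srcc", c("no", "yes"), c(0.85, 0.15), c(0.75, 0.25)),
    ord_feature("t_stage", c("T1a", "T1b", "T2", "T3", "T4a", "T4b"),
                c(0.3, 0.25, 0.2, 0.15, 0.07, 0.03),
                c(0.05, 0.1, 0.2, 0.3, 0.25, 0.1)),
    ord_feature("grade", c("G1", "G2", "G3"),
                c(0.3, 0.45, 0.25), c(0.15, 0.4, 0.45)))
  scenario_spec(n = 462, prevalence = 258 / 462, features = feats,
                label_negative_text = "negative",
                label_positive_text = "positive",
                system_message = "Classify the nodal status.",
                entity_phrase = "Gastric cancer patient ->",
                threshold_interval = c(0.30, 0.60))
}

#' @rdname scenario_sepsis_like
#' @export
scenario_leukemia_like <- function() {
  shifts <- c(1.0, 0.8, 0.6, 0.5, 0.4, 0.3, 0.2, 0.1, 0, 0)
  feats <- lapply(seq_along(shifts), function(i)
    num_feature(paste0("marker", i), mean0 = 0, mean1 = shifts[i], sd = 1,
                rounding = "two_decimal"))
  scenario_spec(n = 584, prevalence = 72 / 584, features = feats,
                label_negative_text = "AML",
                label_positive_text = "APL",
                system_message = "Classify the leukemia subtype.",
                entity_phrase = "Leukemia patient ->",
                threshold_interval = c(0.02, 0.15))
}
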