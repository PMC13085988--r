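# shared fixtures built in code

box_schema <- function() {
  read_schema(system.file("extdata", "sepsis_box_schema.json",
                          package = "iclbench"))
}

box_table <- function() {
  load_table(system.file("extdata", "sepsis_box.csv", package = "iclbench"),
             box_schema())
}

box_train <- function() {
  tab <- box_table()
  tab$data <- tab$data[1:10, ]
  tab
}

box_test_record <- function() box_table()$data[11, ]

read_golden <- function(name) {
  paste(readLines(system.file("extdata", name, package = "iclbench"),
                  encoding = "UTF-8"),
        collapse = "\n")
}

# a tiny mixed-kind schema used across modules
toy_schema <- function() {
  dataset_schema(
    features = list(
      feature_spec("age", "numerical", unit = "years", rounding = "integer"),
      feature_spec("crp", "numerical", unit = "mg/L", rounding = "one_decimal"),
      feature_spec("stage", "ordinal", ordinal_levels = c("I", "II", "III")),
      feature_spec("sex", "categorical", categorical_levels = c("m", "f"))),
    label_name = "y",
    label_negative_text = "no", label_positive_text = "yes",
    system_message = "Classify.", entity_phrase = "Case ->",
    threshold_interval = c(0.1, 0.4))
}

toy_table <- function(n = 8, seed = 1) {
  set.seed(seed)
  patient_table(data.frame(
    patient_id = paste0("p", seq_len(n)),
    age = sample(20:90, n, replace = TRUE),
    crp = round(runif(n, 1, 300), 1),
    stage = sample(c("I", "II", "III"), n, replace = TRUE),
    sex = sample(c("m", "f"), n, replace = TRUE),
    y = rep_len(c(0, 1), n),
    stringsAsFactors = FALSE), toy_schema())
}

# gaussian-features scenario with a chosen implied separation
gaussian_scenario <- function(n = 600, prevalence = 0.3, n_features = 4,
                              shift = 0.8, defects = list()) {
  scenario_spec(n = n, prevalence = prevalence,
                features = lapply(seq_len(n_features), function(i)
                  num_feature(paste0("f", i), mean0 = 0, mean1 = shift)),
                defects = defects)
}

# brute-force near-duplicate oracle: all-pairs double loop
near_dup_oracle <- function(table, tolerance = 0.05) {
  dat <- table$data
  schema <- table$schema
  num <- numerical_features(schema)
  other <- setdiff(schema_feature_names(schema), num)
  sds <- sapply(num, function(nm) {
    x <- dat[[nm]]
    sqrt(mean((x - mean(x))^2))
  })
  res <- list()
  n <- nrow(dat)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- TRUE
    mx <- 0
    for (k in seq_along(num)) {
      if (sds[k] == 0) next
      d <- abs(dat[[num[k]]][i] - dat[[num[k]]][j]) / sds[k]
      mx <- max(mx, d)
      if (d > tolerance) { ok <- FALSE; break }
    }
    if (ok) for (nm in other)
      if (dat[[nm]][i] != dat[[nm]][j]) { ok <- FALSE; break }
    if (ok) res[[length(res) + 1]] <-
        data.frame(id_a = dat$patient_id[i], id_b = dat$patient_id[j],
                   max_scaled_abs_diff = mx)
  }
  if (length(res)) do.call(rbind, res)
  else data.frame(id_a = character(0), id_b = character(0),
                  max_scaled_abs_diff = numeric(0))
}

# brute-force rank oracles for the discrimination metrics
auc_oracle <- function(p, y) {
  pos <- p[y == 1]; neg <- p[y == 0]
  s <- 0
  for (a in pos) for (b in neg)
    s <- s + if (a > b) 1 else if (a == b) 0.5 else 0
  s / (length(pos) * length(neg))
}

ap_oracle <- function(p, y) {
  # walk distinct thresholds from high to low, accumulating precision at
  # each recall increment
  th <- sort(unique(p), decreasing = TRUE)
  n_pos <- sum(y == 1)
  ap <- 0; prev_rec <- 0
  for (t in th) {
    pred <- p >= t
    tp <- sum(pred & y == 1); fp <- sum(pred & y == 0)
    rec <- tp / n_pos
    prec <- tp / (tp + fp)
    ap <- ap + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  ap
}
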