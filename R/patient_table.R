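#' Construct a patient table
#'
#' A patient table binds a typed data frame of patient rows to the schema
#' that describes it. Numerical features are numeric columns, categorical
#' and ordinal features are character columns restricted to their level
#' vocabulary, and the binary outcome is stored as 0/1 (NA allowed for
#' rows whose outcome is unknown, e.g. prediction targets).
#'
#' @param data Data frame with a `patient_id` column, one column per schema
#'   feature, and the label column.
#' @param schema A [dataset_schema()].
#' @return A `patient_table` object.
#' @export
patient_table <- function(data, schema) {
  stopifnot(inherits(schema, "dataset_schema"))
  if (!"patient_id" %in% names(data))
    data$patient_id <- paste0("p", seq_len(nrow(data)))
  data$patient_id <- as.character(data$patient_id)
  if (anyDuplicated(data$patient_id)) stop("duplicate patient_id values", call. = FALSE)
  missing_cols <- setdiff(c(schema_feature_names(schema), schema$label_name), names(data))
  if (length(missing_cols))
    stop("data lacks schema columns: ", paste(missing_cols, collapse = ", "), call. = FALSE)
  for (f in schema$features) {
    v <- data[[f$name]]
    if (f$kind == "numerical") {
      data[[f$name]] <- as.numeric(v)
    } else {
      v <- as.character(v)
      levs <- if (f$kind == "ordinal") f$ordinal_levels else f$categorical_levels
      bad <- which(!is.na(v) & !v %in% levs)
      if (length(bad))
        stop("unknown level '", v[bad[1]], "' for feature '", f$name,
             "' in row ", bad[1], call. = FALSE)
      data[[f$name]] <- v
    }
  }
  lab <- data[[schema$label_name]]
  lab <- label_to_binary(lab, schema)
  data[[schema$label_name]] <- lab
  keep <- c("patient_id", schema_feature_names(schema), schema$label_name)
  structure(list(data = data[keep], schema = schema), class = "patient_table")
}

label_to_binary <- function(lab, schema) {
  lab <- as.character(lab)
  out <- rep(NA_integer_, length(lab))
  out[lab %in% c("0", schema$label_negative_text)] <- 0L
  out[lab %in% c("1", schema$label_positive_text)] <- 1L
  bad <- which(!is.na(lab) & lab != "" & is.na(out))
  if (length(bad))
    stop("label value '", lab[bad[1]], "' in row ", bad[1],
         " is neither 0/1 nor a schema label text", call. = FALSE)
  out
}

#' @export
print.patient_table <- function(x, ...) {
  lab <- x$data[[x$schema$label_name]]
  cat("<patient_table> ", nrow(x$data), " patients, ",
      length(x$schema$features), " features, ",
      sum(lab == 1, na.rm = TRUE), " positive / ",
      sum(lab == 0, na.rm = TRUE), " negative",
      if (anyNA(lab)) paste0(" (", sum(is.na(lab)), " unlabeled)") else "",
      "\n", sep = "")
  invisible(x)
}

#' Number of rows of a patient table
#' @param table A `patient_table`.
#' @return Integer row count.
#' @export
n_patients <- function(table) nrow(table$data)

#' Binary outcome labels of a patient table
#' @param table A `patient_table`.
#' @return Integer 0/1 vector (NA for unlabeled rows), in row order.
#' @export
table_labels <- function(table) table$data[[table$schema$label_name]]

#' Load a patient table from CSV
#'
#' Reads an RFC 4180 CSV with a header row, types each column according to
#' the schema and preserves missing cells as `NA`. Unknown categorical or
#' ordinal levels and non-numeric text in numerical columns are reported as
#' errors naming the row and feature.
#'
#' @param path CSV path.
#' @param schema A [dataset_schema()].
#' @param missing_sentinel Strings to treat as missing in addition to the
#'   empty string (default `c("", "NA")`).
#' @return A `patient_table`.
#' @export
load_table <- function(path, schema, missing_sentinel = c("", "NA")) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         fileEncoding = "UTF-8")
  needed <- c(schema_feature_names(schema), schema$label_name)
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols))
    stop("CSV header lacks schema columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  for (nm in names(raw)) raw[[nm]][raw[[nm]] %in% missing_sentinel] <- NA
  for (f in schema$features) {
    if (f$kind == "numerical") {
      v <- raw[[f$name]]
      num <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & is.na(num))
      if (length(bad))
        stop("non-numeric value '", v[bad[1]], "' for numerical feature '",
             f$name, "' in row ", bad[1], call. = FALSE)
      raw[[f$name]] <- num
    }
  }
  patient_table(raw, schema)
}

#' Write a patient table to CSV
#' @param table A `patient_table`.
#' @param path Output path.
#' @export
write_table_csv <- function(table, path) {
  utils::write.csv(table$data, path, row.names = FALSE, na = "")
  invisible(path)
}

# rounding --------------------------------------------------------------------

#' Round half away from zero
#'
#' Deterministic decimal rounding used throughout the display pipeline
#' (clinical-report convention, unlike the round-half-even rule of
#' [base::round()]).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal digits.
#' @return Rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

rounding_digits <- c(integer = 0, one_decimal = 1, two_decimal = 2)

#' Apply per-feature rounding rules
#'
#' Rounds every numerical feature according to its schema rounding spec
#' (integer, one or two decimals; half away from zero). Non-numerical
#' features are untouched; missing values stay missing.
#'
#' @param table A `patient_table`.
#' @return The table with rounded numerical values.
#' @export
apply_rounding <- function(table) {
  for (f in table$schema$features) {
    if (f$kind != "numerical" || f$rounding == "none") next
    d <- rounding_digits[[f$rounding]]
    table$data[[f$name]] <- round_half_away(table$data[[f$name]], d)
  }
  table
}

# near duplicates --------------------------------------------------------------

#' Screen a cohort for near-duplicate patients
#'
#' Two patients are near duplicates when, for every numerical feature, the
#' absolute difference does not exceed `tolerance` times that feature's SD
#' (population convention), and all categorical/ordinal values are
#' identical. SDs are computed on the table as given, before any cleaning.
#' Constant numerical features (SD 0) are excluded from the criterion with
#' a warning. Each reported pair is flagged for label concordance.
#'
#' @param table A `patient_table`.
#' @param tolerance Fraction of the feature SD (default 0.05).
#' @return A data frame with columns `id_a`, `id_b`, `max_scaled_abs_diff`,
#'   `labels_concordant` (NA when either label is missing).
#' @export
detect_near_duplicates <- function(table, tolerance = 0.05) {
  empty <- data.frame(id_a = character(0), id_b = character(0),
                      max_scaled_abs_diff = numeric(0),
                      labels_concordant = logical(0))
  n <- n_patients(table)
  if (n < 2) return(empty)
  schema <- table$schema
  num <- numerical_features(schema)
  ids <- table$data$patient_id
  labs <- table_labels(table)

  scaled_max <- matrix(0, n, n)
  used_any <- FALSE
  for (nm in num) {
    x <- table$data[[nm]]
    s <- pop_sd(x[!is.na(x)])
    if (is.na(s) || s == 0) {
      warning("feature '", nm, "' has zero/undefined SD; excluded from the ",
              "near-duplicate criterion", call. = FALSE)
      next
    }
    used_any <- TRUE
    d <- abs(outer(x, x, "-")) / s
    d[is.na(d)] <- Inf  # a missing value can never certify closeness
    scaled_max <- pmax(scaled_max, d)
  }
  same_codes <- matrix(TRUE, n, n)
  for (f in schema$features) {
    if (f$kind == "numerical") next
    v <- table$data[[f$name]]
    eq <- outer(v, v, "==")
    eq[is.na(eq)] <- FALSE
    same_codes <- same_codes & eq
  }
  ok <- scaled_max <= tolerance & same_codes
  ok[lower.tri(ok, diag = TRUE)] <- FALSE
  idx <- which(ok, arr.ind = TRUE)
  if (!nrow(idx)) return(empty)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  data.frame(
    id_a = ids[idx[, 1]], id_b = ids[idx[, 2]],
    max_scaled_abs_diff = if (used_any) scaled_max[idx] else 0,
    labels_concordant = labs[idx[, 1]] == labs[idx[, 2]])
}

pop_sd <- function(x) {
  if (!length(x)) return(NA_real_)
  sqrt(mean((x - mean(x))^2))
}

# cleaning ---------------------------------------------------------------------

#' Define a cleaning policy
#'
#' Rules are applied in a fixed order: missing-data removal, exact
#' duplicates, near-duplicate resolution, then dataset-specific rules
#' (zero-valued biomarkers, class removal).
#'
#' @param drop_missing Drop rows with any missing feature or label value.
#' @param drop_exact_duplicates Drop later rows whose feature values and
#'   label exactly repeat an earlier row.
#' @param near_duplicates One of `"keep"` (no action), `"keep_first"`,
#'   `"keep_finer_precision"` (retain the member whose differing numerical
#'   values carry more decimal digits), or `"drop_both"`.
#' @param tolerance Near-duplicate tolerance as a fraction of the feature SD.
#' @param zero_biomarker_features Character vector of numerical features;
#'   rows with a zero value in any of them are dropped.
#' @param drop_label Optional label (0 or 1) whose rows are dropped.
#' @return A `cleaning_policy` object.
#' @export
cleaning_policy <- function(drop_missing = TRUE,
                            drop_exact_duplicates = TRUE,
                            near_duplicates = c("keep", "keep_first",
                                                "keep_finer_precision", "drop_both"),
                            tolerance = 0.05,
                            zero_biomarker_features = character(0),
                            drop_label = NULL) {
  near_duplicates <- match.arg(near_duplicates)
  structure(list(drop_missing = drop_missing,
                 drop_exact_duplicates = drop_exact_duplicates,
                 near_duplicates = near_duplicates,
                 tolerance = tolerance,
                 zero_biomarker_features = zero_biomarker_features,
                 drop_label = drop_label),
            class = "cleaning_policy")
}

decimal_places <- function(x, max_digits = 10) {
  vapply(x, function(v) {
    if (is.na(v)) return(0L)
    for (d in 0:max_digits)
      if (isTRUE(all.equal(v, round(v, d), tolerance = 1e-12))) return(d)
    max_digits
  }, integer(1))
}

#' Clean a patient table under a policy
#'
#' Applies the policy rules in order and records every removal in a
#' cleaning log (one entry per removed patient naming the triggering rule),
#' attached as the `"cleaning_log"` attribute of the returned table.
#'
#' @param table A `patient_table`.
#' @param policy A [cleaning_policy()].
#' @return The reduced `patient_table`; `attr(, "cleaning_log")` is a data
#'   frame with columns `patient_id`, `rule`, `detail`.
#' @export
clean_table <- function(table, policy = cleaning_policy()) {
  stopifnot(inherits(policy, "cleaning_policy"))
  schema <- table$schema
  unknown <- setdiff(policy$zero_biomarker_features, schema_feature_names(schema))
  if (length(unknown))
    stop("cleaning policy references unknown features: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  log <- list()
  note <- function(ids, rule, detail = "") {
    if (length(ids))
      log[[length(log) + 1L]] <<- data.frame(patient_id = ids, rule = rule,
                                             detail = detail,
                                             stringsAsFactors = FALSE)
  }
  dat <- table$data
  featcols <- schema_feature_names(schema)

  if (policy$drop_missing) {
    bad <- !stats::complete.cases(dat[c(featcols, schema$label_name)])
    note(dat$patient_id[bad], "missing")
    dat <- dat[!bad, , drop = FALSE]
  }
  if (policy$drop_exact_duplicates) {
    key <- do.call(paste, c(dat[c(featcols, schema$label_name)], sep = "\r"))
    bad <- duplicated(key)
    note(dat$patient_id[bad], "exact_duplicate")
    dat <- dat[!bad, , drop = FALSE]
  }
  if (policy$near_duplicates != "keep" && nrow(dat) >= 2) {
    sub <- table; sub$data <- dat
    pairs <- suppressWarnings(detect_near_duplicates(sub, policy$tolerance))
    if (nrow(pairs)) {
      drop_ids <- character(0)
      for (i in seq_len(nrow(pairs))) {
        a <- pairs$id_a[i]; b <- pairs$id_b[i]
        if (a %in% drop_ids || b %in% drop_ids) next
        if (policy$near_duplicates == "drop_both") {
          drop_ids <- c(drop_ids, a, b)
        } else if (policy$near_duplicates == "keep_first") {
          drop_ids <- c(drop_ids, b)
        } else { # keep_finer_precision
          ra <- dat[dat$patient_id == a, featcols]
          rb <- dat[dat$patient_id == b, featcols]
          num <- numerical_features(schema)
          diff_feats <- num[vapply(num, function(nm)
            !isTRUE(all.equal(ra[[nm]], rb[[nm]])), logical(1))]
          da <- sum(decimal_places(unlist(ra[diff_feats])))
          db <- sum(decimal_places(unlist(rb[diff_feats])))
          drop_ids <- c(drop_ids, if (db > da) a else b)
        }
      }
      note(drop_ids, "near_duplicate",
           paste0("tolerance=", policy$tolerance, ",action=", policy$near_duplicates))
      dat <- dat[!dat$patient_id %in% drop_ids, , drop = FALSE]
    }
  }
  if (length(policy$zero_biomarker_features)) {
    zb <- policy$zero_biomarker_features
    bad <- Reduce(`|`, lapply(zb, function(nm) !is.na(dat[[nm]]) & dat[[nm]] == 0))
    note(dat$patient_id[bad], "zero_biomarker", paste(zb, collapse = ","))
    dat <- dat[!bad, , drop = FALSE]
  }
  if (!is.null(policy$drop_label)) {
    bad <- !is.na(dat[[schema$label_name]]) & dat[[schema$label_name]] == policy$drop_label
    note(dat$patient_id[bad], "class_removal", paste0("label=", policy$drop_label))
    dat <- dat[!bad, , drop = FALSE]
  }
  out <- table
  out$data <- dat
  attr(out, "cleaning_log") <- if (length(log)) do.call(rbind, log) else
    data.frame(patient_id = character(0), rule = character(0), detail = character(0))
  out
}

#' Write a cleaning log as JSON lines
#' @param table A cleaned `patient_table` (output of [clean_table()]).
#' @param path Output path; one JSON object per removed patient.
#' @export
write_cleaning_log <- function(table, path) {
  log <- attr(table, "cleaning_log")
  if (is.null(log)) stop("table carries no cleaning log", call. = FALSE)
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(log)))
    writeLines(jsonlite::toJSON(as.list(log[i, ]), auto_unbox = TRUE), con)
  invisible(path)
}

# encoding and scaling ---------------------------------------------------------

#' Encode a patient table into a design matrix
#'
#' Numerical columns pass through; ordinal features map to `0..L-1` by
#' level order; binary categorical features collapse to a single indicator
#' (second level coded 1); categorical features with three or more levels
#' expand to one-hot indicators. Column order follows the schema's
#' `encoded_order`.
#'
#' @param table A `patient_table` with no missing feature values.
#' @return A list with `x` (numeric matrix, rownames = patient ids) and
#'   `columns` (the [encoded_columns()] metadata).
#' @export
encode_table <- function(table) {
  schema <- table$schema
  dat <- table$data
  if (anyNA(dat[schema_feature_names(schema)]))
    stop("encode requires a table with no missing feature values", call. = FALSE)
  meta <- encoded_columns(schema)
  cols <- vector("list", nrow(meta))
  for (i in seq_len(nrow(meta))) {
    f <- schema$features[[meta$feature[i]]]
    v <- dat[[f$name]]
    cols[[i]] <- switch(f$kind,
      numerical = as.numeric(v),
      ordinal = {
        idx <- match(v, f$ordinal_levels)
        if (anyNA(idx)) stop("unseen ordinal level in '", f$name, "'", call. = FALSE)
        as.numeric(idx - 1L)
      },
      categorical = {
        if (!all(v %in% f$categorical_levels))
          stop("unseen categorical level in '", f$name, "'", call. = FALSE)
        if (length(f$categorical_levels) > 2)
          as.numeric(v == meta$level[i])
        else
          as.numeric(v == f$categorical_levels[2])
      })
  }
  x <- do.call(cbind, cols)
  dimnames(x) <- list(dat$patient_id, meta$column)
  list(x = x, columns = meta)
}

#' Standard-scale a design matrix (train parameters applied to test)
#'
#' Centers and scales every column of the training matrix to mean 0 and
#' SD 1, using the population SD convention (divisor n). The identical
#' affine transform is applied to the test matrix. Constant columns
#' (SD 0) map to 0 rather than erroring, since tiny stratified samples can
#' make an indicator column constant.
#'
#' @param train Numeric training matrix.
#' @param test Optional numeric test matrix with the same columns.
#' @return A list with `train`, `test` (NULL if absent), `center`, `scale`
#'   (the population SDs; 0 marks a constant column).
#' @export
standard_scale <- function(train, test = NULL) {
  train <- as.matrix(train)
  stopifnot(nrow(train) >= 1)
  center <- colMeans(train)
  scale_ <- apply(train, 2, pop_sd)
  div <- ifelse(scale_ == 0, 1, scale_)
  tr <- sweep(sweep(train, 2, center), 2, div, "/")
  tr[, scale_ == 0] <- 0
  te <- NULL
  if (!is.null(test)) {
    test <- as.matrix(test)
    stopifnot(ncol(test) == ncol(train))
    te <- sweep(sweep(test, 2, center), 2, div, "/")
    te[, scale_ == 0] <- 0
  }
  list(train = tr, test = te, center = center, scale = scale_)
}
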