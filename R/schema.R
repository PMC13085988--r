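#' Declare a single cohort feature
#'
#' A feature specification describes how one column of a patient table is
#' typed, displayed and rounded. Numerical features carry an optional unit
#' and a rounding rule chosen to reflect the granularity of the raw data
#' (integers for counts and pressures, one or two decimals for labs).
#' Categorical and ordinal features carry their level vocabulary; ordinal
#' level order is meaningful and drives integer encoding.
#'
#' @param name Column name in the source table.
#' @param kind One of `"numerical"`, `"categorical"`, `"ordinal"`.
#' @param display_name Human-readable name used in prompts; defaults to `name`.
#' @param unit Optional unit string appended to displayed values
#'   (`"%"` is attached without a space, any other unit with one).
#' @param rounding Rounding rule for numerical features: `"integer"`,
#'   `"one_decimal"`, `"two_decimal"` or `"none"`.
#' @param ordinal_levels Ordered character vector of levels (ordinal only).
#' @param categorical_levels Character vector of levels (categorical only).
#'   For binary features the second level is the one coded 1.
#' @return A `feature_spec` object.
#' @export
feature_spec <- function(name, kind,
                         display_name = name,
                         unit = NULL,
                         rounding = c("none", "integer", "one_decimal", "two_decimal"),
                         ordinal_levels = NULL,
                         categorical_levels = NULL) {
  kind <- match.arg(kind, c("numerical", "categorical", "ordinal"))
  rounding <- match.arg(rounding)
  if (kind == "ordinal" && (is.null(ordinal_levels) || length(ordinal_levels) < 2))
    stop("ordinal feature '", name, "' needs >= 2 ordinal_levels", call. = FALSE)
  if (kind == "categorical" && (is.null(categorical_levels) || length(categorical_levels) < 2))
    stop("categorical feature '", name, "' needs >= 2 categorical_levels", call. = FALSE)
  if (kind != "ordinal" && !is.null(ordinal_levels))
    stop("ordinal_levels only allowed for kind='ordinal'", call. = FALSE)
  if (kind != "categorical" && !is.null(categorical_levels))
    stop("categorical_levels only allowed for kind='categorical'", call. = FALSE)
  if (kind != "numerical" && rounding != "none")
    stop("rounding is defined only for numerical features (", name, ")", call. = FALSE)
  structure(
    list(name = name, display_name = display_name, kind = kind,
         unit = unit, rounding = rounding,
         ordinal_levels = ordinal_levels,
         categorical_levels = categorical_levels),
    class = "feature_spec")
}

#' Declare a dataset schema
#'
#' The schema is the single declarative description of a cohort: its
#' features, the binary outcome vocabulary, the prompt texts, and the
#' clinically relevant decision-threshold interval used for decision curve
#' analysis. Everything downstream (cleaning, encoding, scaling, prompt
#' serialization) is driven by it.
#'
#' @param features List of [feature_spec()] objects, in display order.
#' @param label_name Name of the outcome column.
#' @param label_negative_text,label_positive_text Outcome texts used in
#'   full-context prompts (e.g. `"survives"` / `"dies"`). Must differ.
#' @param system_message System message for full-context prompts.
#' @param entity_phrase Trailing cue closing each patient line
#'   (e.g. `"Sepsis patient ->"`).
#' @param threshold_interval Length-2 numeric `(lo, hi)` with
#'   `0 < lo < hi < 1`: the clinically relevant probability interval over
#'   which mean net benefit is computed.
#' @param encoded_order Optional character vector of feature names giving the
#'   order of encoded design-matrix columns (and hence of generic column
#'   codes). Defaults to the schema feature order. Cohorts whose source table
#'   ordering differs from the prompt display ordering set this explicitly.
#' @return A `dataset_schema` object.
#' @export
dataset_schema <- function(features, label_name,
                           label_negative_text, label_positive_text,
                           system_message = "", entity_phrase = "",
                           threshold_interval = c(0.05, 0.30),
                           encoded_order = NULL) {
  stopifnot(length(features) >= 1)
  features <- lapply(features, function(f) {
    if (!inherits(f, "feature_spec")) stop("features must be feature_spec objects", call. = FALSE)
    f
  })
  nms <- vapply(features, `[[`, "", "name")
  if (anyDuplicated(nms)) stop("duplicate feature names in schema", call. = FALSE)
  names(features) <- nms
  if (identical(label_negative_text, label_positive_text))
    stop("label texts must differ", call. = FALSE)
  ti <- as.numeric(threshold_interval)
  if (length(ti) != 2 || !(ti[1] > 0 && ti[1] < ti[2] && ti[2] < 1))
    stop("threshold_interval must satisfy 0 < lo < hi < 1", call. = FALSE)
  if (is.null(encoded_order)) encoded_order <- nms
  if (!setequal(encoded_order, nms) || length(encoded_order) != length(nms))
    stop("encoded_order must be a permutation of the feature names", call. = FALSE)
  structure(
    list(features = features, label_name = label_name,
         label_negative_text = label_negative_text,
         label_positive_text = label_positive_text,
         system_message = system_message, entity_phrase = entity_phrase,
         threshold_interval = ti, encoded_order = encoded_order),
    class = "dataset_schema")
}

#' @export
print.dataset_schema <- function(x, ...) {
  kinds <- vapply(x$features, `[[`, "", "kind")
  cat("<dataset_schema> ", length(x$features), " features (",
      sum(kinds == "numerical"), " numerical, ",
      sum(kinds == "categorical"), " categorical, ",
      sum(kinds == "ordinal"), " ordinal)\n", sep = "")
  cat("  label: ", x$label_name, " [", x$label_negative_text, " / ",
      x$label_positive_text, "]\n", sep = "")
  cat("  threshold interval: [", x$threshold_interval[1], ", ",
      x$threshold_interval[2], "]\n", sep = "")
  invisible(x)
}

#' Read a dataset schema from JSON or YAML
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` schema file.
#' @return A `dataset_schema` object.
#' @export
read_schema <- function(path) {
  if (!file.exists(path)) stop("schema file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  feats <- lapply(raw$features, function(f) {
    feature_spec(
      name = f$name, kind = f$kind,
      display_name = if (is.null(f$display_name)) f$name else f$display_name,
      unit = f$unit,
      rounding = if (is.null(f$rounding)) "none" else f$rounding,
      ordinal_levels = unlist(f$ordinal_levels),
      categorical_levels = unlist(f$categorical_levels))
  })
  dataset_schema(
    features = feats,
    label_name = raw$label_name,
    label_negative_text = raw$label_negative_text,
    label_positive_text = raw$label_positive_text,
    system_message = if (is.null(raw$system_message)) "" else raw$system_message,
    entity_phrase = if (is.null(raw$entity_phrase)) "" else raw$entity_phrase,
    threshold_interval = unlist(raw$threshold_interval),
    encoded_order = unlist(raw$encoded_order))
}

#' Write a dataset schema to JSON
#'
#' @param schema A `dataset_schema`.
#' @param path Output path.
#' @export
write_schema <- function(schema, path) {
  stopifnot(inherits(schema, "dataset_schema"))
  out <- list(
    features = lapply(unname(schema$features), function(f)
      Filter(Negate(is.null), f[c("name", "display_name", "kind", "unit",
                                  "rounding", "ordinal_levels", "categorical_levels")])),
    label_name = schema$label_name,
    label_negative_text = schema$label_negative_text,
    label_positive_text = schema$label_positive_text,
    system_message = schema$system_message,
    entity_phrase = schema$entity_phrase,
    threshold_interval = schema$threshold_interval,
    encoded_order = schema$encoded_order)
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

# internal helpers shared across modules -------------------------------------

schema_feature_names <- function(schema) names(schema$features)

numerical_features <- function(schema)
  names(schema$features)[vapply(schema$features, `[[`, "", "kind") == "numerical"]

#' Columns of the encoded design matrix implied by a schema
#'
#' Returns the per-column metadata of the design matrix produced by
#' [encode_table()]: numerical and ordinal features map to one column each,
#' binary categorical features collapse to a single indicator (second level
#' coded 1), categorical features with three or more levels expand to full
#' one-hot indicators. Columns follow the schema's `encoded_order`.
#'
#' @param schema A `dataset_schema`.
#' @return A data frame with columns `column`, `feature`, `kind`, `level`.
#' @export
encoded_columns <- function(schema) {
  rows <- list()
  for (nm in schema$encoded_order) {
    f <- schema$features[[nm]]
    if (f$kind == "categorical" && length(f$categorical_levels) > 2) {
      for (lv in f$categorical_levels)
        rows[[length(rows) + 1L]] <- data.frame(
          column = paste0(nm, "=", lv), feature = nm, kind = f$kind,
          level = lv, stringsAsFactors = FALSE)
    } else {
      lv <- if (f$kind == "categorical") f$categorical_levels[2] else NA_character_
      rows[[length(rows) + 1L]] <- data.frame(
        column = nm, feature = nm, kind = f$kind, level = lv,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
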