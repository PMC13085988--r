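#' Context-ablation variants
#'
#' The five prompt dialects, ordered from full clinical context to a pure
#' statistical inference task: `full` (names, units, label texts),
#' `no_units` (dimensional units removed, `%` kept), `permuted_names`
#' (units removed, each display name cyclically replaced by the next
#' feature's name), `generic_names` (units removed, names replaced by
#' generic column codes), and `no_context` (standard-scaled 2-decimal
#' values, generic codes, labels 0/1, generic system message).
#'
#' @return Character vector of variant names.
#' @export
context_variants <- function() {
  c("full", "no_units", "permuted_names", "generic_names", "no_context")
}

NO_CONTEXT_SYSTEM_MESSAGE <- paste(
  "You will be given characteristics of a sample.",
  "Classify the sample outcome into one of the following categories: 0, or 1.",
  "Return only the name of the category, and nothing else.",
  "MAKE SURE your output is one of the two categories stated.", sep = "\n")

# numeric display: round per spec (half away from zero), trim trailing
# zeros but keep at least one decimal for non-integer specs
format_number <- function(v, rounding = "none") {
  if (is.na(v)) stop("cannot format a missing value", call. = FALSE)
  if (rounding == "integer")
    return(sprintf("%d", as.integer(round_half_away(v, 0))))
  d <- switch(rounding, one_decimal = 1L, two_decimal = 2L, none = 6L)
  x <- round_half_away(v, d)
  if (x == 0) x <- 0  # avoid "-0.0"
  s <- sprintf("%.*f", d, x)
  s <- sub("0+$", "", s)
  if (endsWith(s, ".")) s <- paste0(s, "0")
  s
}

strip_units <- function(schema) {
  # keep "%" on dimensionless percent-valued features, drop everything else
  schema$features <- lapply(schema$features, function(f) {
    if (!identical(f$unit, "%")) f$unit <- NULL
    f
  })
  schema
}

#' Cyclically permute feature display names
#'
#' Replaces every display name with the next feature's name in schema
#' order (the last takes the first), leaving values, order and units
#' policy untouched. Applying it `n_features` times recovers the original
#' schema.
#'
#' @param schema A `dataset_schema`.
#' @return The permuted schema.
#' @export
permute_names <- function(schema) {
  m <- length(schema$features)
  if (m < 2) {
    warning("single-feature schema: name permutation is a no-op", call. = FALSE)
    return(schema)
  }
  disp <- vapply(schema$features, `[[`, "", "display_name")
  shifted <- disp[c(2:m, 1)]
  for (i in seq_len(m)) schema$features[[i]]$display_name <- shifted[i]
  schema
}

#' Replace feature display names with generic column codes
#'
#' Display names become `C0..C(m-1)` following the encoded-column order
#' (a feature's code is the index of its first encoded column); units are
#' dropped.
#'
#' @param schema A `dataset_schema`.
#' @return The genericized schema.
#' @export
genericize_names <- function(schema) {
  meta <- encoded_columns(schema)
  first_col <- match(schema_feature_names(schema), meta$feature)
  codes <- paste0("C", first_col - 1L)
  for (i in seq_along(schema$features)) {
    schema$features[[i]]$display_name <- codes[i]
    schema$features[[i]]$unit <- NULL
  }
  schema
}

variant_schema <- function(schema, variant) {
  switch(variant,
    full = schema,
    no_units = strip_units(schema),
    permuted_names = permute_names(strip_units(schema)),
    generic_names = genericize_names(schema),
    stop("variant_schema is undefined for '", variant, "'", call. = FALSE))
}

#' Serialize one patient as a prompt line
#'
#' Produces the comma-separated `DisplayName: value[ unit]` items in schema
#' feature order, closed by `". "` plus the schema's entity phrase.
#' Integer-spec values print bare; decimal values print with trailing
#' zeros trimmed down to a minimum of one decimal place; `%` attaches
#' without a space, other units with one.
#'
#' @param record Named list or one-row data frame of raw feature values.
#' @param schema A `dataset_schema`.
#' @param variant One of [context_variants()] except `"no_context"`.
#' @return A single character string.
#' @export
format_patient_line <- function(record, schema, variant = "full") {
  variant <- match.arg(variant, setdiff(context_variants(), "no_context"))
  schema <- variant_schema(schema, variant)
  record <- as.list(record)
  items <- vapply(schema$features, function(f) {
    v <- record[[f$name]]
    if (is.null(v) || (length(v) == 1 && is.na(v)))
      stop("record lacks a value for feature '", f$name, "'", call. = FALSE)
    val <- if (f$kind == "numerical") format_number(as.numeric(v), f$rounding)
           else as.character(v)
    unit <- if (is.null(f$unit)) ""
            else if (identical(f$unit, "%")) "%"
            else paste0(" ", f$unit)
    paste0(f$display_name, ": ", val, unit)
  }, character(1))
  paste0(paste(items, collapse = ", "), ". ", schema$entity_phrase)
}

#' Parse a full-context prompt line back into feature values
#'
#' Inverse of [format_patient_line()] for the `full` variant: recovers
#' every numeric value and category from a serialized line.
#'
#' @param line Character string produced by [format_patient_line()].
#' @param schema The `dataset_schema` the line was built from.
#' @return Named list of feature values.
#' @export
parse_patient_line <- function(line, schema) {
  body <- sub(paste0(". ", schema$entity_phrase), "", line, fixed = TRUE)
  parts <- strsplit(body, ", ", fixed = TRUE)[[1]]
  if (length(parts) != length(schema$features))
    stop("line has ", length(parts), " items; schema expects ",
         length(schema$features), call. = FALSE)
  out <- list()
  for (i in seq_along(schema$features)) {
    f <- schema$features[[i]]
    prefix <- paste0(f$display_name, ": ")
    if (!startsWith(parts[i], prefix))
      stop("item ", i, " does not start with '", prefix, "'", call. = FALSE)
    val <- substring(parts[i], nchar(prefix) + 1)
    if (f$kind == "numerical") {
      if (!is.null(f$unit)) {
        val <- if (identical(f$unit, "%")) sub("%$", "", val)
               else sub(paste0(" ", f$unit), "", val, fixed = TRUE)
      }
      out[[f$name]] <- as.numeric(val)
    } else out[[f$name]] <- val
  }
  out
}

new_prompt <- function(messages, variant, patient_id) {
  structure(list(messages = messages, variant = variant,
                 patient_id = patient_id), class = "prompt")
}

#' @export
print.prompt <- function(x, ...) {
  cat("<prompt> variant=", x$variant, ", ", length(x$messages),
      " messages, test patient ", x$patient_id, "\n", sep = "")
  invisible(x)
}

#' Build a chat prompt for one test patient
#'
#' Assembles the standard instruct-model chat sequence: the system
#' message, then one (user, assistant) pair per training patient in the
#' order given (assistant content is the outcome text), and a final user
#' message for the test patient. With `TR` training patients the prompt
#' has `2 * TR + 2` messages.
#'
#' @param train A `patient_table` of labeled training patients (order
#'   preserved), or NULL/empty for a zero-shot prompt.
#' @param test Named list or one-row data frame of the test patient's raw
#'   feature values; a `patient_id` entry is carried into the prompt.
#' @param schema A `dataset_schema`.
#' @param variant One of [context_variants()] except `"no_context"`
#'   (see [build_no_context_prompt()] for that dialect).
#' @return A `prompt` object.
#' @export
build_prompt <- function(train, test, schema, variant = "full") {
  variant <- match.arg(variant, setdiff(context_variants(), "no_context"))
  msgs <- list(list(role = "system", content = schema$system_message))
  if (!is.null(train) && n_patients(train) > 0) {
    labs <- table_labels(train)
    if (anyNA(labs))
      stop("training patients must be labeled", call. = FALSE)
    for (i in seq_len(n_patients(train))) {
      rec <- as.list(train$data[i, ])
      msgs[[length(msgs) + 1L]] <-
        list(role = "user", content = format_patient_line(rec, schema, variant))
      msgs[[length(msgs) + 1L]] <-
        list(role = "assistant",
             content = if (labs[i] == 1) schema$label_positive_text
                       else schema$label_negative_text)
    }
  }
  test <- as.list(test)
  msgs[[length(msgs) + 1L]] <-
    list(role = "user", content = format_patient_line(test, schema, variant))
  new_prompt(msgs, variant,
             if (!is.null(test$patient_id)) as.character(test$patient_id)
             else NA_character_)
}

#' Build the no-context prompt from scaled design-matrix rows
#'
#' The no-context dialect poses the task as pure statistical inference:
#' a generic system message with categories `"0"` and `"1"`, user lines of
#' the form `"C0 is v, C1 is v, ... . Outcome is ->"` over standard-scaled
#' values rounded to two decimals, and assistant replies `"0"`/`"1"`.
#'
#' @param train_scaled Numeric matrix of scaled training rows (already
#'   rounded to two decimals or not; values are rendered at two decimals
#'   with trailing zeros trimmed to a minimum of one decimal).
#' @param train_labels Binary vector (0/1) aligned with `train_scaled` rows.
#' @param test_scaled Numeric vector: the scaled test row.
#' @param patient_id Optional test patient id carried into the prompt.
#' @return A `prompt` object with variant `"no_context"`.
#' @export
build_no_context_prompt <- function(train_scaled, train_labels, test_scaled,
                                    patient_id = NA_character_) {
  train_scaled <- as.matrix(train_scaled)
  if (length(test_scaled) != ncol(train_scaled))
    stop("test row has ", length(test_scaled), " columns; train has ",
         ncol(train_scaled), call. = FALSE)
  if (nrow(train_scaled) != length(train_labels))
    stop("train rows and labels misaligned", call. = FALSE)
  codes <- paste0("C", seq_len(ncol(train_scaled)) - 1L)
  line_of <- function(v)
    paste0(paste(paste0(codes, " is ",
                        vapply(v, format_number, "", rounding = "two_decimal")),
                 collapse = ", "),
           ". Outcome is ->")
  msgs <- list(list(role = "system", content = NO_CONTEXT_SYSTEM_MESSAGE))
  for (i in seq_len(nrow(train_scaled))) {
    msgs[[length(msgs) + 1L]] <- list(role = "user",
                                      content = line_of(train_scaled[i, ]))
    msgs[[length(msgs) + 1L]] <- list(role = "assistant",
                                      content = as.character(train_labels[i]))
  }
  msgs[[length(msgs) + 1L]] <- list(role = "user",
                                    content = line_of(test_scaled))
  new_prompt(msgs, "no_context", patient_id)
}

#' Build the no-context prompt straight from patient tables
#'
#' Convenience wrapper: encodes the training table and the test record,
#' fits the standard scaling on the training rows (population SD), rounds
#' to two decimals, and builds the no-context prompt.
#'
#' @param train A labeled `patient_table`.
#' @param test Named list or one-row data frame of raw test values.
#' @param schema A `dataset_schema`.
#' @return A `prompt` object.
#' @export
no_context_prompt_from_tables <- function(train, test, schema) {
  enc_train <- encode_table(train)
  test_df <- as.data.frame(as.list(test), stringsAsFactors = FALSE,
                           check.names = FALSE)
  if (!schema$label_name %in% names(test_df))
    test_df[[schema$label_name]] <- NA
  test_tab <- patient_table(test_df, schema)
  enc_test <- encode_table(test_tab)
  sc <- standard_scale(enc_train$x, enc_test$x)
  build_no_context_prompt(round_half_away(sc$train, 2),
                          table_labels(train),
                          round_half_away(sc$test[1, ], 2),
                          patient_id = test_tab$data$patient_id[1])
}

#' Render a prompt as plain text
#'
#' Canonical text form used for golden-file comparison and inspection:
#' each message as a `#role` marker line followed by its content.
#'
#' @param prompt A `prompt` object.
#' @return A single string.
#' @export
prompt_to_text <- function(prompt) {
  paste(vapply(prompt$messages, function(m)
    paste0("#", m$role, "\n", m$content), character(1)), collapse = "\n")
}

#' Write prompts as JSON lines
#'
#' One JSON object per prompt:
#' `{"messages": [...], "variant", "split_id", "patient_id"}` — directly
#' postable to a chat-completion endpoint.
#'
#' @param prompts List of `prompt` objects.
#' @param path Output path.
#' @param split_id Optional split identifier recorded in every line.
#' @export
write_prompts_jsonl <- function(prompts, path, split_id = NA) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (p in prompts) {
    obj <- list(messages = p$messages, variant = p$variant,
                split_id = split_id, patient_id = p$patient_id)
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, null = "null"), con)
  }
  invisible(path)
}
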