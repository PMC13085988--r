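# iclbench

Benchmarking in-context-learning chat predictors against conventional
machine learning on **small clinical tabular cohorts** — for
biostatisticians and ML researchers who need to know whether a predictor
trained on a few tens of patients can be trusted, and how much its
performance depends on which few tens it was trained on.

## What it implements

A chat model used as a classifier receives every labeled training
patient inside the prompt and answers with a label text; the label's
probability is recovered from the completion's token log-probabilities,
`P = exp(Σ logprob)`, with `1 − P` assigned to the complement class.
Around that predictor contract the package builds the full evaluation
methodology:

- **Schema-driven preprocessing** — declarative feature specs (kinds,
  units, per-feature rounding, level vocabularies), near-duplicate
  screening at 5% of each feature's SD, rule-ordered cleaning with a
  removal log, ordinal/one-hot encoding, and population-SD standard
  scaling.
- **Inverted cross-validation** — training folds of size `TR` are small
  and disjoint; each is tested on the union of the remaining folds
  (`TS = k·TR`, heavily overlapping across folds), so fold-to-fold
  spread measures sensitivity to training-set choice. The fixed test
  size is the largest common multiple of the training sizes that fits
  the smallest cohort, and `n_splits = (TR_max + TS)/TR_max`.
- **Prompt serialization** under five context-ablation variants, from
  full clinical context (names, units, outcome words) down to a pure
  statistical task (scaled 2-decimal values, generic `C0..C19` codes,
  labels 0/1), reproducing a fully printed worked example token for
  token.
- **Predictors** — a strict-parsing chat contract with a deterministic
  logistic mock backend for offline runs, plus conventional baselines
  (ridge logistic, random forest, boosted trees) with nested
  hyperparameter search (inner LOOCV for `TR ≤ 20`, stratified 3-fold
  otherwise, balanced class weights, degenerate folds scored 0.5).
- **Calibration** — Platt, isotonic (weighted PAVA) and beta maps fitted
  on inner leave-one-out training pairs; Brier scoring.
- **Metrics & decision curves** — Mann–Whitney ROC-AUC, noninterpolated
  average precision, F1, balanced accuracy, and net benefit
  `TP/n − (FP/n)·t/(1−t)` averaged over a clinically relevant threshold
  interval.
- **Overlap-aware inference** — percentile bootstrap CIs for fold means
  (stratified patient resampling of the common sample S with masking to
  each fold's test set, plus fold-cluster resampling; 5000 replicates)
  and hierarchical prediction intervals for a single realized split
  (20,000 replicates), for single models and paired differences, with
  the replicate loops in C++.
- **Synthetic cohorts** — class-conditional generators with planted,
  manifest-tracked defects and a matching logistic oracle of known
  implied AUC, so every stage is testable with no download and no model
  serving.

## Worked example

A two-feature synthetic cohort with a mock chat backend, evaluated under
the inverted design at training size 10:

```r
library(iclbench)

scenario <- scenario_spec(
  n = 600, prevalence = 0.3,
  features = list(num_feature("crp", 40, 80, sd = 25, unit = "mg/L"),
                  num_feature("lactate", 1.5, 2.6, sd = 0.9, unit = "mmol/L")),
  label_negative_text = "survives", label_positive_text = "dies",
  system_message = "Classify the patient outcome.",
  entity_phrase = "Patient ->")
cohort <- generate_cohort(scenario, seed = 1)
oracle <- make_oracle(scenario, seed = 2)
oracle
#> <oracle_spec> 2 coefficients, implied AUC 0.872 (MC se 0.0014)

plan <- plan_splits(TR = 10, TR_max = 50, TS = 400)
plan
#> <split_plan> TR=10 TS=400 (k=40), 41 folds, 9 training folds selected
splits <- sample_and_split(cohort$table, plan, seed = 3)

backend <- mock_chat_backend(oracle, cohort$table)
preds <- do.call(rbind, lapply(splits$splits, function(s) {
  train <- cohort$table
  train$data <- train$data[match(s$train_ids, train$data$patient_id), ]
  test <- cohort$table
  test$data <- test$data[match(s$test_ids, test$data$patient_id), ]
  prompts <- lapply(seq_len(400), function(i)
    build_prompt(train, test$data[i, ], cohort$schema, "full"))
  rec <- predict_prompts(prompts, backend, cohort$schema)
  rec$split_id <- s$split_id
  rec
}))

fp <- fold_predictions(preds, splits$cohort$labels, model_id = "mock_full")
ci_fold_mean(fp, "roc_auc", bootstrap_config(seed = 4))
#> <ci> roc_auc [mock_full]: point 0.8345, 95% interval [0.7890, 0.8769] (5000 replicates)
prediction_interval(fp, "roc_auc", bootstrap_config(seed = 4))
#> <pi> roc_auc [mock_full]: point NA, 95% interval [0.7870, 0.8778] (20000 replicates)
```

The point value is the mean ROC-AUC over the 9 training folds; the CI
quantifies uncertainty in that mean from both the test population (via
masked stratified patient resampling, which preserves the correlation
induced by the overlapping test sets) and the choice of training fold
(via cluster resampling). The prediction interval answers a different
question — what a *single* randomly realized training–test split may
yield — and is wider. Both intervals sit consistently with the oracle's
implied AUC of 0.872 given a 410-patient working sample.

End-to-end configured runs write a deterministic artifact tree
(`splits/`, `prompts/`, `predictions/`, `metrics/`, `intervals/`,
`manifest.json`):

```r
cfg <- experiment_config(scenario = scenario, training_sizes = 10,
                         test_size = 40, predictors = c("mock", "lr"),
                         variants = c("full", "no_context"),
                         seed = 17, out_dir = "run1")
validate_config(cfg)   # character(0) when valid
run_experiment(cfg)
```

The worked prompt fixture — an 11-patient sepsis cohort with 20 features
whose full-context and no-context serializations are shipped as golden
files — lives in `inst/extdata/` and is the anchor for the display and
scaling dialect (see the methods vignette, `vignettes/methods.Rmd`).

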