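---
title: "Evaluating in-context-learning clinical predictors on small cohorts: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating in-context-learning clinical predictors on small cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iclbench)
```

## The problem

Training a clinical risk model usually takes hundreds of patients. When
only a few tens are available — rare diseases, single-center registries,
phase-II trial arms — two difficulties compound: the model has little to
learn from, and there is almost nothing left to test on. `iclbench`
implements an evaluation pipeline built around two ideas:

1. **In-context learning as a predictor.** A chat-oriented language model
   is given every labeled training patient inside the prompt and asked to
   classify a new patient. No weights are updated; the prompt *is* the
   model. The probability of the emitted label is recovered from the
   completion's token log-probabilities, `P = exp(sum(logprob))`, with
   the complement `1 - P` assigned to the other class.
2. **Inverted cross-validation as the evaluation geometry.** Instead of
   large overlapping training sets and small disjoint test sets, the
   design uses small *disjoint* training folds and large, heavily
   *overlapping* test sets, so that the spread across folds measures
   sensitivity to training-set choice — exactly the quantity that matters
   when a deployed model will have been trained on one small cohort.

The package ships no language model. A deterministic logistic "oracle"
backend stands behind the same chat contract (completion text plus token
log-probabilities), so the entire pipeline — prompt serialization, strict
response parsing, probability extraction, calibration, metrics, bootstrap
inference — is exercised end to end, offline and reproducibly. Real chat
backends plug in by implementing a single `send(prompt)` function.

## The sampling design

For training size $TR$ and test size $TS$ with $TS = k \cdot TR$, a
sample $S$ of $(k+1) \cdot TR$ patients is drawn from the full cohort,
stratified on the outcome. $S$ is partitioned into $k+1$ stratified folds
of size $TR$; `n_splits` of them are selected (without replacement) as
training folds, and each is tested on the union of the other $k$ folds.

Two constraints pin the constants. The test size is the largest common
multiple of the training sizes under study that still fits the smallest
cohort: for sizes $\{10, 20, 50\}$ and a 462-patient cohort,
$TS = 400$. The number of training folds is fixed across training sizes
at the fold count of the *largest* training size,
$n_{\text{splits}} = (TR_{\max} + TS)/TR_{\max} = 9$. Both numbers are
recomputed from these formulas in the test suite and the acceptance
script, never hard-coded in the pipeline.

Randomness is disciplined: one root seed derives sub-seeds for (a) the
cohort draw, (b) fold assignment, and (c) training-fold selection,
consumed in that fixed order, so adding predictors or variants never
perturbs the splits. Stratified allocation uses largest-remainder
rounding (deterministic, order-independent ties); the spare `+1`
positives are spread over randomly chosen folds and negatives fill each
fold to exactly $TR$. Bit-identical fold membership to any particular
external run is not attempted — only the design's statistical properties
are (fold sizes, stratification within one patient of proportionality,
disjoint training folds, reproducibility from the seed).

## Prompt serialization and the context ablation ladder

A prompt is the standard instruct-model message sequence: one system
message, then one (user, assistant) pair per training patient, then a
final user message for the test patient — $2\,TR + 2$ messages. Patient
lines are `DisplayName: value[ unit]` items in schema order, closed by a
dataset-specific cue (e.g. `"Sepsis patient ->"`). The display dialect is
pinned down by a fully-printed worked example shipped as a fixture (an
11-patient sepsis cohort: 10 training patients plus 1 test patient):
integer-spec values print bare; decimal values print with trailing zeros
trimmed but at least one decimal (`100.0`, `14.2`); `%` attaches without
a space, other units with one. Rounding is half-away-from-zero — the
clinical-report convention — so golden files are stable.

Five variants span the ladder from full context to none:

* `full` — names, units, clinical outcome words.
* `no_units` — dimensional units removed; `%` is kept, since
  percent-valued features (hematocrit, FiO2) are dimensionless.
* `permuted_names` — additionally, every display name is replaced by the
  *next* feature's name (cyclically), destroying the name–value pairing
  while keeping the vocabulary.
* `generic_names` — names replaced by neutral codes `C0..C(m-1)`, in
  encoded-column order.
* `no_context` — a pure statistical task: values standard-scaled on the
  training patients and rounded to two decimals, generic codes, labels
  `"0"`/`"1"`, and a generic system message.

Two dialect details deserve note. First, scaling uses the **population
SD** (divisor $n$): the worked example discriminates between the two
conventions — the first training patient's scaled age prints as $-1.13$
under the population convention and $-1.07$ under the sample convention —
and the package reproduces all 220 printed scaled values exactly.
Second, the schema carries an `encoded_order` distinct from the display
order, because the worked example's generic codes follow the source
table's column order rather than the prompt's display order. Generated
output uses ASCII hyphen-minus throughout; the publication typography's
en-dash is normalized away in the shipped golden files.

For `permuted_names` the cycle is applied to the raw feature list (not
the encoded columns); for `generic_names` a feature's code is the index
of its first encoded column, which coincides with one-code-per-feature
whenever categorical features are binary.

## Predictors

**Chat predictors.** Parsing is strict: the completion, after stripping
surrounding whitespace, must equal one of the two label texts exactly
(case-sensitive); anything else raises an error carrying the raw text.
Instruction-following models comply in practice, and a silent fallback
would corrupt the probability stream. Multi-token completions sum their
token log-probabilities; no length normalization is applied.

**Conventional baselines.** Ridge-penalized logistic regression, random
forests (`ranger`) and gradient-boosted trees (`xgboost`) run behind a
nested grid search inside each training set: inner leave-one-out for
$TR \le 20$, stratified 3-fold otherwise; standard scaling is refit
inside every inner training part to avoid leakage; the grid point with
the best inner ROC-AUC (pooled held-out predictions under LOOCV, mean of
fold AUCs under 3-fold) is refit on the full training set. Class weights
are balanced ($n / 2 n_c$). Inner folds whose training part contains a
single class — routine at $TR = 10$ with one positive — contribute the
degenerate probability 0.5. The logistic fit is an in-package IRLS with
the inverse-regularization convention (penalty $\|\beta\|^2 / 2C$,
intercept unpenalized) because the established penalized fitter refuses
classes with fewer than two observations; a test cross-checks it against
`glmnet` on well-conditioned data. Default grids are small, as befits
$n \le 50$: $C \in \{0.01, 0.1, 1, 10\}$; forests with 100 trees, depth
$\{2, 4, \infty\}$, min leaf $\{1, 2\}$; boosting with learning rate
$\{0.05, 0.1\}$, $\{3, 7\}$ leaves, $\{50, 100\}$ rounds. All grids are
plain data frames and overridable.

**The mock oracle.** A logistic model over the encoded features whose
coefficients are proportional to standardized class-mean differences,
with intercept anchored at the prevalence log-odds. Its implied
(Bayes-level) ROC-AUC is estimated once by Monte Carlo and cached; for a
single Gaussian feature with class shift $\delta$ and unit SD it matches
the closed form $\Phi(\delta/\sqrt{2})$. The oracle answers *through the
chat contract* — label text plus a single log-probability
$\log \max(p, 1-p)$ — so the parsing path under test is identical to a
live backend's.

## Calibration

Completion probabilities pile up near 0 and 1. Three post hoc maps are
provided, each fitted on training-set pairs produced by inner
leave-one-out (the held-out probability is 0.5 whenever the remaining
training patients are single-class), then refit on the pooled pairs —
the pooling choice is ours, made because per-fold averaging is undefined
for isotonic knots:

* **Platt**: logistic regression on the logit of the score.
* **Isotonic**: weighted pool-adjacent-violators (written in-package;
  the base isotonic fitter has no weights), linear interpolation between
  knots, boundary clamping.
* **Beta**: $\mu(s) = \mathrm{plogis}(c + a \log s - b \log(1-s))$ with
  $a, b \ge 0$, fitted as a logistic regression on $(\log s,
  -\log(1-s))$; a negative coefficient triggers a refit without that
  feature. Scores are clipped to $[10^{-6}, 1-10^{-6}]$ before logs.

Beta and Platt are strictly monotone, hence leave ROC-AUC unchanged;
isotonic introduces ties, which for informative scores applied out of
sample can only merge mostly-concordant pairs and therefore does not
increase AUC (the suite asserts this in the train-fit/test-apply
setting; *within* the fitting sample the inequality can reverse, since
pooling collapses locally discordant regions).

## Metrics and decision curves

ROC-AUC is the tie-adjusted Mann–Whitney statistic; average precision is
the noninterpolated precision-weighted sum of recall increments with
tied scores collapsed into one threshold step (no trapezoid, which is
optimistically biased in imbalanced settings); F1 and balanced accuracy
use the 0-on-zero-denominator convention. Net benefit at threshold $t$
is $TP/n - (FP/n)\, t/(1-t)$, classifying positive at $p \ge t$ (the
closed-left tie rule is ours; a tie rule is rarely stated). The curve is
evaluated on a 0.01-step grid and summarized by the arithmetic mean over
grid points inside a clinically relevant interval carried by the schema
— $(.05, .30)$ for sepsis-mortality-like tasks, $(.30, .60)$ for
nodal-status-like tasks, $(.02, .15)$ for leukemia-subtype-like tasks,
intervals centered near prevalence and shifted down where the stakes of
a missed positive are higher.

## Uncertainty: two bootstraps for an unusual geometry

Because the test sets of different folds share most of their patients,
pooling them (or treating fold metrics as independent) is wrong. Two
procedures address the two questions one can ask.

**CI for the fold mean.** Per replicate: (1) resample patients with
replacement from the full sample $S$, stratified by outcome (positives
and negatives resampled separately to their original counts, preserving
prevalence exactly); (2) mask the resample to each fold's test members
and compute the metric on the masked multiset — the shared patients
induce exactly the between-fold correlation the design creates; (3)
resample folds with replacement (a cluster bootstrap over training-set
choice — with replacement is our reading, the standard one for cluster
bootstraps) and store the mean over the drawn folds. The 95% CI is the
percentile interval over 5000 replicates (percentile rather than BCa:
with 9 clusters BCa's acceleration estimate is unstable). A drawn fold
whose masked test multiset is single-class is skipped in that
replicate's mean — the metric is undefined there and imputing would bias
— and the skip frequency is reported.

**Prediction interval for a single realized split.** Per replicate, one
fold is drawn uniformly (the training-set choice) and its test set
resampled with replacement, stratified; the percentile interval over
20,000 replicates describes the dispersion an individual training–test
realization may show — wider than the CI for the mean, by construction.

**Pairing.** For model comparisons, both models see the *same* patient
resample and the same fold draws inside every replicate before
differencing. The replicate loops are implemented in C++ (scores never
change across replicates, so sort orders and tie groups are precomputed
per fold and only the resample weights vary); the R-level RNG drives all
draws, so `set.seed` governs everything. The weighted metric kernels are
verified against the plain R metrics on expanded multisets, and the
paired streams against independently-run marginal streams.

## The synthetic-data generator

Scenarios emulate the shapes of published small-cohort tasks: a
sepsis-mortality-like cohort (n = 1205, prevalence 191/1205, 19 numerical
features plus binary gender), a gastric-cancer nodal-status-like cohort
(n = 462, prevalence 258/462, 2 numerical / 4 categorical / 2 ordinal),
and an acute-leukemia-subtype-like cohort (n = 584, prevalence 72/584,
10 numerical features). Numerical features are Gaussian per class with a
location shift (lognormal optional, to stress the rounding and
formatting path with skewed labs); categorical and ordinal features draw
from per-class level probabilities. Class separations in the presets are
moderate (shifts of 0.1–1.0 SD, several uninformative features) — chosen
once as what small-cohort clinical signal typically looks like. Labels
are independent Bernoulli draws at the scenario prevalence; with
`exact_prevalence = TRUE` the class counts are fixed instead, emulating
a cohort obtained by outcome-stratified sampling.

Defects are planted with a ground-truth manifest — missing cells, exact
duplicates, and near-duplicate rows perturbed by at most 1% of each
feature's SD, far inside the 5%-of-SD screening radius — so cleaning
tests are exact rather than statistical. What the generator does *not*
emulate: correlations between named labs, measurement artifacts,
informative missingness, and free text. Passing tests therefore
demonstrate the pipeline's correctness and calibration under its own
assumptions, not clinical performance on real data.

## Numerical and testing choices

* Near-duplicate screening: two patients are near duplicates when every
  numerical feature differs by at most 5% of that feature's SD
  (population convention, computed on the loaded table before any
  removal) and every categorical/ordinal value matches exactly — a
  fraction-of-SD band is meaningless for codes. Implementation is the
  vectorized all-pairs computation; tests compare it against a literal
  double-loop oracle up to 200 rows.
* Cleaning order: missing rows, exact duplicates, near duplicates
  (keep-first / keep-finer-precision / drop-both), then dataset-specific
  rules (zero-valued biomarkers, class removal), every removal logged
  with its triggering rule.
* Zero-SD columns scale to 0 rather than erroring: a 10-patient
  stratified sample can easily make an indicator column constant.
* Statistical test tolerances are derived from independent simulations
  of a *correct* estimator's sampling distribution (e.g. the beta-map
  identity-recovery bound at n = 2000 is the 99.9th percentile of a
  maximum-likelihood fit's max grid deviation, 0.06), not from the
  implementation under test.
* The bootstrap-coverage experiment runs 300 simulations of the full
  study geometry ($TR = 10$, $TS = 400$, 9 folds, cohort 410, prevalence
  0.3, implied AUC 0.85) with 2000 CI replicates each — sizes chosen to
  keep the experiment under a minute while leaving the coverage
  estimate's binomial error near one percentage point. Measured coverage
  of the nominal 95% fold-mean CI: ~95% for ROC-AUC. For average
  precision coverage sits slightly below nominal (~92%): noninterpolated
  AP carries a small finite-sample optimism (about +0.003 at 400 test
  patients, measured by direct simulation) which the percentile
  bootstrap inherits. This is a property of the statistic, documented
  rather than patched.
* Intervals, prompts, predictions and metrics serialize to JSON/CSV with
  `digits = NA`, and experiment artifacts contain no timestamps, so a
  rerun under the same configuration and seed is byte-identical.

## Limitations

The pipeline evaluates predictors; it does not serve language models,
reproduce any particular model's outputs, tokenize prompts, or model
costs. TabPFN/TabICL-style pretrained tabular predictors are accommodated
only as adapters behind the chat-free predictor contract. Multi-class
outcomes, imputation (small cohorts here remove rather than impute), and
multiple-testing correction across the model-by-size grid are out of
scope. The orchestration layer is exposed as R functions
(`experiment_config()`, `validate_config()`, `run_experiment()`); these,
with the vignette, are the package's interface — there is no shell
entry point beyond the acceptance script.
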