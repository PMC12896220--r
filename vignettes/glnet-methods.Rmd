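---
title: "Methods: global-local state-space networks for depression-risk modelling"
author: "glnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: global-local state-space networks for depression-risk modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glnet)
```

## The problem and the model

`glnet` models the probability that a student is depressed from a survey of
mixed-type risk factors: demographics (age, gender, city), academic
indicators (CGPA, study satisfaction, academic pressure), lifestyle items
(sleep-duration category, dietary habits, work/study hours, job
satisfaction, work pressure) and additional history items (profession,
degree, suicidal ideation, family history of mental illness, financial
stress). The label is binary: depressed (1) versus non-depressed (0).

The classifier is a U-shaped residual network of *Global-and-Local Blocks*
(GLBs). The encoded factor vector is first linearly embedded into `E`
deep features (default `E = 128`). Each GLB then treats its `D`-dimensional
feature vector as a length-`D` sequence of scalar channels and applies, in
order:

1. a **selective state-space scan** (Mamba-style) for global context:
   with diagonal continuous-time state matrix `A < 0` and input-dependent
   step size and mixing vectors,

   $$\Delta_t = \mathrm{softplus}(w_d x_t + b_d),\quad
     B_t = w_B x_t + b_B,\quad C_t = w_C x_t + b_C,$$
   $$\bar A_t = \exp(\Delta_t A),\quad
     h_t = \bar A_t \odot h_{t-1} + \Delta_t B_t x_t,\quad
     y_t = \langle C_t, h_t\rangle + D\,x_t,$$

   the zero-order-hold discretization of a linear state-space model whose
   parameters adapt to the current input — the "selective" mechanism that
   lets the layer carry long-range context across the feature sequence in
   linear time;
2. a **1-D convolution** (kernel 3, zero-padded "same") for local context;
3. a leaky-ReLU activation;
4. a linear resize — the first two blocks double the width, the last two
   halve it;
5. batch normalization.

The four blocks form the chain `E -> 2E -> 4E -> 2E -> E`, and a residual
connection adds the first block's output (width `2E`) to the third block's
output before the final block — the "U" that joins shallow and deep
features of equal width. A linear 2-class head with softmax produces the
depression probability.

### Assumptions and consequences

* The feature *order* is meaningful to the scan and the convolution, so
  the encoded column order is locked to the schema; permuting columns
  changes predictions (this is tested).
* Batch normalization uses batch moments during training and frozen
  running moments at inference, so evaluation is deterministic and
  batch-size invariant (also tested).
* The model expects standardized inputs; standardization parameters are
  fit on the training partition only.

## Encoding and partitioning

Categorical survey factors (at minimum profession, degree, city, sleep
duration, dietary habits) are split into one indicator column per level,
*without* dropping a reference level, so that every level can later carry
its own attribution (e.g. "sleep duration of less than 5 h"). Ordinal
survey scales (academic pressure, satisfaction, financial stress) stay as
single numeric columns: their attribution is naturally colored low-to-high
in summary plots. Binary factors map to a single 0/1 column. The encoded
column count is therefore a closed-form function of the schema.

Records with any missing field are dropped listwise — no imputation — and
the dropped count is reported.

The train/test split uses floor rounding on the *training pool*:
`pool = floor(n (1 - test_fraction))`, test = remainder. At 80:20 this
maps 27,898 records to a 22,318-record pool and 5,580 test records; the
validation set then takes `floor(0.15 * pool)` rows. Assignment is
stratified by label with largest-remainder apportionment, so each
partition's prevalence tracks the parent's; gender/age consistency is a
tolerance check, not forced. Whether the original split was stratified is
not documented; stratification is the default here because matched margins
across partitions are the reported behaviour.

## Training recipe

* **Loss**: class-weighted cross-entropy with inverse-frequency weights
  `w_c = n / (2 n_c)` (mean one when balanced) against the roughly 59/41
  label imbalance.
* **Optimizer**: Ranger, i.e. RAdam (variance-rectified Adam) with
  Lookahead (slow weights updated every 6 steps, interpolation 0.5).
  Implemented here directly; verified against the gradient by
  finite-difference checks through the entire network.
* **Learning rate**: 1e-4 initially, cosine-annealed to zero over the
  epoch budget, so the rate decreases monotonically through training.
  The default is 100 epochs with patience-10 early stopping on
  validation loss, and scaled-down runs in this package state their
  epoch budget explicitly.
* **Batch size**: 256.
* **Augmentation**: 10% factor dropout — each training entry is
  independently zeroed with probability 0.1 — and a 10% data shift on
  surviving entries. A "shift" of a tabular factor has no single
  canonical form; additive uniform jitter of magnitude 0.1 on the
  standardized scale was chosen because it is scale-free across factors
  and seed-reproducible. The alternative readings (multiplicative ±10%,
  index shifting) are isolated behind `augment_batch()` if a user wants
  to swap them.
* The best-validation-loss weights are returned, and training is bit
  reproducible under its seed.

## Evaluation

Accuracy, sensitivity, specificity and F1 follow the standard confusion
matrix identities; `acc = (TP+TN)/n`, `sen = TP/(TP+FN)`,
`spe = TN/(TN+FP)`, `f1 = 2TP/(2TP+FP+FN)`. Ties at the decision
threshold (default 0.5, configurable) go to the positive class so that
reports are bit-reproducible. AUC is the tie-corrected Mann-Whitney
statistic. Confidence intervals are percentile bootstrap over
(score, label) pairs — 1,000 seeded replicates by default; single-class
replicates are skipped and counted, and more than 50% degenerate
replicates is an error rather than a silent answer. Zero-denominator
metrics are reported as `NaN` with a warning, never as 0.

## Shapley factor attribution

Per-factor contributions are Shapley values of the class-1 probability.
The coalition value is the *interventional* expectation: features in the
coalition are pinned to the explained instance, the rest are filled from a
background reference sample drawn from the training partition (test-set
backgrounds trigger a leakage warning), and the model's predictions are
averaged. A literal reading of the defining sum would retrain the model
for every feature subset, which is both intractable (2^114 subsets) and
not what SHAP-style analyses do in practice; the background-masking value
function is the standard fixed-model interpretation.

Two estimators are provided:

* **exact enumeration** over all `2^d` coalitions for `d <= 15` — the
  oracle used by tests, which verifies the efficiency
  (`sum(phi) + base = f(x)`), symmetry and dummy axioms;
* **permutation sampling** (default `M = 200` orderings per row) — an
  unbiased estimator with per-feature Monte-Carlo standard errors, batched
  so each model call evaluates thousands of hybrid rows at once. Its
  telescoping sum preserves efficiency exactly per sampled row.

Attribution targets the probability (not the logit): positive values push
toward the depressed class, matching the beeswarm sign convention.
Global summaries rank encoded columns by mean |phi|; subgroup summaries
recompute the ranking on a raw-factor filter (e.g. `Gender=Female`) and
report the signed correlation between each column's value and its phi —
the quantity behind statements like "higher CGPA, higher predicted risk
among female students".

## The synthetic-data generator

Real student-survey records cannot ship with the package, so every stage
is exercised against a generator with a known logistic ground truth over
the sixteen-factor schema above. Defaults:

* marginals: truncated normals for age (26 ± 5 on 18-40), CGPA
  (7.5 ± 1.5 on 5-10) and work/study hours (6 ± 3 on 0-12); discrete
  uniform 1-5 for the survey scales; uniform categoricals; 50% "Yes" for
  the binary history items. Marginals are not the point — the planted
  conditional structure is — and all are overridable.
* main effects, on unit-sd standardized terms so coefficient magnitude is
  effect size: suicidal ideation +2.0, academic pressure +1.4, financial
  stress +1.1, work/study hours +0.9, family history +0.7, sleep below
  five hours +0.6; age -0.5, healthy diet -0.45, study satisfaction -0.4.
  Indicator terms are standardized by their level probability and sd for
  exactly this comparability; interaction indicators stay raw 0/1 so the
  partner effect is confined to the indicated subgroup.
* planted interactions: CGPA × female +0.8 (CGPA matters for female
  students, slope ~0 for male) and unhealthy diet × doctoral degree +1.0.
* intercept calibrated by root-finding so the realized prevalence matches
  the 59% target; labels are Bernoulli draws.

What passing tests on this generator do **not** show: anything about the
real survey's joint distribution (no copulas, no missingness mechanism,
no measurement error), nor any performance figure on real survey data,
which cannot ship with the package. The generator supports *recovery*
claims only: that the pipeline finds structure that is genuinely there.

## Numerical choices

* Scan parameters initialize to the standard stable regime: `A = -(1..N)`
  (N = 16 states by default), step-size bias so `E[delta] ~ 0.01`, skip
  `D = 1`, near-identity convolution kernel — the untrained block
  approximately passes its input through, which keeps early training
  well-conditioned.
* Softplus is computed in its overflow-safe form; batch-norm variance is
  floored at `eps = 1e-5`; standard deviations of constant columns are
  floored at 1e-8 so standardization never divides by zero.
* Checkpoints serialize doubles with 17 significant digits, so
  save/load round-trips are bit-exact.
* One user seed fans out to per-stage streams (hashed stage names), so
  stages are independently rerunnable yet jointly deterministic.

## Problem sizes used by the test suite and acceptance script

Desk-scale runs keep the full pipeline inside a few minutes while leaving
the contracts intact: recovery studies use n = 5,000 records, a width-64
embedding, the default learning rate (1e-4), batch size 256 and a
200-epoch budget without early stopping (at desk scale an epoch holds
few optimization steps, so the budget is chosen to keep the total step
count comparable to a full-scale run; a noisy small-validation-set
minimum would otherwise freeze training early); attribution explains 360
test rows with 12 permutations against a 16-row training background. Split arithmetic is
checked at the full n = 27,898. The package defaults are unchanged
(`embed_dim = 128`, 100 epochs); the smaller study sizes are stated
choices of the bundled experiments, not package behaviour.

## Known limitations

* The scan treats a fixed feature ordering as a sequence; the ordering is
  schema-locked but still arbitrary, and no claim is made that it is the
  best ordering.
* Ranger here is RAdam + Lookahead without gradient centralization.
* Bootstrap CIs are percentile (no analytic DeLong AUC intervals).
* Attribution assumes feature independence in the interventional sense,
  as all background-masking SHAP variants do; correlated factors share
  credit accordingly.
* No imputation, survey weighting or free-text handling.
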