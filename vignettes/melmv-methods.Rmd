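---
title: "Multi-view ensemble learning with missing values: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-view ensemble learning with missing values: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Inpatient falls are graded on the 1–9 AHRQ Common Format harm scale; a score
of 6 or above marks significant harm and defines a *severe* fall. The goal is
a severity index — a probability in [0, 1] that a given fall is severe —
computed from routinely recorded clinical data that arrives in distinct
*views*: demographics (age, sex, race), admission diagnoses (ICD-9 codes
collapsed to hierarchy categories), procedures in the ten days before the
fall (CPT codes), and bone-density measurements (forearm and dual-femur DEXA,
each a BMD value plus t-score). The views differ sharply in availability:
demographics and diagnoses exist for every case, while procedures (~30%),
dual-femur (~7.5%) and forearm bone density (~5%) are mostly missing. The
central methodological question is how to combine views without discarding
the majority of cases or imputing hundreds of raw features.

## The model

`melmv` implements a stacked multi-view ensemble with a model-based
missing-data device:

1. **Stage one.** Each view is learned independently, on the cases where it
   is available, by one linear and one nonlinear base inducer. The linear
   inducer is ridge-penalized logistic regression (the penalty is needed for
   the several-hundred-column sparse diagnosis view; a fixed small
   `logistic_lambda = 0.01` is the default). The nonlinear inducer is a
   support-vector machine for the wide views and support-vector *regression*
   for the two-column bone-density views. All inducers emit scores in [0, 1]:
   logistic outputs are probabilities; SVM decision values pass through a
   Platt-style sigmoid calibration fitted on the training decision values
   (the contract is rank preservation, verified in the tests); SVR outputs
   are clipped.

2. **Missing-view substitution.** For each classifier, the Youden-optimal
   cutoff of its own training ROC curve — the score maximizing
   sensitivity + specificity under the rule "score ≥ t ⇒ severe" — is stored
   as its *threshold*. Cases whose view is missing receive the threshold in
   place of a prediction, and a binary *missing flag* (1 = substituted)
   records which outputs are real. Flags are emitted only for views with any
   missing cases. The completed score columns and the flags together form the
   meta-feature table: one gap-free row per case.

3. **Wrapper ensemble selection.** Rather than combining every candidate, a
   wrapper search selects the subset of meta-features maximizing the
   cross-validated AUC of a logistic meta-learner: exhaustive over all
   2^p − 1 subsets when p ≤ 15 candidates, greedy-forward otherwise
   (stopping when no addition gains more than `1e-4` AUC). The selected
   subset is refit on the full training table; the sigmoid of its linear
   predictor is the severity index.

## Numerical and procedural choices

* **Youden candidate cutoffs** are the midpoints between adjacent distinct
  sorted scores plus sentinels below/above all scores, clipped into [0, 1];
  midpoints make the rule independent of the score scale. Ties are broken
  toward the smallest maximizing candidate, for determinism. When all scores
  are identical there is no interior candidate; the implementation returns
  that score itself (every cutoff at or below it is equivalent, with
  sensitivity + specificity = 1). The implementation computes sensitivity
  and specificity from sorted-score counts; the test suite checks it against
  a naive exhaustive search, exactly, on hundreds of random instances.

* **Thresholds are computed on the same training rows the classifier was fit
  on**, with no inner split. Inside cross-validation, classifiers and
  thresholds are refit within each training fold, so no test-fold
  information ever reaches a threshold.

* **Selection CV** uses one stratified k-fold partition (default 10 folds),
  shared across all candidate subsets so their comparison is paired, with a
  seed derived independently of the outer evaluation. The subset score is
  the pooled out-of-fold AUC of the logistic meta-learner. Ties break toward
  the smaller subset, then lexicographically. If no subset beats AUC 0.5 the
  single best column is returned with a warning — the selection is never
  empty.

* **Outer evaluation is fully nested**: `repeated_kfold_cv()` and
  `cv_compare()` refit the entire pipeline — stage-one classifiers,
  thresholds, selection, meta-fit, and (for the single-model baselines) the
  imputation models — inside every training fold. Anything less leaks. Fold
  assignment is stratified by outcome; at ~16% prevalence an unstratified
  10-fold split could otherwise produce single-class training folds. Pooled
  out-of-fold scores per repeat yield one AUC per repeat; pooling is
  smoother than averaging per-fold AUCs at this prevalence (the alternative
  is noted, not implemented as an option).

* **Degenerate inputs.** A view whose available rows hold a single label
  class cannot be learned; `fit_view_classifier()` errors, and the pipeline
  drops that (view, inducer) pair with a warning. A view whose features are
  all constant yields a degenerate classifier scoring 0.5 with a warning, so
  pipelines on pathological inputs still run. Perfect separation in the
  meta-fit (detected by boundary fitted values or glm warnings) falls back
  to a ridge-penalized fit.

* **Serialization.** Stage-one parameters are extracted into plain numeric
  form at fit time (coefficients for logistic; weight vector and offset for
  linear SVM/SVR; support-vector expansion for RBF) and *all scoring is
  computed from these parameters*, never from the fitting object. Models
  therefore round-trip through 17-significant-digit JSON exactly, and a
  reloaded model reproduces predictions bit-for-bit.

## Baselines

The comparator roster mirrors the study design: (i) single logistic and
single SVM models on the column-wise concatenation of all views, with
missing entries completed by chained-equation imputation; (ii) a random
forest on exactly the meta-features the ensemble sees, with
variables-per-split tuned by cross-validated AUC; (iii) an unselected
logistic ensemble of all candidates; and (iv) a logistic combiner of the two
single-view models.

The chained-equation imputation is written in-package (no installed package
provides it): each incomplete column is regressed on a pre-screened
predictor set — linear model for numeric columns, logistic for binary — and
missing entries are drawn from the fitted conditional, cycling ten times by
default. Two stabilizations matter in this data shape: predictors per column
are capped at the 30 largest absolute correlations *and* at a third of the
column's observed rows (bone-density columns are observed on only 5–7.5% of
cases; an unrestricted regression there is wildly overdetermined and the
cycle diverges), and numeric draws are squeezed into the observed range.
Held-out data are imputed from the training-fitted column models only.
Draws are stochastic by design; each CV run re-imputes with a fresh seed.

## The synthetic cohort generator

The cohorts this method was developed on are protected health records with
no public accession, so the generator is first-class, tested code that
emulates their statistical structure. Defaults (`scenario("table1_like")`)
encode the published marginals: age ~ N(63.0, 15.7²) floored at 18, 51.3%
female, the reported race multinomial, a 723-category diagnosis vocabulary
with geometric-decay popularity and a per-case Poisson(4) category count
(each category emitting one or two ICD-9-style subcodes, so the
collapse-and-deduplicate rule is exercised), a 202-code procedure vocabulary,
availability rates (30.4%, 7.5%, 5.0%), and a target prevalence of 16.2%.
Bone density is a correlated (BMD, t-score) pair with t ~ N(−1.2, 1.4²),
between the two published measurement types; the published dual-femur BMD
mean differs sharply between the training and testing cohorts with similar
t-scores — likely an extraction artifact — so the t-score is the signal
carrier and BMD is ancillary.

Risk is latent-linear: standardized age, a female indicator, per-category
and per-code effects drawn N(0, sd) with scenario-set scales, and a negated
standardized t-score effect (lower bone density, higher severity risk). The
intercept is solved by bisection so the expected prevalence hits the target
to within 0.1 percentage points. Availability is drawn per view; with
`gamma ≠ 0` the final availability is redrawn as
Bernoulli(sigmoid(logit(rate) + γ·label)) — outcome-informative missingness,
the regime in which missing flags carry signal. Because the label must be
drawn before outcome-informative availability, the latent risk uses a
provisional missing-completely-at-random availability draw; the scenarios
that set γ ≠ 0 put zero risk weight on the missable views, so the
re-draw never contradicts the risk model.

Scenario design, fixed up front: the mechanism scenarios (`null`,
`single_view_signal`, `all_view_signal`, `informative_missingness`) use a
compact vocabulary (60 diagnosis categories, 20 CPT codes) because they
probe pipeline behaviour — leakage, selection, the flag mechanism — not the
published cohort's scale; `table1_like` keeps the full vocabularies. What
the generator does *not* emulate: real ICD-9 semantics and between-code
correlation structure, longitudinal records, repeat falls by one patient,
and site effects. Tests passing on these cohorts therefore demonstrate the
pipeline's statistical mechanics, not clinical transportability.

## What the property suite establishes, and at what sizes

The acceptance-style tests run end to end at sizes chosen for a single CPU:
exact oracle equivalence of the Youden cutoff and the AUC statistic on 500
random instances each; exact equivalence of the DeLong variance with the
materialized structural-components estimator on 100 instances, plus
agreement of DeLong and bootstrap interval widths within 20% on binormal
scores at n = 500; a null cohort (n = 2000, 5-fold nested CV) on which every
model must score within [0.45, 0.55] — the leakage alarm; recovery of the
informative view's classifier in ≥ 90% of 100 replicates at n = 2000 (run
with a logistic-only candidate roster to isolate subset selection from
inducer choice); the flag mechanism isolated over 20 paired replicates;
superiority of the selected ensemble's mean held-out AUC over the
unselected ensemble and both single models across 20 replicates at
n = 3000; generator calibration at n = 5000; byte-identical
simulate→train→predict runs; and 90–99% coverage of the 95% bootstrap AUC
interval over 200 cohorts with true AUC 0.75.

One property deserves emphasis because it was discovered by the suite: under
outcome-informative missingness, the *completed score columns* of missable
views are themselves weak missingness proxies — substituted cases sit
exactly at the threshold while observed noise scores spread around a
different mean, so even a "flag-free" meta-learner that sees substituted
columns detects the outcome. This is a property of the substitution device,
not a bug. The flag-mechanism test therefore compares a meta-learner on the
always-observed views' scores plus flags against one on the always-observed
views' scores alone — identical rosters except the flags.

## Known limitations

* The SVM/SVR hyperparameters are fixed defaults (linear kernel, cost 1),
  tunable through `learner_control()` but not searched; per-view
  hyperparameter optimization is out of scope.
* The DeLong interval is a normal approximation clipped to [0, 1]; a
  logit-scale interval is not implemented.
* `wrapper_select` with the exhaustive search at the full 13-candidate
  roster evaluates 8191 subsets per fold set; inside nested CV this is
  costly, which is why the simulation studies and the comparison harness
  default to the greedy search. Exhaustive and greedy agree on instances
  with a dominant subset (tested).
* Prediction on cases whose views were *all* absent at training time falls
  back entirely to thresholds and flags; the severity index then depends
  only on the missingness pattern.
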