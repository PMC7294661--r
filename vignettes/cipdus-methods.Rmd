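---
title: "Methods: building and evaluating the CIP-DUS risk score"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: building and evaluating the CIP-DUS risk score}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cipdus)
```

## The problem and the model

Digital ulcers (DU) are a painful ischemic complication of systemic
sclerosis (SSc). The CIP-DUS is an additive points score that predicts which
SSc patients will develop new DU over a ~12-month follow-up, combining
clinical data (cutaneous subtype, modified Rodnan skin score > 8, pulmonary
arterial hypertension), patient history (present or past digital ulcers or
pitting scars), nailfold capillaroscopy (NC; the Cutolo scleroderma pattern
grades and reduced capillary density), fluorescence optical imaging (FOI)
and colour Doppler ultrasonography (CDUS).

The construction recipe implemented here is:

1. For each candidate feature, fit a univariate logistic regression of the
   outcome (new DU) on the feature and estimate its discrimination by the
   AUC, both apparent and after 10-fold cross-validation (`cv_auc()`).
2. Retain features whose cvAUC exceeds 0.6 and convert the cvAUC to an
   integer weight (`weight_from_cvauc()`): 1 for (0.6, 0.65], 2 for
   (0.65, 0.7], 3 above 0.7. The four-level NC pattern is graded
   early = 1, active = 2, late = 3, normal = 0.
3. A patient's score is the sum of the weights of their positive features
   plus the NC pattern weight (`compute_scores()`); classification uses
   `score >= cutoff` with a default cutoff of 10.
4. The full score (maximum 16 points) is compared against an imaging-free
   variant that drops the FOI and CDUS components (maximum 14) by the DeLong
   test on the correlated AUCs, the continuous net reclassification
   improvement (NRI), the integrated discrimination improvement (IDI), and
   Hosmer-Lemeshow calibration.

The published instrument departs from the weight rule in two places (mRSS > 8
carries weight 2 although its cvAUC of 0.73 maps to 3; PAH is included with
weight 1 although its cvAUC of 0.54 maps to exclusion), and the early NC
pattern keeps weight 1 despite a cvAUC of 0.55, following the instrument's
explicit grading of the pattern levels. `canonical_weights()` is therefore
the source of truth for the published score, while the rule path exists for
building new scores; `weight_rule_audit()` surfaces the departures rather
than hiding them. Whether the two binary-feature departures were deliberate
clinical overrides is not documented in the source study; this package makes
no attempt to adjudicate and simply provides both paths.

```{r audit}
weight_rule_audit()
```

## Per-feature diagnostic statistics

Each feature is summarized against the outcome in a 2x2 table
(complete-case per feature, which is why denominators differ across
features). The odds ratio uses the Haldane–Anscombe continuity correction
(+0.5 to all four cells) *only when a cell is zero*: this exact convention
reproduces the published interval of the history-of-ulcers feature, whose
table has no feature-negative events. The confidence interval is the Woolf
log-normal interval on the corrected cells; the p-value is the two-sided
Fisher exact test (sum of hypergeometric probabilities not exceeding the
observed table's) on the uncorrected counts. Displayed odds ratios are
conventionally rounded to one decimal, half away from zero.

`reconstruct_table()` inverts a printed sensitivity/specificity pair and its
group denominators back into the implicit 2x2 table, which is how
`replicate_published_numbers()` recomputes every published odds ratio
without patient-level data:

```{r replicate}
replicate_published_numbers()
```

The two `FALSE` rows are last-digit artifacts of the zero-cell row: the
Haldane reconstruction gives 36.15 against a printed 36.2 (and an upper CI
bound of 626.4 against 626.9); the study does not state its
separation-handling method, and this package documents the reconstruction
rather than chasing the final digit.

## Cross-validated AUC

`cv_auc()` splits the data into k = 10 outcome-stratified folds, fits the
univariate logistic model on each complement, and computes **one** AUC on
the pooled out-of-fold predictions. With only 22 events, per-fold AUCs would
rest on ~2 events each and be frequently degenerate; pooling keeps the
estimate defined. Stratification is a package choice (the source study does
not state it); fold assignment is controlled by an explicit seed, and a
training fold containing a single outcome class raises an error rather than
being silently skipped. AUC itself is computed twice internally — as the
trapezoidal area under the empirical ROC staircase and as the midrank
Mann-Whitney statistic with ties credited 0.5 — and the test suite asserts
the two paths agree to 1e-12, with a brute-force pairwise loop as a third
oracle.

## Numerical choices

* **Separation**: the logistic slope is capped at |15| on the log-odds scale
  and flagged. Prediction *ordering* is unaffected, so AUCs are valid; the
  odds ratio reported for a separated feature comes from the
  continuity-corrected table, never from the capped slope.
* **Score-to-risk mapping**: model comparison maps each integer score to a
  probability through its own univariate logistic fit of outcome on score
  (an empirical per-score-value rate mapping is available behind
  `mapping = "empirical"`). Mapped risks are kept off the exact 0/1 boundary
  (clamped at 1e-6) because a capped-slope fit under quasi-separation would
  otherwise emit degenerate risks.
* **Hosmer-Lemeshow**: patients are cut into risk-decile groups with tied
  probabilities kept together; the statistic uses the
  `(obs-exp)^2 / (exp (1 - exp/n))` form. Degrees of freedom default to
  g - 2 (probabilities fitted in-sample); when probabilities come from an
  external model the caller should pass `df = n_groups`, which is what the
  calibration-uniformity tests do. With fewer than three distinct
  probabilities quantile grouping is impossible and the implementation falls
  back to equal-sized positional groups with a warning.
* **NRI flavor**: continuous / any-movement. The published reclassification
  counts (14 up / 4 down of 22 events, 18 down / 9 up of 54 non-events)
  refer to movements of predicted probabilities, not category crossings, and
  they reproduce NRI = 62.1 exactly on the x100 scale used throughout.
  The NRI p-value is the asymptotic normal test with the multinomial
  variance of the two net-movement proportions; the IDI p-value is the
  two-group z-test on per-patient probability changes.
* **Cutoff search**: thresholds are the observed score values (the score is
  integer-valued by construction); positivity is `score >= threshold`, and
  Youden ties resolve toward higher sensitivity, then lower threshold.

## The synthetic cohort generator

No patient-level data accompany the source study, so `cipdus_config()`
encodes the development cohort's statistical structure: exactly 22 events
and 54 non-events (stratified, never sampled), each binary feature drawn
with P(positive | event) equal to its published sensitivity and
P(positive | non-event) equal to one minus its published specificity.
Missingness is modeled only for the two features whose published
denominators differ from the group sizes — capillary density (3 of 22
events, 9 of 54 non-events unassessed) and FOI (6 of 22 and 10 of 54) —
because those denominators are forced by the printed
sensitivity/specificity/OR triples. The NC pattern is ordinal; events carry
no mass on "normal" (published sensitivity of any scleroderma pattern is
100%) and the early/active/late split defaults to uniform, a synthetic-only
choice the published table does not constrain. One integer seed drives the
whole cohort through deterministic per-feature substreams, so adding a
feature never perturbs the draws of the others.

A deliberate consequence of one simplification: features are drawn
**conditionally independently given the outcome**. Real SSc features are
positively correlated (a late NC pattern predicts reduced density; history
and present ulcers co-occur), which *reduces* the information a sum of
features carries. Synthetic cohorts therefore yield composite AUCs around
0.95, higher than the published 0.83, and the scaled-down replication checks
of score-level performance are qualitative (cutoff near 10, full score
usually beating the imaging-free score, IDI usually positive) rather than
numeric. Passing tests demonstrate that the *machinery* is correct and that
every per-feature quantity is recovered at the published value; they do not
certify real-data score-level performance, which would need the original
cohort. One cohort-level inconsistency in the source material is resolved in
favor of the feature table: the supplement's subtype counts (43 limited +
19 diffuse) disagree with the diffuse-feature sensitivity/specificity, which
imply 27 diffuse / 49 limited; the generator follows the feature table.

## Problem sizes in the test suite

Distribution-level checks run at sizes chosen to make their tolerances
meaningful: prevalence recovery and OR recovery use cohorts scaled 100x
(2200 events / 5400 non-events) over 25–50 seeds; AUC oracle equivalence
uses 1000 random instances of n <= 40; DeLong-vs-bootstrap uses n = 200 with
2000 bootstrap resamples; calibration uniformity uses 200 cohorts of
n = 500 probed by a Kolmogorov-Smirnov test. At the 100x scale the 10%
log-OR recovery tolerance corresponds to only ~2 standard errors for the
capillary-density feature (whose effective event denominator is ~1900 with
~100 expected feature-negative events), so its per-seed coverage is
expected near 96% — right at the asserted 95% bar; the suite reports this
check honestly rather than loosening it.

## Limitations

* The score's external validity is untested here by construction: the
  package reproduces the development study's arithmetic and provides the
  instrument, not new clinical evidence.
* The generator matches first-order (outcome-conditional marginal)
  structure only; no feature correlations, no drop-out process, no
  traumatic-vs-ischemic ulcer distinction.
* Scoring incomplete patients treats missing components as 0 points (with
  the count surfaced); the source study is silent on incomplete patients,
  and users with systematic missingness should treat such scores as lower
  bounds.
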