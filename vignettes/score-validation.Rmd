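---
title: "Validating the aneurysm-specific prediction score on multiple-aneurysm cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating the aneurysm-specific prediction score on multiple-aneurysm cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(miascore)
```

## The clinical problem

Roughly a third of patients with an intracranial aneurysm harbour several.
When such a patient presents with subarachnoid hemorrhage, the treating
team must decide which aneurysm bled before choosing what to clip or coil
first; picking the wrong lesion risks rebleeding. The hemorrhage pattern on
CT is often ambiguous, so morphology-based rules that rank a patient's
aneurysms are attractive.

The aneurysm-specific prediction score is such a rule: a linear score over
each aneurysm's CT-angiography morphology,

$$\mathrm{score} = A + B + C,$$

with $A = 0.0427 \times \text{maximum diameter (mm)}$, $B$ a location
coefficient (0 at the anterior communicating and anterior cerebral
arteries, $-0.0104$ at the posterior communicating artery, $-0.1831$ in the
posterior circulation, $-0.4055$ at the middle cerebral artery, $-0.5973$
at the internal carotid artery) and $C = 0.5387$ for irregular (lobulated
or blebbed) shape, else 0. Within a patient, the aneurysm with the maximum
score is predicted to be the ruptured one. The coefficients come from a
component-wise gradient-boosting fit in the score's derivation study; this
package applies and validates them, it does not refit them. They are data,
not code: `asps_coefficients()` accepts alternatives and
`read_coefficients()` loads them from YAML/JSON, but the defaults are the
published values and the test suite freezes them.

## The validation analysis

`asps_validate()` runs the full analysis on a validation cohort (one row
per aneurysm; exactly one ruptured aneurysm per patient, at least two
aneurysms each):

* per-aneurysm scores (`score_cohort()`), kept at full double precision and
  displayed to 5 decimals, the precision score tables print;
* the largest-score rule and its competitors (`predict_rupture()`): largest
  diameter (also a within-patient argmax), irregular shape, and the five
  location classifiers (aneurysm-level membership rules, with AcomA and AA
  merged for reporting as accuracy tables conventionally group them);
* aneurysm-level confusion counts and metrics per rule
  (`evaluate_all_rules()`). The argmax rules are per-patient classifiers —
  their "predicted" column totals the number of patients — while membership
  rules total the number of aneurysms carrying the feature; this is the
  only reading under which published count columns are internally
  consistent, and it is how the package tabulates them;
* the misidentified-patient list (`misidentified_patients()`): patients
  whose ruptured aneurysm is not in the predicted set;
* ROC/AUC for the score and each component (`roc_analysis()`), at the
  aneurysm level.

```{r fixture}
fit <- asps_validate(table3_fixture())
fit
```

The packaged fixture is, deliberately, the published table of
*misidentified* patients, so the largest-score rule misses all 17 rupture
sources on it — a useful end-to-end oracle because every recomputed score
must match a printed value to 5 decimals.

### Metric conventions

Five metrics are reported in percent: sensitivity, specificity, their
exact complements `beta = 100 - SEN` and `alpha = 100 - SPE`, and the
diagnostic accuracy `(tp + tn) / n`. The complement definitions are chosen
because they are the only ones that reproduce every row of the published
accuracy table from its own counts; the textbook false omission rate
`fn / (fn + tn)`, with which `beta` is sometimes confused, is exposed
separately as `false_omission_rate`. Display rounding is 1 decimal for
metrics, 3 for AUC, and p-values print with a `<0.001` floor; all objects
carry full precision.

### ROC and AUC

The AUC is computed as the tie-corrected concordance probability (ruptured
vs unruptured pairs; ties count one half), which equals the trapezoidal
area under the empirical ROC curve and is invariant under strictly
increasing transforms — the tests verify both identities to 1e-12 against
independent brute-force implementations. The published AUC table encodes
shape as 0/1 rather than 0/0.5387; the two encodings give identical AUC by
monotone invariance, and `roc_feature_values()` exposes the 0/1 encoding.
Confidence intervals default to DeLong's nonparametric method; a seeded
percentile bootstrap (2000 resamples by default) is the alternative. The
p-value for AUC = 0.5 uses the normal approximation on the same variance.
A constant predictor is returned as AUC 0.5 with `NA` interval rather than
an error, so degenerate synthetic cohorts summarise gracefully.

### Between-group comparisons

`cohort_summary()` tabulates morphology by rupture status and tests
differences: continuous variables by Student's t test when both groups pass
a Shapiro–Wilk check at 0.05 (the gate is configurable), otherwise by the
Mann–Whitney U test; binary rows by the chi-squared test without continuity
correction by default (the common statistical-package default for these
tables; `correct = TRUE` restores Yates). Inter-rater agreement for
categorical readings is available as `cohens_kappa()`.

## The synthetic cohort generator

`generate_cohort()` draws validation cohorts with the structure of the
134-patient, 290-aneurysm series the score was externally validated on:
115/16/3 patients with 2/3/4 aneurysms, exactly one ruptured aneurysm per
patient, ruptured diameters targeting 7.88 ± 3.02 mm and unruptured
5.02 ± 2.44 mm on the observed 1.8–20.7 mm range, irregular-shape
probabilities 0.709 and 0.231, and the observed location frequencies per
group. Design choices worth knowing:

* **Truncated normal diameters, moment-matched.** Only means, SDs and the
  range are reported, so the simplest compatible model is a normal
  truncated to the range, sampled by rejection. Naive truncation would
  inflate the means (to ≈8.04 and ≈5.47 mm), so the parent location is
  solved (by `uniroot` on the closed-form truncated mean) so that the
  *realised* mean equals the configured target; the realised SD sits
  slightly below nominal, a documented side effect of truncation.
* **Independence given rupture status.** Shape and location are sampled
  independently within each group because only marginals are reported.
  Real aneurysms correlate size, site and shape, so generated cohorts are
  a structural emulation, not a clone: passing tests show the pipeline
  arithmetic is right, not that the synthetic data reproduce every joint
  feature of real series.
* **AcomA/AA split 50/50** within their merged frequency, since separate
  frequencies are not published.
* **Reproducibility.** One integer seed; each patient draws from a
  substream derived deterministically from (seed, patient index), so early
  patients are unchanged when `n_patients` grows, and the global RNG state
  is restored on exit. With `deterministic_counts = TRUE` (default) the
  per-patient aneurysm counts follow the distribution's quantiles exactly
  (115/16/3 at the default size); sampling them is available for fully
  stochastic draws.

`generate_from_counts()` inverts an accuracy-table row: given a rule's
confusion counts it constructs a minimal cohort on which re-evaluation
reproduces them exactly (feasibility is checked — an argmax rule, for
instance, forces `fp == fn` because each misidentified patient contributes
exactly one of each). This is how published metric rows are exercised end
to end without the study's per-aneurysm supplementary data.

## Numerical and policy choices

* **Ties.** Published within-patient scores are distinct; ties arise only
  in degenerate data. Every argmax attainer is flagged; `tie_policy =
  "flag_all"` (default) predicts all of them, `"flag_none"` abstains. A
  tied ruptured aneurysm counts as identified only if predicted. Tie
  detection uses exact floating-point equality, which is the right notion
  here because equal morphology yields bitwise-equal scores.
* **Validation errors** are classed conditions (`miascore_parse_error`,
  `miascore_validation_error`, `miascore_config_error`) naming the
  offending row or patient; the command-line wrapper maps them to exit
  codes 2 and 3.
* **Problem sizes in the test suite.** Property checks run on 100 random
  ROC sets of up to 50 values, 1,000 seeded generator draws of 2–10
  patients (the structural invariants are size-independent), and one
  5,000-patient draw for moment recovery within three standard errors —
  sizes chosen to give the properties real bite while keeping the default
  suite quick to run.

## Limitations

* The full-cohort diagnostic metrics and AUCs of the validation study
  depend on its per-aneurysm supplementary data, which are not printed in
  the article; the package reproduces exactly the quantities that are
  printed (the misidentified-patient table, metric arithmetic from
  published counts) and checks the rest by construction and property.
* The score itself is applied, not recalibrated; its derivation (gradient
  boosting) and competing systems such as PHASES or UIATS are out of
  scope.
* Generated cohorts do not model reader measurement error, post-rupture
  morphology change, or dependence between size, site and shape.
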