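# miascore

Identifying the ruptured aneurysm in patients with multiple intracranial
aneurysms, using the **aneurysm-specific prediction score**.

About 30% of patients with an intracranial aneurysm have more than one.
When such a patient presents with subarachnoid hemorrhage, the bleeding
aneurysm must be identified before treatment — and the hemorrhage pattern
alone is often ambiguous. The aneurysm-specific prediction score ranks a
patient's aneurysms by a linear function of CT-angiography morphology:

```
score = A + B + C
A = 0.0427 × maximum diameter (mm)
B = 0 (AcomA, AA) | −0.0104 (PcomA) | −0.1831 (PC) | −0.4055 (MCA) | −0.5973 (ICA)
C = 0.5387 if irregular shape, else 0
```

Within each patient the highest-scoring aneurysm is predicted to be the
ruptured one. This package is for biostatisticians and clinical
researchers validating that rule: it computes the score, applies it and
the competing single-feature rules (largest diameter, irregular shape,
location), tabulates aneurysm-level diagnostic accuracy (sensitivity,
specificity, their complements, overall accuracy), runs ROC/AUC analysis
with DeLong or bootstrap confidence intervals, and generates seeded
synthetic multiple-aneurysm cohorts for end-to-end testing.

## Worked example

The package ships a fixture cohort: the 17 patients (38 aneurysms) of the
validation series in whom the score ranked an *unruptured* aneurysm
first. Validating on it exercises the whole pipeline against printed
values — every recomputed score matches the published 5-decimal column,
and all 17 rupture sources are, by construction, missed:

```r
library(miascore)
fit <- asps_validate(table3_fixture())
fit
#> Aneurysm-specific prediction score validation: 17 patients, 38 aneurysms
#>   largest-score rule: SEN 0.0%, SPE 19.0%, DA 10.5%
#>   ruptured aneurysm missed in 17 of 17 patients (100.0%)
#>   score AUC 0.357
```

(`SEN 0.0%` because none of the 17 ruptured aneurysms attains its
patient's maximum score — that is what makes these patients the
misidentified ones.) Scoring new patients:

```r
nd <- data.frame(patient_id = "q1", aneurysm_id = c("a1", "a2"),
                 diameter_mm = c(7.9, 3.0), location = c("PcomA", "ICA"),
                 shape = c("irregular", "regular"))
predict(fit, nd, type = "rupture")[, c("aneurysm_id", "score", "predicted_ruptured")]
#>   aneurysm_id    score predicted_ruptured
#> 1          a1  0.86563               TRUE
#> 2          a2 -0.46920              FALSE
```

The 7.9 mm irregular PcomA aneurysm scores 0.86563 (0.0427×7.9 − 0.0104 +
0.5387) and outranks the small regular ICA lesion, so it is the predicted
rupture source. On large synthetic cohorts with the validation study's
structure, the score rule dominates every single-feature rule:

```r
co <- generate_cohort(generator_config(n_patients = 2000, seed = 31))
tab <- evaluate_all_rules(co)
tab[tab$rule %in% c("diameter_largest", "shape_irregular", "score_largest"),
    c("rule", "sen", "spe", "da")]
#>               rule  sen  spe   da
#>   diameter_largest 78.5 81.5 80.1
#>    shape_irregular 71.7 76.6 74.3
#>      score_largest 84.6 86.8 85.8
```

`summary(fit)`, `plot(fit)` (ROC curves), `coef(fit)` and
`write_report(fit, dir)` (JSON + markdown) render the results; the
`inst/cli/mia` script exposes `score`, `evaluate` and `simulate`
subcommands for shell pipelines. See the vignette
(`vignettes/score-validation.Rmd`) for the model, conventions and
generator design.

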