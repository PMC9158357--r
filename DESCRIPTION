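Package: miascore
Title: Ruptured-Aneurysm Identification in Multiple Intracranial Aneurysms
    with the Aneurysm-Specific Prediction Score
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Validation toolkit for the aneurysm-specific prediction score,
    a linear score over maximum diameter, location and shape used to rank
    intracranial aneurysms within a patient and identify the ruptured lesion
    in patients with multiple aneurysms and subarachnoid hemorrhage.
    Provides aneurysm-level cohort input/output and validation, score
    computation, within-patient argmax and single-feature identification
    rules, diagnostic-accuracy metrics (sensitivity, specificity, their
    complements and overall accuracy), ROC/AUC analysis with DeLong or
    bootstrap confidence intervals, inter-rater agreement (Cohen's kappa),
    a seeded synthetic multiple-aneurysm cohort generator, and a small
    command-line front end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    jsonlite,
    pROC,
    stats,
    utils,
    yaml
Suggests:
    e1071,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
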