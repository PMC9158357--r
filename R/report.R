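#' Write machine- and human-readable validation reports
#'
#' Renders an [asps_validate()] result to `report.json` and `report.md`
#' in `dir`: the group-wise morphology table, the per-rule diagnostic
#' accuracy table, the AUC table and the misidentified-patient list.
#' Reports embed the coefficient values used, so runs with recalibrated
#' coefficients are self-describing. Display rounding follows clinical
#' convention: metrics to 1 decimal, AUC to 3, p-values to 3 with a
#' `<0.001` floor; the JSON carries full precision.
#'
#' @param validation an `asps_validation`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(validation, dir) {
  stopifnot(inherits(validation, "asps_validation"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cf <- validation$coefficients
  roc_tab <- lapply(validation$roc, function(r) {
    list(auc = r$auc, ci_low = r$ci_low, ci_high = r$ci_high,
         p_value = r$p_value, ci_method = r$ci_method)
  })
  payload <- list(
    coefficients = list(size_coeff = cf$size_coeff,
                        location_coeffs = as.list(cf$location_coeffs),
                        irregular_bonus = cf$irregular_bonus),
    tie_policy = validation$tie_policy,
    n_patients = length(unique(validation$cohort$patient_id)),
    n_aneurysms = nrow(validation$cohort),
    morphology = list(
      n = as.list(validation$summary$n),
      continuous = validation$summary$continuous,
      categorical = validation$summary$categorical
    ),
    rules = validation$rules,
    roc = roc_tab,
    misidentified = validation$misidentified
  )
  json_path <- file.path(dir, "report.json")
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")

  md_path <- file.path(dir, "report.md")
  con <- file(md_path, "w", encoding = "UTF-8")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("# Aneurysm-specific prediction score validation report")
  w("")
  w("Coefficients: A = %.4f x diameter (mm); B = %s; C = +%.4f if irregular.",
    cf$size_coeff,
    paste(sprintf("%s %.4f", names(cf$location_coeffs), cf$location_coeffs),
          collapse = ", "),
    cf$irregular_bonus)
  w("")
  w("Cohort: %d patients, %d aneurysms (%d ruptured, %d unruptured).",
    payload$n_patients, payload$n_aneurysms,
    validation$summary$n["ruptured"], validation$summary$n["unruptured"])
  w("")
  w("## Morphology by rupture status")
  w("")
  w("| Variable | Unruptured | Ruptured | p | Test |")
  w("|---|---|---|---|---|")
  cc <- validation$summary$continuous
  for (i in seq_len(nrow(cc))) {
    w("| %s | %.2f +/- %.2f | %.2f +/- %.2f | %s | %s |",
      cc$variable[i], cc$mean_unruptured[i], cc$sd_unruptured[i],
      cc$mean_ruptured[i], cc$sd_ruptured[i],
      sub("^= ", "", format_p(cc$p[i])), cc$test[i])
  }
  ct <- validation$summary$categorical
  for (i in seq_len(nrow(ct))) {
    w("| %s: %s | %d (%.1f%%) | %d (%.1f%%) | %s | chi-squared |",
      ct$variable[i], ct$level[i], ct$n_unruptured[i], ct$pct_unruptured[i],
      ct$n_ruptured[i], ct$pct_ruptured[i], sub("^= ", "", format_p(ct$p[i])))
  }
  w("")
  w("## Diagnostic accuracy by identification rule")
  w("")
  w("| Rule | TP | FP | FN | TN | SEN%% | SPE%% | beta%% | alpha%% | DA%% |")
  w("|---|---|---|---|---|---|---|---|---|---|")
  rt <- validation$rules
  for (i in seq_len(nrow(rt))) {
    w("| %s | %d | %d | %d | %d | %.1f | %.1f | %.1f | %.1f | %.1f |",
      rt$rule[i], rt$tp[i], rt$fp[i], rt$fn[i], rt$tn[i],
      rt$sen[i], rt$spe[i], rt$beta[i], rt$alpha[i], rt$da[i])
  }
  w("")
  w("## Area under the ROC curve (aneurysm level)")
  w("")
  w("| Feature | AUC | 95%% CI | p |")
  w("|---|---|---|---|")
  for (nm in names(validation$roc)) {
    r <- validation$roc[[nm]]
    ci <- if (is.na(r$ci_low)) "-" else sprintf("%.3f-%.3f", r$ci_low, r$ci_high)
    w("| %s | %.3f | %s | %s |", nm, r$auc, ci,
      sub("^= ", "", format_p(r$p_value)))
  }
  w("")
  w("## Patients with a misidentified rupture source (largest-score rule)")
  w("")
  w("%d of %d patients: %s", validation$misidentified$count,
    payload$n_patients,
    if (validation$misidentified$count) {
      paste(validation$misidentified$patient_ids, collapse = ", ")
    } else "none")
  invisible(c(json = json_path, markdown = md_path))
}
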