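#' Validate the aneurysm-specific prediction score on a cohort
#'
#' The central entry point: runs the full within-patient identification
#' analysis on a validation cohort and returns one object holding every
#' result. Concretely it (i) scores all aneurysms, (ii) applies the
#' largest-score rule and the competing single-feature rules
#' (largest diameter, irregular shape, the five location classifiers),
#' (iii) tabulates confusion counts and diagnostic metrics per rule,
#' (iv) lists the patients whose ruptured aneurysm the score missed, and
#' (v) computes aneurysm-level ROC/AUC for the score and its three
#' components, plus a group-wise morphology summary.
#'
#' @param data a validation-mode `mia_cohort`, or a data frame / CSV path
#'   coercible to one (one row per aneurysm with patient_id, aneurysm_id,
#'   diameter_mm, location, shape, ruptured).
#' @param coefficients an [asps_coefficients()] object.
#' @param tie_policy passed to [predict_rupture()].
#' @param ci_method,boot_n,seed passed to [roc_analysis()].
#' @return An object of class `asps_validation` with components `cohort`
#'   (scored), `coefficients`, `rules` (the per-rule metric table),
#'   `misidentified`, `roc` (list over A_size/B_location/C_shape/score)
#'   and `summary` (group-wise morphology).
#' @examples
#' fit <- asps_validate(table3_fixture())
#' fit
#' coef(fit)
#' @export
asps_validate <- function(data, coefficients = asps_coefficients(),
                          tie_policy = c("flag_all", "flag_none"),
                          ci_method = c("delong", "bootstrap"),
                          boot_n = 2000, seed = NULL) {
  tie_policy <- match.arg(tie_policy)
  ci_method <- match.arg(ci_method)
  cohort <- if (inherits(data, "mia_cohort")) {
    data
  } else if (is.character(data) && length(data) == 1) {
    read_cohort(data, mode = "validation")
  } else {
    as_cohort(data, mode = "validation")
  }
  if (cohort_mode(cohort) != "validation") {
    cohort_error("asps_validate requires a validation-mode cohort",
                 "miascore_validation_error")
  }
  structure(list(
    cohort = score_cohort(cohort, coefficients),
    coefficients = coefficients,
    tie_policy = tie_policy,
    rules = evaluate_all_rules(cohort, coefficients, tie_policy),
    misidentified = misidentified_patients(
      cohort, prediction_rule("score_largest"), coefficients, tie_policy
    ),
    roc = roc_all_features(cohort, coefficients, ci_method = ci_method,
                           boot_n = boot_n, seed = seed),
    summary = cohort_summary(cohort, coefficients)
  ), class = "asps_validation")
}

#' @export
print.asps_validation <- function(x, ...) {
  n_pat <- length(unique(x$cohort$patient_id))
  score_row <- x$rules[x$rules$rule == "score_largest", ]
  cat(sprintf("Aneurysm-specific prediction score validation: %d patients, %d aneurysms\n",
              n_pat, nrow(x$cohort)))
  cat(sprintf("  largest-score rule: SEN %.1f%%, SPE %.1f%%, DA %.1f%%\n",
              score_row$sen, score_row$spe, score_row$da))
  cat(sprintf("  ruptured aneurysm missed in %d of %d patients (%.1f%%)\n",
              x$misidentified$count, n_pat,
              100 * x$misidentified$count / n_pat))
  cat(sprintf("  score AUC %.3f\n", x$roc$score$auc))
  invisible(x)
}

#' @export
summary.asps_validation <- function(object, ...) {
  structure(object, class = c("summary.asps_validation", class(object)))
}

#' @export
print.summary.asps_validation <- function(x, ...) {
  print.asps_validation(x)
  cat("\nGroup-wise morphology:\n")
  print(x$summary)
  cat("\nDiagnostic accuracy by rule:\n")
  tab <- x$rules
  tab[c("sen", "spe", "beta", "alpha", "da")] <-
    lapply(tab[c("sen", "spe", "beta", "alpha", "da")], round, 1)
  print(tab, row.names = FALSE)
  cat("\nAUC (aneurysm level):\n")
  for (nm in names(x$roc)) {
    cat(sprintf("  %-10s ", nm)); print(x$roc[[nm]])
  }
  invisible(x)
}

#' @export
coef.asps_validation <- function(object, ...) {
  cf <- object$coefficients
  c(size = cf$size_coeff, setNames(as.numeric(cf$location_coeffs),
                                   paste0("location.", names(cf$location_coeffs))),
    irregular = cf$irregular_bonus)
}

#' Score new aneurysms or predict rupture sources with a fitted validation
#'
#' `type = "score"` returns the newdata cohort with score columns appended;
#' `type = "rupture"` additionally applies the largest-score rule and
#' returns a per-aneurysm predicted flag column.
#'
#' @param object an `asps_validation`.
#' @param newdata a cohort, data frame or CSV path; defaults to the
#'   validated cohort itself.
#' @param type `"score"` or `"rupture"`.
#' @param ... unused.
#' @export
predict.asps_validation <- function(object, newdata = NULL,
                                    type = c("score", "rupture"), ...) {
  type <- match.arg(type)
  cohort <- if (is.null(newdata)) {
    object$cohort
  } else if (inherits(newdata, "mia_cohort")) {
    newdata
  } else if (is.character(newdata) && length(newdata) == 1) {
    read_cohort(newdata, mode = "prediction", allow_single = TRUE)
  } else {
    as_cohort(newdata, mode = "prediction", allow_single = TRUE)
  }
  sc <- score_cohort(cohort, object$coefficients)
  if (type == "rupture") {
    pr <- predict_rupture(cohort, prediction_rule("score_largest"),
                          object$coefficients, object$tie_policy)
    sc$predicted_ruptured <- pr$predicted
  }
  sc
}

#' Plot ROC curves of a validated score
#'
#' Draws the aneurysm-level ROC curves of the score and its three
#' components with their AUCs in the legend.
#'
#' @param x an `asps_validation`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.asps_validation <- function(x, ...) {
  cols <- c(A_size = "#1b9e77", B_location = "#d95f02",
            C_shape = "#7570b3", score = "black")
  graphics::plot(c(0, 1), c(0, 1), type = "l", lty = 3, col = "grey",
                 xlab = "False-positive rate (1 - specificity)",
                 ylab = "True-positive rate (sensitivity)", ...)
  for (nm in names(x$roc)) {
    pts <- x$roc[[nm]]$points
    graphics::lines(pts$fpr, pts$tpr, col = cols[nm],
                    lwd = if (nm == "score") 2 else 1)
  }
  graphics::legend("bottomright", bty = "n",
                   legend = sprintf("%s (AUC %.3f)", names(x$roc),
                                    vapply(x$roc, `[[`, numeric(1), "auc")),
                   col = cols[names(x$roc)], lwd = c(1, 1, 1, 2))
  invisible(x)
}

#' Simulate cohorts matched to a validation's structure
#'
#' Draws `nsim` synthetic validation cohorts from the generator with the
#' same number of patients as the validated cohort and the default
#' study-structure parameters; simulation `i` uses seed `seed + i - 1`.
#'
#' @param object an `asps_validation`.
#' @param nsim number of cohorts.
#' @param seed base integer seed.
#' @param ... unused.
#' @return List of `mia_cohort`s (a single cohort if `nsim = 1`).
#' @export
simulate.asps_validation <- function(object, nsim = 1, seed = 1L, ...) {
  n_pat <- length(unique(object$cohort$patient_id))
  sims <- lapply(seq_len(nsim), function(i) {
    generate_cohort(generator_config(n_patients = n_pat, seed = seed + i - 1L))
  })
  if (nsim == 1) sims[[1]] else sims
}
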