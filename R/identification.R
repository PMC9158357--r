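#' Identification rules for the ruptured aneurysm
#'
#' Four rule families predict which aneurysm(s) of a patient ruptured:
#' \describe{
#'   \item{`score_largest`}{within each patient, the aneurysm with the
#'     maximum prediction score is predicted ruptured (the score's intended
#'     use).}
#'   \item{`diameter_largest`}{the aneurysm with the maximum diameter.}
#'   \item{`shape_irregular`}{every irregular aneurysm is predicted
#'     ruptured, regardless of patient structure.}
#'   \item{`location_is`}{every aneurysm at `location_target` is predicted
#'     ruptured. The target `"AcomA+AA"` merges the two anterior labels,
#'     matching how published accuracy tables group them.}
#' }
#' The argmax rules are per-patient ranking classifiers (their "predicted"
#' totals count patients); the membership rules are aneurysm-level
#' classifiers (totals count aneurysms at the feature). This distinction is
#' what makes the published count columns add up: the diameter row totals
#' the number of patients while each location row totals the number of
#' aneurysms at that site.
#'
#' @param kind rule family.
#' @param location_target required iff `kind = "location_is"`: one of PC,
#'   AcomA, AA, PcomA, MCA, ICA or the merged `"AcomA+AA"`.
#' @return A `prediction_rule` object.
#' @examples
#' prediction_rule("score_largest")
#' prediction_rule("location_is", "AcomA+AA")
#' @export
prediction_rule <- function(kind = c("score_largest", "diameter_largest",
                                     "shape_irregular", "location_is"),
                            location_target = NULL) {
  kind <- match.arg(kind)
  if (kind == "location_is") {
    if (is.null(location_target)) {
      cohort_error("location_is rule requires a location_target",
                   "miascore_config_error")
    }
    valid <- c(LOCATION_LEVELS, "AcomA+AA")
    if (!location_target %in% valid) {
      cohort_error(
        sprintf("unknown location_target '%s'", location_target),
        "miascore_config_error"
      )
    }
  } else if (!is.null(location_target)) {
    cohort_error("location_target is only meaningful for location_is rules",
                 "miascore_config_error")
  }
  structure(list(kind = kind, location_target = location_target),
            class = "prediction_rule")
}

#' @export
print.prediction_rule <- function(x, ...) {
  cat("<prediction_rule>", rule_label(x), "\n")
  invisible(x)
}

rule_label <- function(rule) {
  if (rule$kind == "location_is") {
    paste0("location_", gsub("\\+", "_", rule$location_target))
  } else {
    rule$kind
  }
}

#' Predict the ruptured aneurysm under an identification rule
#'
#' Applies a [prediction_rule()] to a cohort. For the argmax rules every
#' aneurysm attaining the within-patient maximum is in the predicted set;
#' a patient with more than one attainer has `tie_flag = TRUE` and the tie
#' policy decides whether the tied aneurysms are predicted (`"flag_all"`,
#' the default — conservative and explicit) or abstained from
#' (`"flag_none"`). Published within-patient scores are all distinct, so
#' ties only arise in degenerate or synthetic data. Membership rules never
#' tie.
#'
#' @param cohort a `mia_cohort` (validation or prediction mode).
#' @param rule a [prediction_rule()].
#' @param coefficients an [asps_coefficients()] object (used by
#'   `score_largest`).
#' @param tie_policy `"flag_all"` or `"flag_none"`.
#' @return A `prediction_result`: list with `predicted` (logical, one entry
#'   per aneurysm in cohort row order), `per_patient` (named list of
#'   predicted aneurysm ids), `tie_flag` (named logical per patient), plus
#'   the rule and cohort identity used.
#' @examples
#' pr <- predict_rupture(table3_fixture(), prediction_rule("score_largest"))
#' sum(pr$predicted)  # one prediction per patient, 17 in all
#' @export
predict_rupture <- function(cohort, rule = prediction_rule("score_largest"),
                            coefficients = asps_coefficients(),
                            tie_policy = c("flag_all", "flag_none")) {
  tie_policy <- match.arg(tie_policy)
  if (!inherits(rule, "prediction_rule")) rule <- prediction_rule(rule)
  if (!inherits(cohort, "mia_cohort")) {
    cohort <- as_cohort(cohort, mode = "prediction", allow_single = TRUE)
  }
  n <- nrow(cohort)
  predicted <- logical(n)
  pids <- unique(cohort$patient_id)
  tie_flag <- setNames(rep(FALSE, length(pids)), pids)
  per_patient <- setNames(vector("list", length(pids)), pids)

  if (rule$kind %in% c("score_largest", "diameter_largest")) {
    key <- if (rule$kind == "score_largest") {
      score_cohort(cohort, coefficients)$score
    } else {
      cohort$diameter_mm
    }
    for (pid in pids) {
      idx <- which(cohort$patient_id == pid)
      attain <- idx[key[idx] == max(key[idx])]
      tie <- length(attain) > 1
      tie_flag[pid] <- tie
      if (tie && tie_policy == "flag_none") attain <- integer()
      predicted[attain] <- TRUE
      per_patient[[pid]] <- cohort$aneurysm_id[attain]
    }
  } else {
    member <- if (rule$kind == "shape_irregular") {
      cohort$shape == "irregular"
    } else if (identical(rule$location_target, "AcomA+AA")) {
      cohort$location %in% c("AcomA", "AA")
    } else {
      cohort$location == rule$location_target
    }
    predicted <- as.logical(member)
    for (pid in pids) {
      idx <- which(cohort$patient_id == pid)
      per_patient[[pid]] <- cohort$aneurysm_id[idx][predicted[idx]]
    }
  }

  structure(list(
    predicted = predicted,
    per_patient = per_patient,
    tie_flag = tie_flag,
    rule = rule,
    tie_policy = tie_policy,
    cohort_ids = paste(cohort$patient_id, cohort$aneurysm_id, sep = "\r")
  ), class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf("<prediction_result> rule %s: %d aneurysm(s) predicted ruptured in %d patient(s); %d tie(s)\n",
              rule_label(x$rule), sum(x$predicted), length(x$per_patient),
              sum(x$tie_flag)))
  invisible(x)
}

#' Patients whose ruptured aneurysm the rule missed
#'
#' A patient is misidentified when their ruptured aneurysm is not in the
#' rule's predicted set (a ruptured aneurysm tied at the maximum counts as
#' identified only if the tie policy put it in the predicted set).
#'
#' @inheritParams predict_rupture
#' @return List with `count` and `patient_ids`.
#' @examples
#' misidentified_patients(table3_fixture())$count  # 17
#' @export
misidentified_patients <- function(cohort,
                                   rule = prediction_rule("score_largest"),
                                   coefficients = asps_coefficients(),
                                   tie_policy = c("flag_all", "flag_none")) {
  if (cohort_mode(cohort) != "validation") {
    cohort_error("misidentified_patients requires a validation-mode cohort (rupture labels)",
                 "miascore_validation_error")
  }
  pr <- predict_rupture(cohort, rule, coefficients, tie_policy)
  pids <- unique(cohort$patient_id)
  missed <- vapply(pids, function(pid) {
    idx <- which(cohort$patient_id == pid)
    rupt_id <- cohort$aneurysm_id[idx][cohort$ruptured[idx]]
    !rupt_id %in% pr$per_patient[[pid]]
  }, logical(1))
  list(count = sum(missed), patient_ids = pids[missed])
}
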