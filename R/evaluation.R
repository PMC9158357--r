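#' Aneurysm-level confusion counts for an identification rule
#'
#' Cross-tabulates true rupture status against the rule's predicted flag
#' over every aneurysm of a validation cohort: `tp` ruptured & predicted,
#' `fp` unruptured & predicted, `fn` ruptured & missed, `tn` unruptured &
#' not predicted. The four counts always sum to the number of aneurysms.
#'
#' @param cohort the validation-mode `mia_cohort` the prediction was made on.
#' @param prediction a `prediction_result` from [predict_rupture()] on the
#'   same cohort (an id mismatch is an error).
#' @return A `confusion_counts` object (list with tp/fp/fn/tn).
#' @export
confusion_counts <- function(cohort, prediction) {
  if (cohort_mode(cohort) != "validation") {
    cohort_error("confusion counts require a validation-mode cohort",
                 "miascore_validation_error")
  }
  ids <- paste(cohort$patient_id, cohort$aneurysm_id, sep = "\r")
  if (!identical(ids, prediction$cohort_ids)) {
    cohort_error("prediction was computed on a different cohort (aneurysm ids differ)",
                 "miascore_validation_error")
  }
  p <- prediction$predicted
  r <- cohort$ruptured
  structure(list(
    tp = sum(r & p), fp = sum(!r & p),
    fn = sum(r & !p), tn = sum(!r & !p)
  ), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> tp=%d fp=%d fn=%d tn=%d (n=%d)\n",
              x$tp, x$fp, x$fn, x$tn, x$tp + x$fp + x$fn + x$tn))
  invisible(x)
}

#' Diagnostic-accuracy metrics, in percent
#'
#' The five headline metrics of a rupture-identification rule:
#' sensitivity `sen = 100*tp/(tp+fn)`, specificity `spe = 100*tn/(fp+tn)`,
#' `beta = 100 - sen`, `alpha = 100 - spe`, and diagnostic accuracy
#' `da = 100*(tp+tn)/n`. `beta` and `alpha` are defined as the exact
#' complements of sensitivity and specificity — that is the only reading
#' under which every published accuracy row is internally consistent, even
#' though those columns are sometimes labelled "false omission rate" and
#' "diagnostic error rate". The textbook false omission rate
#' `100*fn/(fn+tn)` is returned separately as `false_omission_rate` to
#' avoid the ambiguity.
#'
#' Values are kept at full precision; `print` rounds to 1 decimal.
#'
#' @param counts a [confusion_counts()] object (or list with tp/fp/fn/tn).
#' @return A `diagnostic_metrics` object with fields `sen`, `spe`, `beta`,
#'   `alpha`, `da`, `false_omission_rate` and the input counts.
#' @examples
#' m <- diagnostic_metrics(list(tp = 117, fp = 17, fn = 17, tn = 139))
#' round(m$sen, 1)  # 87.3
#' @export
diagnostic_metrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn; tn <- counts$tn
  stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0)
  if (tp + fn == 0 || fp + tn == 0) {
    cohort_error("metrics undefined: one outcome class is empty",
                 "miascore_metric_error")
  }
  n <- tp + fp + fn + tn
  sen <- 100 * tp / (tp + fn)
  spe <- 100 * tn / (fp + tn)
  structure(list(
    sen = sen, spe = spe, beta = 100 - sen, alpha = 100 - spe,
    da = 100 * (tp + tn) / n,
    false_omission_rate = if (fn + tn > 0) 100 * fn / (fn + tn) else NA_real_,
    counts = list(tp = tp, fp = fp, fn = fn, tn = tn)
  ), class = "diagnostic_metrics")
}

#' @export
print.diagnostic_metrics <- function(x, ...) {
  cat(sprintf("SEN %.1f%%  SPE %.1f%%  beta %.1f%%  alpha %.1f%%  DA %.1f%%\n",
              x$sen, x$spe, x$beta, x$alpha, x$da))
  invisible(x)
}

#' Evaluate every identification rule on a cohort
#'
#' Runs the eight standard rules — largest diameter, irregular shape, the
#' five location classifiers (PC, merged AcomA+AA, PcomA, MCA, ICA) and the
#' largest prediction score — and tabulates confusion counts and metrics
#' for each, one row per rule.
#'
#' @inheritParams predict_rupture
#' @return Data frame with columns `rule`, `tp`, `fp`, `fn`, `tn`, `sen`,
#'   `spe`, `beta`, `alpha`, `da`, `ties` (number of tied patients under
#'   argmax rules).
#' @examples
#' evaluate_all_rules(table3_fixture())
#' @export
evaluate_all_rules <- function(cohort, coefficients = asps_coefficients(),
                               tie_policy = c("flag_all", "flag_none")) {
  tie_policy <- match.arg(tie_policy)
  rules <- list(
    prediction_rule("diameter_largest"),
    prediction_rule("shape_irregular"),
    prediction_rule("location_is", "PC"),
    prediction_rule("location_is", "AcomA+AA"),
    prediction_rule("location_is", "PcomA"),
    prediction_rule("location_is", "MCA"),
    prediction_rule("location_is", "ICA"),
    prediction_rule("score_largest")
  )
  rows <- lapply(rules, function(rule) {
    pr <- predict_rupture(cohort, rule, coefficients, tie_policy)
    cc <- confusion_counts(cohort, pr)
    m <- diagnostic_metrics(cc)
    data.frame(
      rule = rule_label(rule), tp = cc$tp, fp = cc$fp, fn = cc$fn, tn = cc$tn,
      sen = m$sen, spe = m$spe, beta = m$beta, alpha = m$alpha, da = m$da,
      ties = sum(pr$tie_flag), stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Group-wise morphology summary with between-group tests
#'
#' Summarises a validation cohort the way clinical series are tabulated:
#' per rupture group, mean +/- SD maximum diameter and prediction score,
#' and counts/percentages for shape and location (AcomA and AA merged for
#' reporting). Continuous rows are compared with Student's t test when both
#' groups pass a Shapiro-Wilk normality check at `normality_alpha`, else
#' with the Mann-Whitney U test; categorical rows with the chi-squared test
#' (no continuity correction by default, the usual statistical-package
#' default; expected-count warnings are suppressed but the statistic is
#' unchanged).
#'
#' @param cohort a validation-mode `mia_cohort`.
#' @param coefficients an [asps_coefficients()] object.
#' @param normality_alpha significance level of the Shapiro-Wilk gate.
#' @param correct logical; Yates continuity correction for 2x2 chi-squared.
#' @return A `cohort_summary` list with elements `n` (group sizes),
#'   `continuous` (data frame: variable, group means/SDs, p, test used) and
#'   `categorical` (data frame: variable, level, counts, percents, p).
#' @export
cohort_summary <- function(cohort, coefficients = asps_coefficients(),
                           normality_alpha = 0.05, correct = FALSE) {
  if (cohort_mode(cohort) != "validation") {
    cohort_error("cohort_summary requires a validation-mode cohort",
                 "miascore_validation_error")
  }
  sc <- score_cohort(cohort, coefficients)
  g <- factor(ifelse(sc$ruptured, "ruptured", "unruptured"),
              levels = c("unruptured", "ruptured"))

  cont_row <- function(name, x) {
    xs <- split(x, g)
    normal <- all(vapply(xs, function(v) {
      if (length(unique(v)) < 3 || length(v) < 3 || length(v) > 5000) {
        return(FALSE)
      }
      stats::shapiro.test(v)$p.value > normality_alpha
    }, logical(1)))
    test <- if (normal) "t" else "mann-whitney"
    p <- if (normal) {
      stats::t.test(x ~ g)$p.value
    } else {
      suppressWarnings(stats::wilcox.test(x ~ g)$p.value)
    }
    data.frame(
      variable = name,
      mean_unruptured = mean(xs$unruptured), sd_unruptured = stats::sd(xs$unruptured),
      mean_ruptured = mean(xs$ruptured), sd_ruptured = stats::sd(xs$ruptured),
      p = p, test = test, stringsAsFactors = FALSE
    )
  }

  cat_p <- function(member) {
    tab <- table(member, g)
    if (nrow(tab) < 2 || any(rowSums(tab) == 0)) return(NA_real_)
    suppressWarnings(stats::chisq.test(tab, correct = correct)$p.value)
  }

  loc_merged <- as.character(sc$location)
  loc_merged[loc_merged %in% c("AcomA", "AA")] <- "AcomA+AA"
  loc_levels <- c("PC", "AcomA+AA", "PcomA", "MCA", "ICA")
  cat_rows <- rbind(
    data.frame(variable = "shape", level = "irregular",
               n_unruptured = sum(sc$shape == "irregular" & !sc$ruptured),
               n_ruptured = sum(sc$shape == "irregular" & sc$ruptured),
               p = cat_p(sc$shape == "irregular"), stringsAsFactors = FALSE),
    do.call(rbind, lapply(loc_levels, function(lv) {
      data.frame(variable = "location", level = lv,
                 n_unruptured = sum(loc_merged == lv & !sc$ruptured),
                 n_ruptured = sum(loc_merged == lv & sc$ruptured),
                 p = cat_p(loc_merged == lv), stringsAsFactors = FALSE)
    }))
  )
  n_un <- sum(!sc$ruptured); n_ru <- sum(sc$ruptured)
  cat_rows$pct_unruptured <- 100 * cat_rows$n_unruptured / n_un
  cat_rows$pct_ruptured <- 100 * cat_rows$n_ruptured / n_ru

  structure(list(
    n = c(unruptured = n_un, ruptured = n_ru),
    continuous = rbind(cont_row("diameter_mm", sc$diameter_mm),
                       cont_row("score", sc$score)),
    categorical = cat_rows
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort: %d unruptured vs %d ruptured aneurysms\n",
              x$n["unruptured"], x$n["ruptured"]))
  cc <- x$continuous
  for (i in seq_len(nrow(cc))) {
    cat(sprintf("  %-12s %.2f +/- %.2f vs %.2f +/- %.2f  (p %s, %s)\n",
                cc$variable[i], cc$mean_unruptured[i], cc$sd_unruptured[i],
                cc$mean_ruptured[i], cc$sd_ruptured[i],
                format_p(cc$p[i]), cc$test[i]))
  }
  ct <- x$categorical
  for (i in seq_len(nrow(ct))) {
    cat(sprintf("  %s=%-9s %d (%.1f%%) vs %d (%.1f%%)  (p %s)\n",
                ct$variable[i], ct$level[i],
                ct$n_unruptured[i], ct$pct_unruptured[i],
                ct$n_ruptured[i], ct$pct_ruptured[i], format_p(ct$p[i])))
  }
  invisible(x)
}

format_p <- function(p) {
  if (is.na(p)) "NA" else if (p < 0.001) "<0.001" else sprintf("= %.3f", p)
}

#' Cohen's kappa for two raters
#'
#' Chance-corrected agreement `(po - pe) / (1 - pe)` between two equal-length
#' categorical sequences (e.g. two readers' shape or location calls).
#' Returns 1 for perfect agreement whenever chance agreement is below 1.
#'
#' @param ratings_a,ratings_b equal-length vectors of categorical ratings.
#' @return Kappa as a single number.
#' @examples
#' cohens_kappa(c("r", "r", "i"), c("r", "r", "i"))  # 1
#' @export
cohens_kappa <- function(ratings_a, ratings_b) {
  if (length(ratings_a) != length(ratings_b) || length(ratings_a) < 1) {
    cohort_error("ratings must be equal-length, non-empty sequences",
                 "miascore_validation_error")
  }
  lev <- union(unique(as.character(ratings_a)), unique(as.character(ratings_b)))
  a <- factor(as.character(ratings_a), levels = lev)
  b <- factor(as.character(ratings_b), levels = lev)
  tab <- table(a, b)
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (pe >= 1) return(if (po == 1) 1 else NA_real_)
  (po - pe) / (1 - pe)
}
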