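#' ROC curve and AUC for a continuous rupture predictor
#'
#' Aneurysm-level receiver operating characteristic analysis. The AUC is
#' computed as the tie-corrected concordance probability: over all
#' ruptured x unruptured pairs, a pair where the ruptured aneurysm has the
#' larger value counts 1, an exact tie counts 1/2, divided by
#' `n_ruptured * n_unruptured`. This equals the trapezoidal area under the
#' empirical ROC curve and is invariant under strictly increasing
#' transforms of the predictor.
#'
#' The 95% confidence interval uses DeLong's nonparametric variance by
#' default, or a seeded percentile bootstrap (`boot_n` resamples). The
#' p-value tests AUC = 0.5 with the normal approximation on the same
#' variance. Degenerate inputs (a constant predictor) return AUC 0.5 with
#' `NA` interval and p-value.
#'
#' @param values numeric predictor values, one per aneurysm.
#' @param ruptured logical rupture status, same length.
#' @param ci_method `"delong"` or `"bootstrap"`.
#' @param boot_n bootstrap resamples when `ci_method = "bootstrap"`.
#' @param seed optional integer seed for the bootstrap (the global RNG
#'   state is restored afterwards).
#' @param conf_level confidence level of the interval.
#' @return A `roc_result`: list with `points` (data frame of threshold,
#'   fpr, tpr, from (0,0) to (1,1)), `auc`, `ci_low`, `ci_high`,
#'   `p_value`, `ci_method`, and the class sizes.
#' @examples
#' fx <- score_cohort(table3_fixture())
#' roc_analysis(fx$score, fx$ruptured)
#' @export
roc_analysis <- function(values, ruptured, ci_method = c("delong", "bootstrap"),
                         boot_n = 2000, seed = NULL, conf_level = 0.95) {
  ci_method <- match.arg(ci_method)
  stopifnot(length(values) == length(ruptured))
  ruptured <- as.logical(ruptured)
  if (anyNA(values) || anyNA(ruptured)) {
    cohort_error("ROC input contains missing values", "miascore_validation_error")
  }
  n1 <- sum(ruptured); n0 <- sum(!ruptured)
  if (n1 == 0 || n0 == 0) {
    cohort_error("ROC requires both ruptured and unruptured aneurysms",
                 "miascore_validation_error")
  }

  # tie-corrected concordance via midranks (Mann-Whitney identity)
  r <- rank(values)
  auc <- (sum(r[ruptured]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  # operating points: classify value >= threshold as predicted-ruptured
  thr <- sort(unique(values), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(ruptured & values >= t) / n1, numeric(1))
  fpr <- vapply(thr, function(t) sum(!ruptured & values >= t) / n0, numeric(1))
  points <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))

  degenerate <- length(unique(values)) < 2
  ci <- c(NA_real_, NA_real_)
  p_value <- NA_real_
  if (!degenerate) {
    proc <- pROC::roc(response = ruptured, predictor = values,
                      levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
    if (ci_method == "delong") {
      ci_obj <- suppressWarnings(
        pROC::ci.auc(proc, method = "delong", conf.level = conf_level)
      )
      ci <- as.numeric(ci_obj)[c(1, 3)]
      v <- suppressWarnings(as.numeric(pROC::var(proc, method = "delong")))
      p_value <- if (!is.na(v) && v > 0) {
        2 * stats::pnorm(-abs(auc - 0.5) / sqrt(v))
      } else NA_real_
    } else {
      p_value_from <- function(lo, hi) {
        se <- (hi - lo) / (2 * stats::qnorm(1 - (1 - conf_level) / 2))
        if (se > 0) 2 * stats::pnorm(-abs(auc - 0.5) / se) else NA_real_
      }
      run_boot <- function() {
        ci_obj <- suppressWarnings(
          pROC::ci.auc(proc, method = "bootstrap", boot.n = boot_n,
                       conf.level = conf_level, progress = "none")
        )
        as.numeric(ci_obj)[c(1, 3)]
      }
      if (!is.null(seed)) {
        old <- if (exists(".Random.seed", envir = globalenv())) {
          get(".Random.seed", envir = globalenv())
        }
        on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
        set.seed(seed)
      }
      ci <- run_boot()
      p_value <- p_value_from(ci[1], ci[2])
    }
  }

  structure(list(
    points = points, auc = auc, ci_low = ci[1], ci_high = ci[2],
    p_value = p_value, ci_method = ci_method, conf_level = conf_level,
    n_ruptured = n1, n_unruptured = n0
  ), class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  ci <- if (is.na(x$ci_low)) "CI not available" else {
    sprintf("%.0f%% CI %.3f-%.3f (%s)", 100 * x$conf_level, x$ci_low,
            x$ci_high, x$ci_method)
  }
  p <- if (is.na(x$p_value)) "" else sprintf(", p %s", format_p(x$p_value))
  cat(sprintf("AUC %.3f, %s%s  [%d ruptured vs %d unruptured]\n",
              x$auc, ci, p, x$n_ruptured, x$n_unruptured))
  invisible(x)
}

#' AUC table for the score and its three components
#'
#' Runs [roc_analysis()] on the four standard feature encodings (`A_size`,
#' `B_location`, `C_shape` with irregular = 1, and the full `score`) over
#' all aneurysms of a validation cohort.
#'
#' @inheritParams cohort_summary
#' @inheritParams roc_analysis
#' @return Named list of `roc_result` objects
#'   (`A_size`, `B_location`, `C_shape`, `score`).
#' @export
roc_all_features <- function(cohort, coefficients = asps_coefficients(),
                             ci_method = c("delong", "bootstrap"),
                             boot_n = 2000, seed = NULL) {
  ci_method <- match.arg(ci_method)
  if (cohort_mode(cohort) != "validation") {
    cohort_error("ROC analysis requires a validation-mode cohort",
                 "miascore_validation_error")
  }
  feats <- c("A_size", "B_location", "C_shape", "score")
  setNames(lapply(feats, function(f) {
    roc_analysis(roc_feature_values(cohort, f, coefficients), cohort$ruptured,
                 ci_method = ci_method, boot_n = boot_n, seed = seed)
  }), feats)
}
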