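#' Coefficients of the aneurysm-specific prediction score
#'
#' The score of an aneurysm is the sum of three components,
#' `score = A + B + C`:
#' \itemize{
#'   \item `A = size_coeff * diameter_mm` — 0.0427 per millimetre of
#'     maximum diameter;
#'   \item `B = location_coeffs[location]` — 0 at the anterior communicating
#'     (AcomA) and anterior cerebral (AA) arteries, −0.0104 at PcomA,
#'     −0.1831 in the posterior circulation (PC), −0.4055 at MCA, −0.5973 at
#'     ICA;
#'   \item `C = irregular_bonus` (0.5387) for irregular shape, 0 for regular.
#' }
#' The defaults are the published coefficients (fitted in the original
#' derivation study by component-wise gradient boosting with linear base
#' learners; this package only applies them). Coefficients are data, not
#' code: alternative values — e.g. a future recalibration — can be supplied
#' here or loaded from a YAML/JSON file with [read_coefficients()].
#'
#' @param size_coeff per-mm diameter multiplier.
#' @param location_coeffs named numeric vector over all six location labels
#'   (PC, AcomA, AA, PcomA, MCA, ICA). AcomA and AA share the default value 0
#'   but both entries must be present.
#' @param irregular_bonus additive term for irregular shape.
#' @return An immutable `asps_coefficients` object.
#' @examples
#' asps_coefficients()
#' @export
asps_coefficients <- function(size_coeff = 0.0427,
                              location_coeffs = c(
                                PC = -0.1831, AcomA = 0, AA = 0,
                                PcomA = -0.0104, MCA = -0.4055, ICA = -0.5973
                              ),
                              irregular_bonus = 0.5387) {
  stopifnot(is.numeric(size_coeff), length(size_coeff) == 1L,
            is.numeric(irregular_bonus), length(irregular_bonus) == 1L,
            is.numeric(location_coeffs))
  missing_loc <- setdiff(LOCATION_LEVELS, names(location_coeffs))
  if (length(missing_loc)) {
    cohort_error(
      paste0("location_coeffs missing entries for: ",
             paste(missing_loc, collapse = ", ")),
      "miascore_config_error"
    )
  }
  obj <- list(
    size_coeff = as.numeric(size_coeff),
    location_coeffs = location_coeffs[LOCATION_LEVELS],
    irregular_bonus = as.numeric(irregular_bonus)
  )
  class(obj) <- "asps_coefficients"
  obj
}

#' @export
print.asps_coefficients <- function(x, ...) {
  cat("Aneurysm-specific prediction score coefficients\n")
  cat(sprintf("  A: %.4f per mm maximum diameter\n", x$size_coeff))
  cat("  B:", paste(sprintf("%s %.4f", names(x$location_coeffs),
                            x$location_coeffs), collapse = ", "), "\n")
  cat(sprintf("  C: +%.4f if irregular\n", x$irregular_bonus))
  invisible(x)
}

#' Load score coefficients from a YAML or JSON file
#'
#' The file must define `size_coeff`, `location_coeffs` (all six locations)
#' and `irregular_bonus`; see [asps_coefficients()] for the defaults.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return An `asps_coefficients` object.
#' @export
read_coefficients <- function(path) {
  if (!file.exists(path)) {
    cohort_error(sprintf("coefficient file not found: %s", path),
                 "miascore_config_error")
  }
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  need <- c("size_coeff", "location_coeffs", "irregular_bonus")
  if (!all(need %in% names(raw))) {
    cohort_error(
      paste0("coefficient file must define: ", paste(need, collapse = ", ")),
      "miascore_config_error"
    )
  }
  asps_coefficients(
    size_coeff = as.numeric(raw$size_coeff),
    location_coeffs = unlist(raw$location_coeffs),
    irregular_bonus = as.numeric(raw$irregular_bonus)
  )
}

#' Write score coefficients to YAML or JSON
#'
#' @param coefficients an `asps_coefficients` object.
#' @param path output path; format chosen by extension (`.json` vs YAML).
#' @export
write_coefficients <- function(coefficients, path) {
  x <- list(
    size_coeff = coefficients$size_coeff,
    location_coeffs = as.list(coefficients$location_coeffs),
    irregular_bonus = coefficients$irregular_bonus
  )
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' Compute the aneurysm-specific prediction score
#'
#' `compute_score()` scores a single aneurysm given as diameter, location
#' and shape; `score_cohort()` scores every aneurysm of a cohort, appending
#' columns `component_A`, `component_B`, `component_C` and `score` while
#' preserving the patient grouping. Scores are kept at full double
#' precision; printing and report writers round to 5 decimals.
#'
#' @param diameter_mm positive maximum diameter in millimetres.
#' @param location one of PC, AcomA, AA, PcomA, MCA, ICA (synonyms accepted).
#' @param shape `"regular"` or `"irregular"`.
#' @param coefficients an [asps_coefficients()] object.
#' @return `compute_score()`: a one-row data frame with the three components
#'   and their sum; `score_cohort()`: the cohort with four added columns.
#' @examples
#' compute_score(7.9, "PcomA", "irregular")$score  # 0.86563
#' head(score_cohort(table3_fixture()))
#' @export
compute_score <- function(diameter_mm, location, shape,
                          coefficients = asps_coefficients()) {
  stopifnot(is.numeric(diameter_mm), all(diameter_mm > 0))
  location <- parse_location(location)
  shape <- parse_shape(shape)
  a <- coefficients$size_coeff * diameter_mm
  b <- unname(coefficients$location_coeffs[as.character(location)])
  c_ <- ifelse(shape == "irregular", coefficients$irregular_bonus, 0)
  data.frame(component_A = a, component_B = b, component_C = c_,
             score = a + b + c_)
}

#' @rdname compute_score
#' @param cohort a `mia_cohort` (or data frame coercible to one).
#' @export
score_cohort <- function(cohort, coefficients = asps_coefficients()) {
  if (!inherits(cohort, "mia_cohort")) {
    cohort <- as_cohort(cohort, mode = "prediction", allow_single = TRUE)
  }
  if (nrow(cohort) == 0) {
    for (col in c("component_A", "component_B", "component_C", "score")) {
      cohort[[col]] <- numeric()
    }
    return(cohort)
  }
  sc <- compute_score(cohort$diameter_mm, cohort$location, cohort$shape,
                      coefficients)
  cohort$component_A <- sc$component_A
  cohort$component_B <- sc$component_B
  cohort$component_C <- sc$component_C
  cohort$score <- sc$score
  cohort
}

#' Continuous feature encodings used in the ROC analysis
#'
#' Returns the per-aneurysm continuous value for one of the four ROC
#' features: `A_size` (coefficient-scaled diameter), `B_location` (the
#' location coefficient), `C_shape` (irregular = 1, regular = 0, the 0/1
#' encoding used in the published AUC table; AUC is invariant to using the
#' 0/0.5387 score term instead) or `score` (the full A + B + C).
#'
#' @param cohort a `mia_cohort`.
#' @param feature one of `"A_size"`, `"B_location"`, `"C_shape"`, `"score"`.
#' @param coefficients an [asps_coefficients()] object.
#' @return Numeric vector, one value per aneurysm.
#' @export
roc_feature_values <- function(cohort,
                               feature = c("A_size", "B_location",
                                           "C_shape", "score"),
                               coefficients = asps_coefficients()) {
  feature <- match.arg(feature)
  sc <- score_cohort(cohort, coefficients)
  switch(feature,
    A_size = sc$component_A,
    B_location = sc$component_B,
    C_shape = as.numeric(sc$shape == "irregular"),
    score = sc$score
  )
}
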