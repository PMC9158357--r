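#' @importFrom stats setNames
NULL

# Canonical controlled vocabularies. AcomA and AA are distinct input labels:
# they share one location coefficient but Table-1-style summaries merge them
# only at reporting time, never in the stored data.
LOCATION_LEVELS <- c("PC", "AcomA", "AA", "PcomA", "MCA", "ICA")
SHAPE_LEVELS <- c("regular", "irregular")

# Case-insensitive synonyms accepted on input (keys are lower-case).
LOCATION_SYNONYMS <- c(
  "pc" = "PC", "posterior circulation" = "PC", "posterior_circulation" = "PC",
  "acoma" = "AcomA", "acom" = "AcomA", "anterior communicating artery" = "AcomA",
  "aa" = "AA", "aca" = "AA", "anterior cerebral artery" = "AA",
  "pcoma" = "PcomA", "pcom" = "PcomA", "posterior communicating artery" = "PcomA",
  "mca" = "MCA", "middle cerebral artery" = "MCA",
  "ica" = "ICA", "internal carotid artery" = "ICA"
)

cohort_error <- function(msg, class) {
  stop(structure(
    class = c(class, "miascore_error", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

parse_location <- function(x, row = NULL) {
  key <- tolower(trimws(as.character(x)))
  out <- unname(LOCATION_SYNONYMS[key])
  bad <- which(is.na(out) | key == "")
  if (length(bad)) {
    where <- if (is.null(row)) bad[1] else row[bad[1]]
    cohort_error(
      sprintf("unknown location label '%s' (row %s)", x[bad[1]], where),
      "miascore_parse_error"
    )
  }
  factor(out, levels = LOCATION_LEVELS)
}

parse_shape <- function(x, row = NULL) {
  key <- tolower(trimws(as.character(x)))
  bad <- which(!key %in% SHAPE_LEVELS)
  if (length(bad)) {
    where <- if (is.null(row)) bad[1] else row[bad[1]]
    cohort_error(
      sprintf("unknown shape label '%s' (row %s)", x[bad[1]], where),
      "miascore_parse_error"
    )
  }
  factor(key, levels = SHAPE_LEVELS)
}

parse_ruptured <- function(x, row = NULL) {
  key <- tolower(trimws(as.character(x)))
  map <- c("0" = FALSE, "1" = TRUE, "true" = TRUE, "false" = FALSE,
           "yes" = TRUE, "no" = FALSE)
  out <- unname(map[key])
  bad <- which(is.na(out))
  if (length(bad)) {
    where <- if (is.null(row)) bad[1] else row[bad[1]]
    cohort_error(
      sprintf("unreadable ruptured flag '%s' (row %s)", x[bad[1]], where),
      "miascore_parse_error"
    )
  }
  out
}

#' Assemble and validate an aneurysm-level cohort
#'
#' A cohort is a plain data frame with one row per aneurysm and columns
#' `patient_id`, `aneurysm_id`, `diameter_mm`, `location`, `shape` and
#' (except in prediction mode) `ruptured`. `as_cohort()` normalises the
#' controlled vocabularies, checks the invariants and attaches the
#' `mia_cohort` class. Within-patient row order is preserved exactly as
#' given; no sorting is performed, so downstream tie handling is
#' deterministic.
#'
#' Invariants enforced: positive diameters; locations in
#' `r paste(LOCATION_LEVELS, collapse = ", ")` (case-insensitive, with
#' documented synonyms such as "posterior circulation" for PC); shapes
#' regular/irregular; aneurysm ids unique within each patient; every patient
#' holds at least two aneurysms unless `allow_single = TRUE`; and in
#' validation mode exactly one ruptured aneurysm per patient (the
#' multiple-aneurysm subarachnoid-hemorrhage setting: one lesion bled, the
#' rest did not).
#'
#' @param data data frame of aneurysm rows.
#' @param mode `"validation"` (rupture labels present, one per patient) or
#'   `"prediction"` (labels optional and unchecked).
#' @param allow_single permit patients with a single aneurysm (useful when
#'   scoring, meaningless when validating within-patient identification).
#' @return A `mia_cohort` data frame with a `mode` attribute.
#' @examples
#' df <- data.frame(
#'   patient_id = c("p1", "p1"), aneurysm_id = c("a1", "a2"),
#'   diameter_mm = c(7.9, 7.6), location = c("PcomA", "PcomA"),
#'   shape = c("irregular", "irregular"), ruptured = c(FALSE, TRUE)
#' )
#' as_cohort(df)
#' @export
as_cohort <- function(data, mode = c("validation", "prediction"),
                      allow_single = FALSE) {
  mode <- match.arg(mode)
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  required <- c("patient_id", "aneurysm_id", "diameter_mm", "location", "shape")
  if (mode == "validation") required <- c(required, "ruptured")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols)) {
    cohort_error(
      paste0("missing column(s): ", paste(missing_cols, collapse = ", ")),
      "miascore_parse_error"
    )
  }

  n <- nrow(data)
  rows <- seq_len(n)
  out <- data.frame(
    patient_id = as.character(data$patient_id),
    aneurysm_id = as.character(data$aneurysm_id),
    diameter_mm = suppressWarnings(as.numeric(as.character(data$diameter_mm))),
    stringsAsFactors = FALSE
  )
  if (n > 0) {
    bad <- which(is.na(out$diameter_mm) | out$diameter_mm <= 0)
    if (length(bad)) {
      cohort_error(
        sprintf("diameter_mm must be a positive number (row %d: '%s')",
                bad[1], as.character(data$diameter_mm)[bad[1]]),
        "miascore_parse_error"
      )
    }
    out$location <- parse_location(data$location, rows)
    out$shape <- parse_shape(data$shape, rows)
    if ("ruptured" %in% names(data)) {
      out$ruptured <- parse_ruptured(data$ruptured, rows)
    } else {
      out$ruptured <- rep(NA, n)
    }
  } else {
    out$location <- factor(character(), levels = LOCATION_LEVELS)
    out$shape <- factor(character(), levels = SHAPE_LEVELS)
    out$ruptured <- logical()
  }

  # group by patient preserving first-appearance order and in-file row order
  out$patient_id <- factor(out$patient_id, levels = unique(out$patient_id))
  split_ids <- split(out$aneurysm_id, out$patient_id)
  for (pid in names(split_ids)) {
    ids <- split_ids[[pid]]
    if (anyDuplicated(ids)) {
      cohort_error(
        sprintf("duplicate aneurysm_id '%s' within patient %s",
                ids[anyDuplicated(ids)], pid),
        "miascore_validation_error"
      )
    }
    if (length(ids) < 2 && !allow_single) {
      cohort_error(
        sprintf("patient %s has a single aneurysm; the cohort is multiple-aneurysm only (set allow_single = TRUE to permit)", pid),
        "miascore_validation_error"
      )
    }
  }
  if (mode == "validation" && n > 0) {
    nrupt <- tapply(out$ruptured, out$patient_id, sum)
    bad <- names(nrupt)[nrupt != 1]
    if (length(bad)) {
      cohort_error(
        sprintf("patient %s has %d ruptured aneurysms; validation mode requires exactly one per patient",
                bad[1], nrupt[[bad[1]]]),
        "miascore_validation_error"
      )
    }
  }
  out$patient_id <- as.character(out$patient_id)
  structure(out, mode = mode, class = c("mia_cohort", "data.frame"))
}

#' @export
print.mia_cohort <- function(x, ...) {
  if (is.null(x$patient_id)) return(print.data.frame(x, ...))
  cat(sprintf("<mia_cohort> %d patients, %d aneurysms (%s mode)\n",
              length(unique(x$patient_id)), nrow(x), cohort_mode(x)))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat(sprintf("... %d more rows\n", nrow(x) - 10))
  invisible(x)
}

#' Cohort mode
#' @param cohort a `mia_cohort`.
#' @return `"validation"` or `"prediction"`.
#' @export
cohort_mode <- function(cohort) {
  m <- attr(cohort, "mode")
  if (is.null(m)) "validation" else m
}

#' Read an aneurysm-level cohort from CSV
#'
#' The file must be comma-separated UTF-8 with a header row containing
#' `patient_id, aneurysm_id, diameter_mm, location, shape, ruptured`
#' (`ruptured` may be omitted in prediction mode). Decimal points only;
#' integer diameters parse as reals. The ruptured column accepts
#' 0/1/true/false/yes/no case-insensitively. Rows are grouped by
#' `patient_id` preserving file order within each patient.
#'
#' @inheritParams as_cohort
#' @param path CSV file path.
#' @return A validated `mia_cohort`.
#' @seealso [write_cohort()], [table3_fixture()]
#' @export
read_cohort <- function(path, mode = c("validation", "prediction"),
                        allow_single = FALSE) {
  mode <- match.arg(mode)
  if (!file.exists(path)) {
    cohort_error(sprintf("file not found: %s", path), "miascore_io_error")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", fileEncoding = "UTF-8")
  as_cohort(df, mode = mode, allow_single = allow_single)
}

#' Write a cohort to CSV
#'
#' Writes the canonical six columns so that [read_cohort()] reproduces the
#' cohort field-for-field (round-trip identity). Ruptured flags are written
#' as `yes`/`no`; unknown flags (prediction mode) leave the column out.
#'
#' @param cohort a `mia_cohort`.
#' @param path output CSV path.
#' @export
write_cohort <- function(cohort, path) {
  df <- data.frame(
    patient_id = cohort$patient_id,
    aneurysm_id = cohort$aneurysm_id,
    diameter_mm = vapply(cohort$diameter_mm, format, character(1), digits = 15),
    location = as.character(cohort$location),
    shape = as.character(cohort$shape),
    stringsAsFactors = FALSE
  )
  if (nrow(cohort) == 0 || !all(is.na(cohort$ruptured))) {
    df$ruptured <- ifelse(cohort$ruptured, "yes", "no")
  }
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) cohort_error(sprintf("cannot write to %s", path), "miascore_io_error")
  invisible(path)
}

#' The misidentified-patient fixture cohort
#'
#' The 17 patients (38 aneurysms) in whom the largest-score rule picked an
#' unruptured aneurysm, shipped with the package as a plain-CSV fixture.
#' Only the raw morphology (maximum diameter, location, shape) and rupture
#' status are stored; prediction scores are always recomputed from the
#' coefficients, never read from disk.
#'
#' @return A validation-mode `mia_cohort` of 17 patients / 38 aneurysms.
#' @examples
#' fx <- table3_fixture()
#' nrow(fx)
#' @export
table3_fixture <- function() {
  path <- system.file("extdata", "table3_cohort.csv", package = "miascore",
                      mustWork = TRUE)
  read_cohort(path, mode = "validation")
}
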