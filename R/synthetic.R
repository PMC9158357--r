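LOCATION_GROUPS <- c("PC", "AcomA+AA", "PcomA", "MCA", "ICA")

#' Configuration of the synthetic multiple-aneurysm cohort generator
#'
#' The defaults reproduce the structure of the validation cohort the score
#' was tested on: 134 patients with 2-4 aneurysms each (115 with 2, 16 with
#' 3, 3 with 4 — 290 aneurysms in all), exactly one ruptured aneurysm per
#' patient, ruptured diameters 7.88 +/- 3.02 mm and unruptured 5.02 +/-
#' 2.44 mm (truncated to the observed 1.8-20.7 mm range), irregular-shape
#' probabilities 0.709 (ruptured) and 0.231 (unruptured), and the observed
#' location frequencies over PC / AcomA+AA / PcomA / MCA / ICA for each
#' group. AcomA+AA draws are split 50/50 between the two labels (separate
#' frequencies are not reported). Shape and location are sampled
#' independently given rupture status, since only group marginals are
#' reported.
#'
#' Diameters are sampled by rejection from a normal truncated to
#' `size_range`; the parent location parameter is solved so that the
#' truncated distribution's mean equals the configured mean (the configured
#' values are targets for the realised moments, not parent parameters; the
#' realised SD is slightly below nominal because of the truncation).
#'
#' @param n_patients number of patients.
#' @param aneurysms_per_patient_dist named probabilities over counts 2, 3, 4.
#' @param ruptured_size,unruptured_size `c(mean, sd)` of maximum diameter
#'   in mm for each group.
#' @param irregular_prob_ruptured,irregular_prob_unruptured probability of
#'   irregular shape.
#' @param location_probs_ruptured,location_probs_unruptured named
#'   probabilities over `PC, AcomA+AA, PcomA, MCA, ICA`, summing to 1.
#' @param size_range `c(min, max)` diameter truncation bounds in mm.
#' @param seed integer seed; one global stream with per-patient substreams
#'   derived deterministically, so patient i's draw does not change when
#'   `n_patients` does.
#' @param deterministic_counts if `TRUE` (default), per-patient aneurysm
#'   counts follow the distribution's quantiles deterministically (the
#'   defaults then give exactly 115/16/3 patients with 2/3/4 aneurysms);
#'   if `FALSE`, counts are sampled.
#' @return A validated `generator_config` list.
#' @examples
#' cfg <- generator_config(seed = 1)
#' cfg$ruptured_size
#' @export
generator_config <- function(n_patients = 134,
                             aneurysms_per_patient_dist = c(
                               "2" = 115 / 134, "3" = 16 / 134, "4" = 3 / 134
                             ),
                             ruptured_size = c(mean = 7.88, sd = 3.02),
                             unruptured_size = c(mean = 5.02, sd = 2.44),
                             irregular_prob_ruptured = 0.709,
                             irregular_prob_unruptured = 0.231,
                             location_probs_ruptured = c(
                               "PC" = 0.037, "AcomA+AA" = 0.179,
                               "PcomA" = 0.471, "MCA" = 0.246, "ICA" = 0.067
                             ),
                             location_probs_unruptured = c(
                               "PC" = 0.064, "AcomA+AA" = 0.103,
                               "PcomA" = 0.244, "MCA" = 0.333, "ICA" = 0.256
                             ),
                             size_range = c(1.8, 20.7),
                             seed = 1L,
                             deterministic_counts = TRUE) {
  cfg <- list(
    n_patients = as.integer(n_patients),
    aneurysms_per_patient_dist = aneurysms_per_patient_dist,
    ruptured_size = ruptured_size, unruptured_size = unruptured_size,
    irregular_prob_ruptured = irregular_prob_ruptured,
    irregular_prob_unruptured = irregular_prob_unruptured,
    location_probs_ruptured = location_probs_ruptured,
    location_probs_unruptured = location_probs_unruptured,
    size_range = as.numeric(size_range),
    seed = as.integer(seed),
    deterministic_counts = isTRUE(deterministic_counts)
  )
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

validate_generator_config <- function(cfg) {
  bad <- function(msg) cohort_error(msg, "miascore_config_error")
  if (is.na(cfg$n_patients) || cfg$n_patients < 1) bad("n_patients must be >= 1")
  d <- cfg$aneurysms_per_patient_dist
  if (!all(names(d) %in% c("2", "3", "4")) || any(d < 0) || any(d > 1) ||
      abs(sum(d) - 1) > 1e-9) {
    bad("aneurysms_per_patient_dist must be probabilities over counts 2, 3, 4 summing to 1")
  }
  for (nm in c("ruptured_size", "unruptured_size")) {
    s <- cfg[[nm]]
    if (length(s) != 2 || any(is.na(s)) || s[2] <= 0 || s[1] <= 0) {
      bad(sprintf("%s must be c(mean > 0, sd > 0)", nm))
    }
  }
  for (nm in c("irregular_prob_ruptured", "irregular_prob_unruptured")) {
    p <- cfg[[nm]]
    if (length(p) != 1 || is.na(p) || p < 0 || p > 1) bad(sprintf("%s must be in [0, 1]", nm))
  }
  for (nm in c("location_probs_ruptured", "location_probs_unruptured")) {
    p <- cfg[[nm]]
    if (!identical(sort(names(p)), sort(LOCATION_GROUPS)) || any(p < 0) ||
        any(p > 1) || abs(sum(p) - 1) > 1e-9) {
      bad(sprintf("%s must cover %s and sum to 1", nm,
                  paste(LOCATION_GROUPS, collapse = ", ")))
    }
  }
  if (length(cfg$size_range) != 2 || cfg$size_range[1] <= 0 ||
      cfg$size_range[1] >= cfg$size_range[2]) {
    bad("size_range must be c(min > 0, max > min)")
  }
  for (nm in c("ruptured_size", "unruptured_size")) {
    s <- cfg[[nm]]
    if (cfg$size_range[1] > s[1] + 6 * s[2] || cfg$size_range[2] < s[1] - 6 * s[2]) {
      bad(sprintf("size_range excludes %s mean +/- 6 sd: truncation infeasible", nm))
    }
  }
  invisible(cfg)
}

# mean of N(mu, sigma) truncated to [a, b]
truncated_normal_mean <- function(mu, sigma, a, b) {
  alpha <- (a - mu) / sigma
  beta <- (b - mu) / sigma
  mass <- stats::pnorm(alpha, lower.tail = FALSE) -
    stats::pnorm(beta, lower.tail = FALSE)
  mu + sigma * (stats::dnorm(alpha) - stats::dnorm(beta)) / mass
}

# parent location such that the [a, b]-truncated mean hits target_mean
solve_parent_mean <- function(target_mean, sigma, a, b) {
  stats::uniroot(
    function(mu) truncated_normal_mean(mu, sigma, a, b) - target_mean,
    interval = c(target_mean - 6 * sigma, target_mean + 6 * sigma),
    extendInt = "upX", tol = 1e-10
  )$root
}

rtrunc_norm <- function(n, mu, sigma, a, b) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    draw <- stats::rnorm(length(need), mu, sigma)
    ok <- draw >= a & draw <= b
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

# deterministic per-patient counts: inverse CDF at patient mid-quantiles
deterministic_counts_for <- function(n, dist) {
  counts <- as.integer(names(dist))
  cum <- cumsum(dist)
  q <- (seq_len(n) - 0.5) / n
  counts[findInterval(q, cum, left.open = TRUE) + 1L]
}

#' Generate a synthetic validation cohort
#'
#' Draws a cohort under a [generator_config()]: each patient receives an
#' aneurysm count, exactly one aneurysm is designated ruptured, its
#' morphology is sampled from the ruptured-group distributions and the
#' rest from the unruptured ones. Fully reproducible: the same config
#' (including seed) yields the same cohort field-for-field, and the global
#' RNG state is left untouched.
#'
#' @param config a [generator_config()].
#' @return A validation-mode `mia_cohort`.
#' @examples
#' co <- generate_cohort(generator_config(seed = 42))
#' nrow(co)  # 290 with the default deterministic counts
#' @export
generate_cohort <- function(config = generator_config()) {
  validate_generator_config(config)
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })

  mu_r <- solve_parent_mean(config$ruptured_size[[1]], config$ruptured_size[[2]],
                            config$size_range[1], config$size_range[2])
  mu_u <- solve_parent_mean(config$unruptured_size[[1]], config$unruptured_size[[2]],
                            config$size_range[1], config$size_range[2])
  det_counts <- if (config$deterministic_counts) {
    deterministic_counts_for(config$n_patients, config$aneurysms_per_patient_dist)
  }

  rows <- vector("list", config$n_patients)
  for (i in seq_len(config$n_patients)) {
    # per-patient substream: stable under n_patients changes
    set.seed((config$seed + i * 1000003) %% 2147483647L)
    k <- if (config$deterministic_counts) {
      det_counts[i]
    } else {
      as.integer(sample(names(config$aneurysms_per_patient_dist), 1,
                        prob = config$aneurysms_per_patient_dist))
    }
    ruptured_idx <- sample.int(k, 1)
    ruptured <- seq_len(k) == ruptured_idx
    diam <- shape <- loc <- character(k)
    for (j in seq_len(k)) {
      if (ruptured[j]) {
        d <- rtrunc_norm(1, mu_r, config$ruptured_size[[2]],
                         config$size_range[1], config$size_range[2])
        irr <- stats::runif(1) < config$irregular_prob_ruptured
        grp <- sample(LOCATION_GROUPS, 1, prob = config$location_probs_ruptured[LOCATION_GROUPS])
      } else {
        d <- rtrunc_norm(1, mu_u, config$unruptured_size[[2]],
                         config$size_range[1], config$size_range[2])
        irr <- stats::runif(1) < config$irregular_prob_unruptured
        grp <- sample(LOCATION_GROUPS, 1, prob = config$location_probs_unruptured[LOCATION_GROUPS])
      }
      diam[j] <- format(d, digits = 15)
      shape[j] <- if (irr) "irregular" else "regular"
      loc[j] <- if (grp == "AcomA+AA") sample(c("AcomA", "AA"), 1) else grp
    }
    rows[[i]] <- data.frame(
      patient_id = sprintf("p%04d", i),
      aneurysm_id = sprintf("a%d", seq_len(k)),
      diameter_mm = diam, location = loc, shape = shape,
      ruptured = ruptured, stringsAsFactors = FALSE
    )
  }
  as_cohort(do.call(rbind, rows), mode = "validation")
}

#' Reconstruct a cohort from a rule's confusion counts
#'
#' Inverse construction: builds a minimal synthetic cohort on which the
#' given identification rule reproduces the supplied aneurysm-level
#' confusion counts exactly. For an argmax rule (`score_largest`,
#' `diameter_largest`) this requires `fp == fn` (each misidentified patient
#' contributes exactly one false positive and one false negative) and
#' `tn >= tp`; extra non-maximal unruptured aneurysms realise `tn` beyond
#' the two-aneurysm base. For a membership rule every feature-positive
#' aneurysm must be packable into patients that each hold one ruptured
#' aneurysm and at least one unruptured one (`fp + tn >= tp + fn`).
#' Useful as an oracle: published accuracy-table rows can be materialised
#' and re-evaluated end to end.
#'
#' @param counts list with `tp`, `fp`, `fn`, `tn`.
#' @param rule a [prediction_rule()] (membership construction uses PcomA as
#'   the target site unless the rule names another).
#' @return A validation-mode `mia_cohort`.
#' @examples
#' co <- generate_from_counts(list(tp = 117, fp = 17, fn = 17, tn = 139),
#'                            prediction_rule("score_largest"))
#' length(unique(co$patient_id))  # 134
#' @export
generate_from_counts <- function(counts, rule = prediction_rule("score_largest")) {
  if (!inherits(rule, "prediction_rule")) rule <- prediction_rule(rule)
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn; tn <- counts$tn
  stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0)
  bad <- function(msg) cohort_error(msg, "miascore_config_error")

  if (rule$kind %in% c("score_largest", "diameter_largest")) {
    if (fp != fn) {
      bad(sprintf("argmax rule infeasible: predicted totals imply one prediction per patient, so fp (%d) must equal fn (%d)", fp, fn))
    }
    if (tn < tp) bad("argmax rule infeasible: tn must be at least tp")
    n_pat <- tp + fp
    if (n_pat < 1) bad("no patients implied by counts")
    extras <- tn - tp
    rows <- vector("list", n_pat)
    for (i in seq_len(n_pat)) {
      correct <- i <= tp
      # same location/shape throughout: score is then increasing in diameter
      d <- if (correct) c(10, 5) else c(5, 10)  # (ruptured, unruptured)
      rows[[i]] <- data.frame(
        patient_id = sprintf("p%04d", i), aneurysm_id = c("a1", "a2"),
        diameter_mm = d, location = "AcomA", shape = "regular",
        ruptured = c(TRUE, FALSE), stringsAsFactors = FALSE
      )
    }
    if (extras > 0) {
      host <- rep(seq_len(n_pat), length.out = extras)
      slot <- stats::ave(host, host, FUN = seq_along)
      extra_rows <- data.frame(
        patient_id = sprintf("p%04d", host),
        aneurysm_id = sprintf("x%d", slot),
        diameter_mm = 2 - 0.01 * seq_len(extras),  # below every maximum, all distinct
        location = "AcomA", shape = "regular", ruptured = FALSE,
        stringsAsFactors = FALSE
      )
      rows <- c(rows, list(extra_rows))
    }
    df <- do.call(rbind, rows)
    df <- df[order(df$patient_id), ]
    return(as_cohort(df, mode = "validation"))
  }

  # membership rule: tp+fn patients, one ruptured each; fp+tn unruptured
  n_pat <- tp + fn
  if (n_pat < 1) bad("no patients implied by counts")
  if (fp + tn < n_pat) {
    bad("membership rule infeasible: fewer unruptured aneurysms than patients")
  }
  target <- if (rule$kind == "shape_irregular") NULL else {
    if (identical(rule$location_target, "AcomA+AA")) "AcomA" else rule$location_target
  }
  other_loc <- if (is.null(target) || target != "MCA") "MCA" else "ICA"
  morph <- function(positive) {
    if (rule$kind == "shape_irregular") {
      list(location = "MCA", shape = if (positive) "irregular" else "regular")
    } else {
      list(location = if (positive) target else other_loc, shape = "regular")
    }
  }
  rupt_pos <- c(rep(TRUE, tp), rep(FALSE, fn))
  unrupt_pos <- c(rep(TRUE, fp), rep(FALSE, tn))
  host <- rep(seq_len(n_pat), length.out = fp + tn)  # >= 1 unruptured each
  rows <- lapply(seq_len(n_pat), function(i) {
    m <- morph(rupt_pos[i])
    data.frame(patient_id = sprintf("p%04d", i), aneurysm_id = "r1",
               diameter_mm = 6, location = m$location, shape = m$shape,
               ruptured = TRUE, stringsAsFactors = FALSE)
  })
  un <- lapply(seq_along(unrupt_pos), function(j) {
    m <- morph(unrupt_pos[j])
    data.frame(patient_id = sprintf("p%04d", host[j]),
               aneurysm_id = sprintf("u%d", j), diameter_mm = 4,
               location = m$location, shape = m$shape, ruptured = FALSE,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, c(rows, un))
  df <- df[order(df$patient_id), ]
  as_cohort(df, mode = "validation")
}
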