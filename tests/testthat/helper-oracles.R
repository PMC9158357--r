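# Published per-aneurysm scores of the misidentified-patient table, in
# fixture row order. Frozen from the printed 5-decimal column; tests
# recompute them from the raw morphology.
TABLE3_SCORES <- c(
  0.86563, 0.85282, 0.21591, 0.14759, 0.73085, -0.22189, 0.59009,
  0.63078, 0.19456, 0.72899, 0.16040, 0.42783, -0.23043, 0.32025,
  0.26047, 0.39367, -0.23862, 0.44491, 0.14759, 0.17321, -0.37099,
  0.85468, 0.53920, 0.21777, -0.25178, 0.22018, 0.08982, -0.45639,
  -0.46920, 0.42356, 0.75888, 0.27569, 0.82720, 0.77169, -0.28594,
  0.83147, -0.46920, 0.81012
)

# Published aneurysm-level confusion counts (tp, fp, fn, tn) per rule.
TABLE2_COUNTS <- list(
  diameter_largest = list(tp = 109, fp = 25, fn = 25, tn = 131),
  shape_irregular = list(tp = 95, fp = 36, fn = 39, tn = 120),
  location_PcomA = list(tp = 63, fp = 38, fn = 71, tn = 118),
  score_largest = list(tp = 117, fp = 17, fn = 17, tn = 139)
)

# Random cohort builder independent of the package generator.
random_cohort <- function(n_patients = 10, seed = 1, round_digits = 1) {
  set.seed(seed)
  rows <- lapply(seq_len(n_patients), function(i) {
    k <- sample(2:4, 1)
    data.frame(
      patient_id = paste0("p", i),
      aneurysm_id = paste0("a", seq_len(k)),
      diameter_mm = round(runif(k, 1.8, 20.7), round_digits),
      location = sample(c("PC", "AcomA", "AA", "PcomA", "MCA", "ICA"), k,
                        replace = TRUE),
      shape = sample(c("regular", "irregular"), k, replace = TRUE),
      ruptured = seq_len(k) == sample.int(k, 1),
      stringsAsFactors = FALSE
    )
  })
  as_cohort(do.call(rbind, rows))
}

# Exhaustive-scan argmax oracle: an aneurysm is predicted iff no
# patient-mate has a strictly larger key (flag_all semantics).
brute_argmax <- function(cohort, key) {
  vapply(seq_len(nrow(cohort)), function(i) {
    mates <- cohort$patient_id == cohort$patient_id[i]
    all(key[i] >= key[mates])
  }, logical(1))
}

# Brute-force tie-corrected concordance over all ruptured x unruptured pairs.
auc_pairs <- function(values, ruptured) {
  pos <- values[ruptured]
  neg <- values[!ruptured]
  s <- 0
  for (p in pos) s <- s + sum(p > neg) + 0.5 * sum(p == neg)
  s / (length(pos) * length(neg))
}

# Trapezoidal area under an ROC point set.
trapezoid_auc <- function(points) {
  o <- order(points$fpr, points$tpr)
  x <- points$fpr[o]
  y <- points$tpr[o]
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

# Two-aneurysm toy cohort where the score rule is perfect.
perfect_cohort <- function() {
  as_cohort(data.frame(
    patient_id = rep(c("p1", "p2"), each = 2),
    aneurysm_id = rep(c("a1", "a2"), 2),
    diameter_mm = c(9, 3, 8, 4),
    location = "AcomA", shape = "regular",
    ruptured = c(TRUE, FALSE, TRUE, FALSE),
    stringsAsFactors = FALSE
  ))
}
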