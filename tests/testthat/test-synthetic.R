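test_that("default configuration carries the study-structure parameters", {
  cfg <- generator_config()
  expect_equal(cfg$n_patients, 134L)
  expect_equal(unname(cfg$ruptured_size), c(7.88, 3.02))
  expect_equal(unname(cfg$unruptured_size), c(5.02, 2.44))
  expect_equal(cfg$irregular_prob_ruptured, 0.709)
  expect_equal(cfg$irregular_prob_unruptured, 0.231)
  expect_equal(sum(cfg$location_probs_ruptured), 1)
  expect_equal(sum(cfg$location_probs_unruptured), 1)
  expect_equal(cfg$size_range, c(1.8, 20.7))
  expect_equal(unname(cfg$aneurysms_per_patient_dist),
               c(115, 16, 3) / 134)
})

test_that("invalid configurations are rejected", {
  expect_error(generator_config(location_probs_ruptured = c(
    "PC" = 0.5, "AcomA+AA" = 0.5, "PcomA" = 0.2, "MCA" = 0, "ICA" = 0
  )), class = "miascore_config_error")
  expect_error(generator_config(ruptured_size = c(7.88, -1)),
               class = "miascore_config_error")
  expect_error(generator_config(size_range = c(-1, 20)),
               class = "miascore_config_error")
  # truncation window entirely outside mean +/- 6 sd
  expect_error(generator_config(ruptured_size = c(200, 1),
                                size_range = c(1.8, 20.7)),
               class = "miascore_config_error")
})

test_that("default draws give 134 patients, 290 aneurysms, one rupture each", {
  co <- generate_cohort(generator_config(seed = 5))
  expect_equal(length(unique(co$patient_id)), 134)
  expect_equal(nrow(co), 290)
  expect_equal(sum(co$ruptured), 134)
  sizes <- table(table(co$patient_id))
  expect_equal(unname(sizes[c("2", "3", "4")]), c(115, 16, 3),
               ignore_attr = TRUE)
  expect_true(all(co$diameter_mm >= 1.8 & co$diameter_mm <= 20.7))
})

test_that("generation is deterministic given the seed, and leaves the RNG alone", {
  set.seed(123)
  before <- .Random.seed
  c1 <- generate_cohort(generator_config(seed = 11))
  expect_identical(.Random.seed, before)
  c2 <- generate_cohort(generator_config(seed = 11))
  expect_identical(as.data.frame(c1), as.data.frame(c2))
  c3 <- generate_cohort(generator_config(seed = 12))
  expect_false(identical(c1$diameter_mm, c3$diameter_mm))
})

test_that("per-patient substreams keep early patients stable under n changes", {
  small <- generate_cohort(generator_config(n_patients = 20, seed = 3))
  large <- generate_cohort(generator_config(n_patients = 40, seed = 3))
  first <- small[small$patient_id %in% sprintf("p%04d", 1:15), ]
  expect_equal(first$diameter_mm,
               large[seq_len(nrow(first)), ]$diameter_mm)
})

test_that("sampled (non-deterministic) counts stay within 2-4 per patient", {
  co <- generate_cohort(generator_config(n_patients = 60, seed = 9,
                                         deterministic_counts = FALSE))
  k <- table(co$patient_id)
  expect_true(all(k >= 2 & k <= 4))
})

test_that("generated cohorts always satisfy the cohort invariants", {
  for (seed in 1:40) {
    n <- 2 + (seed %% 12)
    co <- generate_cohort(generator_config(
      n_patients = n, seed = seed,
      deterministic_counts = seed %% 2 == 0
    ))
    expect_s3_class(co, "mia_cohort")  # as_cohort re-validated on build
    expect_equal(sum(co$ruptured), n)
    expect_true(all(tapply(co$ruptured, co$patient_id, sum) == 1))
    expect_true(all(table(co$patient_id) >= 2))
  }
})

test_that("the generator recovers the configured moments at large n", {
  big <- generate_cohort(generator_config(n_patients = 5000, seed = 20260928))
  r <- big$ruptured
  se_mean <- sd(big$diameter_mm[r]) / sqrt(sum(r))
  expect_lt(abs(mean(big$diameter_mm[r]) - 7.88), 3 * se_mean)
  p_hat <- mean(big$shape[r] == "irregular")
  se_p <- sqrt(0.709 * (1 - 0.709) / sum(r))
  expect_lt(abs(p_hat - 0.709), 3 * se_p)
  # unruptured side too
  se_u <- sd(big$diameter_mm[!r]) / sqrt(sum(!r))
  expect_lt(abs(mean(big$diameter_mm[!r]) - 5.02), 3 * se_u)
})

test_that("on large default cohorts the score rule beats every single feature", {
  co <- generate_cohort(generator_config(n_patients = 2000, seed = 31))
  tab <- evaluate_all_rules(co)
  score_da <- tab$da[tab$rule == "score_largest"]
  expect_true(all(score_da > tab$da[tab$rule != "score_largest"]))
})

test_that("count reconstruction is exact and rejects infeasible tables", {
  co <- generate_from_counts(list(tp = 117, fp = 17, fn = 17, tn = 139),
                             prediction_rule("score_largest"))
  expect_equal(length(unique(co$patient_id)), 134)
  tab <- evaluate_all_rules(co)
  row <- tab[tab$rule == "score_largest", ]
  expect_equal(round(row$sen, 1), 87.3)

  perfect <- generate_from_counts(list(tp = 10, fp = 0, fn = 0, tn = 10),
                                  prediction_rule("score_largest"))
  prow <- evaluate_all_rules(perfect)
  prow <- prow[prow$rule == "score_largest", ]
  expect_equal(c(prow$fp, prow$fn), c(0, 0))

  # 135 predicted "yes" against 134 patients cannot arise from an argmax rule
  expect_error(
    generate_from_counts(list(tp = 110, fp = 25, fn = 24, tn = 131),
                         prediction_rule("diameter_largest")),
    class = "miascore_config_error"
  )
  expect_error(
    generate_from_counts(list(tp = 5, fp = 1, fn = 5, tn = 1),
                         prediction_rule("shape_irregular")),
    class = "miascore_config_error"
  )
})
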