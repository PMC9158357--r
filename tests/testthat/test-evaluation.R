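test_that("fixture confusion: every ruptured aneurysm is missed by the score rule", {
  fx <- table3_fixture()
  cc <- confusion_counts(fx, predict_rupture(fx, prediction_rule("score_largest")))
  expect_equal(cc$tp, 0)
  expect_equal(cc$fn, 17)
  expect_equal(cc$tp + cc$fp + cc$fn + cc$tn, 38)
  # and the score row of the full evaluation has sensitivity 0
  tab <- evaluate_all_rules(fx)
  expect_equal(tab$sen[tab$rule == "score_largest"], 0)
})

test_that("metrics reproduce the published cells from the published counts", {
  m <- diagnostic_metrics(list(tp = 117, fp = 17, fn = 17, tn = 139))
  expect_equal(round(c(m$sen, m$spe, m$beta, m$alpha, m$da), 1),
               c(87.3, 89.1, 12.7, 10.9, 88.3))
  m2 <- diagnostic_metrics(list(tp = 109, fp = 25, fn = 25, tn = 131))
  expect_equal(round(c(m2$sen, m2$spe, m2$da), 1), c(81.3, 84.0, 82.8))
})

test_that("degenerate confusion tables behave per contract", {
  perfect <- diagnostic_metrics(list(tp = 5, fp = 0, fn = 0, tn = 7))
  expect_equal(c(perfect$sen, perfect$spe, perfect$da), c(100, 100, 100))
  expect_error(diagnostic_metrics(list(tp = 0, fp = 3, fn = 0, tn = 5)),
               class = "miascore_metric_error")
  expect_error(diagnostic_metrics(list(tp = 2, fp = 0, fn = 1, tn = 0)),
               class = "miascore_metric_error")
})

test_that("the textbook false omission rate is exposed separately", {
  m <- diagnostic_metrics(list(tp = 109, fp = 25, fn = 25, tn = 131))
  expect_equal(m$false_omission_rate, 100 * 25 / 156)
  expect_false(isTRUE(all.equal(m$false_omission_rate, m$beta)))
})

test_that("complement identities hold for every rule on every cohort", {
  for (seed in 1:6) {
    co <- random_cohort(12, seed = seed)
    tab <- evaluate_all_rules(co)
    expect_equal(tab$sen + tab$beta, rep(100, nrow(tab)))
    expect_equal(tab$spe + tab$alpha, rep(100, nrow(tab)))
    expect_equal(tab$tp + tab$fp + tab$fn + tab$tn, rep(nrow(co), nrow(tab)))
  }
})

test_that("cohorts rebuilt from published counts reproduce the printed metrics", {
  printed <- list(
    diameter_largest = c(sen = 81.3, spe = 84.0, da = 82.8),
    shape_irregular = c(sen = 70.9, spe = 76.9, da = 74.1),
    location_PcomA = c(sen = 47.0, spe = 75.6, da = 62.4),
    score_largest = c(sen = 87.3, spe = 89.1, da = 88.3)
  )
  rules <- list(
    diameter_largest = prediction_rule("diameter_largest"),
    shape_irregular = prediction_rule("shape_irregular"),
    location_PcomA = prediction_rule("location_is", "PcomA"),
    score_largest = prediction_rule("score_largest")
  )
  for (nm in names(TABLE2_COUNTS)) {
    counts <- TABLE2_COUNTS[[nm]]
    co <- generate_from_counts(counts, rules[[nm]])
    expect_equal(nrow(co), 290)
    tab <- evaluate_all_rules(co)
    row <- tab[tab$rule == nm, ]
    expect_equal(unname(c(row$tp, row$fp, row$fn, row$tn)),
                 unname(unlist(counts)))
    expect_equal(round(c(row$sen, row$spe, row$da), 1),
                 unname(printed[[nm]]))
  }
})

test_that("single-patient counts sum to that patient's aneurysm count", {
  co <- as_cohort(data.frame(
    patient_id = "p1", aneurysm_id = c("a1", "a2", "a3"),
    diameter_mm = c(9, 4, 2), location = "MCA",
    shape = c("irregular", "regular", "regular"),
    ruptured = c(TRUE, FALSE, FALSE)
  ))
  tab <- evaluate_all_rules(co)
  expect_true(all(tab$tp + tab$fp + tab$fn + tab$tn == 3))
})

test_that("confusion counting rejects a prediction from another cohort", {
  fx <- table3_fixture()
  other <- perfect_cohort()
  pr <- predict_rupture(other, prediction_rule("score_largest"))
  expect_error(confusion_counts(fx, pr), class = "miascore_validation_error")
})

test_that("the group-wise summary matches independent arithmetic on the fixture", {
  fx <- table3_fixture()
  s <- cohort_summary(fx)
  expect_equal(unname(s$n), c(21, 17))
  d_rupt <- fx$diameter_mm[fx$ruptured]
  d_un <- fx$diameter_mm[!fx$ruptured]
  cont <- s$continuous[s$continuous$variable == "diameter_mm", ]
  expect_equal(cont$mean_ruptured, mean(d_rupt))
  expect_equal(cont$sd_unruptured, sd(d_un))
  # AcomA and AA are merged only in the report
  acom <- s$categorical[s$categorical$level == "AcomA+AA", ]
  expect_equal(acom$n_unruptured,
               sum(!fx$ruptured & fx$location %in% c("AcomA", "AA")))
})

test_that("identical groups give chi-squared p = 1 without continuity correction", {
  rows <- do.call(rbind, lapply(1:6, function(i) data.frame(
    patient_id = paste0("p", i), aneurysm_id = c("a1", "a2"),
    diameter_mm = c(6, 4),
    location = c("MCA", "MCA"),
    shape = c("irregular", "irregular"),
    ruptured = c(TRUE, FALSE)
  )))
  rows$shape[rows$patient_id %in% c("p4", "p5", "p6")] <- "regular"
  s <- cohort_summary(as_cohort(rows), correct = FALSE)
  expect_equal(s$categorical$p[s$categorical$level == "irregular"], 1)
})

test_that("Cohen's kappa matches hand computation and chance behaviour", {
  expect_equal(cohens_kappa(c("a", "b", "a", "c"), c("a", "b", "a", "c")), 1)

  # hand-built 2x2 table: 45 agree-A, 15 agree-B, 25 + 15 disagreements
  a <- c(rep("A", 45), rep("B", 15), rep("A", 25), rep("B", 15))
  b <- c(rep("A", 45), rep("B", 15), rep("B", 25), rep("A", 15))
  po <- 60 / 100
  pe <- (70 / 100) * (60 / 100) + (30 / 100) * (40 / 100)
  expect_equal(cohens_kappa(a, b), (po - pe) / (1 - pe))

  # independent cross-check against an established implementation
  expect_equal(cohens_kappa(a, b),
               e1071::classAgreement(table(a, b))$kappa)

  # independent random sequences agree only by chance
  set.seed(99)
  x <- sample(c("r", "i"), 4000, TRUE)
  y <- sample(c("r", "i"), 4000, TRUE)
  expect_lt(abs(cohens_kappa(x, y)), 0.05)

  expect_error(cohens_kappa(c("a", "b"), c("a")),
               class = "miascore_validation_error")
})
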