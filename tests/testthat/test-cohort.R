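test_that("the packaged fixture is a valid 17-patient, 38-aneurysm cohort", {
  fx <- table3_fixture()
  expect_s3_class(fx, "mia_cohort")
  expect_identical(cohort_mode(fx), "validation")
  expect_equal(length(unique(fx$patient_id)), 17)
  expect_equal(nrow(fx), 38)
  # exactly one rupture per patient (validation invariant)
  expect_true(all(tapply(fx$ruptured, fx$patient_id, sum) == 1))
  expect_equal(sum(!fx$ruptured), 21)
  # first patient: the pair of irregular PcomA aneurysms
  p1 <- fx[fx$patient_id == "1", ]
  expect_equal(p1$diameter_mm, c(7.9, 7.6))
  expect_equal(as.character(p1$location), c("PcomA", "PcomA"))
  expect_equal(as.character(p1$shape), c("irregular", "irregular"))
  expect_equal(p1$ruptured, c(FALSE, TRUE))
})

test_that("write then read is the identity on all fields", {
  for (co in list(table3_fixture(), random_cohort(8, seed = 3),
                  perfect_cohort())) {
    path <- withr::local_tempfile(fileext = ".csv")
    write_cohort(co, path)
    back <- read_cohort(path)
    expect_equal(as.data.frame(back), as.data.frame(co))
  }
})

test_that("an empty file with header only round-trips to an empty cohort", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("patient_id,aneurysm_id,diameter_mm,location,shape,ruptured", path)
  co <- read_cohort(path)
  expect_equal(nrow(co), 0)
  out <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, out)
  expect_equal(nrow(read_cohort(out)), 0)
})

test_that("a two-aneurysm patient writes exactly two data rows", {
  co <- as_cohort(data.frame(
    patient_id = "p1", aneurysm_id = c("a1", "a2"), diameter_mm = c(5, 3),
    location = c("MCA", "ICA"), shape = "regular", ruptured = c(TRUE, FALSE)
  ))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  expect_length(readLines(path), 3)  # header + 2
})

test_that("vocabulary parsing is case-insensitive with documented synonyms", {
  df <- data.frame(
    patient_id = "p1", aneurysm_id = c("a1", "a2", "a3"),
    diameter_mm = c("3", "14", "5.5"),  # integer diameters parse as reals
    location = c("posterior circulation", "PCOMA", "internal carotid artery"),
    shape = c("Regular", "IRREGULAR", "regular"),
    ruptured = c("No", "1", "false")
  )
  co <- as_cohort(df)
  expect_equal(as.character(co$location), c("PC", "PcomA", "ICA"))
  expect_equal(co$diameter_mm, c(3, 14, 5.5))
  expect_equal(co$ruptured, c(FALSE, TRUE, FALSE))
})

test_that("malformed input raises labelled errors", {
  base <- data.frame(
    patient_id = c("P1", "P1"), aneurysm_id = c("a1", "a2"),
    diameter_mm = c(5, 3), location = c("MCA", "ICA"),
    shape = c("regular", "regular"), ruptured = c(TRUE, FALSE),
    stringsAsFactors = FALSE
  )
  bad_loc <- base; bad_loc$location[2] <- "basilar"
  expect_error(as_cohort(bad_loc), "basilar", class = "miascore_parse_error")

  bad_diam <- base; bad_diam$diameter_mm[1] <- -2
  expect_error(as_cohort(bad_diam), "row 1", class = "miascore_parse_error")

  two_rupt <- base; two_rupt$ruptured <- c(TRUE, TRUE)
  expect_error(as_cohort(two_rupt), "P1", class = "miascore_validation_error")

  zero_rupt <- base; zero_rupt$ruptured <- c(FALSE, FALSE)
  expect_error(as_cohort(zero_rupt), "P1", class = "miascore_validation_error")

  single <- base[1, ]
  expect_error(as_cohort(single), class = "miascore_validation_error")
  expect_silent(as_cohort(single, allow_single = TRUE))

  dup <- base; dup$aneurysm_id <- c("a1", "a1")
  expect_error(as_cohort(dup), class = "miascore_validation_error")
})

test_that("prediction mode tolerates absent rupture labels", {
  df <- data.frame(
    patient_id = "p1", aneurysm_id = c("a1", "a2"),
    diameter_mm = c(5, 3), location = c("MCA", "ICA"), shape = "regular"
  )
  co <- as_cohort(df, mode = "prediction")
  expect_true(all(is.na(co$ruptured)))
  expect_error(as_cohort(df, mode = "validation"),
               class = "miascore_parse_error")
})

test_that("within-patient row order is preserved from file", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "patient_id,aneurysm_id,diameter_mm,location,shape,ruptured",
    "p1,z,4.2,MCA,regular,no",
    "p2,b,3.0,ICA,regular,no",
    "p1,a,6.1,MCA,regular,yes",
    "p2,c,9.9,ICA,regular,yes"
  ), path)
  co <- read_cohort(path)
  expect_equal(co$aneurysm_id[co$patient_id == "p1"], c("z", "a"))
  expect_equal(unique(co$patient_id), c("p1", "p2"))
})
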