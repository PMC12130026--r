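test_that("age below the inclusion threshold is rejected with a clear message", {
  p <- patient_record("kid", age_years = 59L,
                      medications = medication("N02BE01", daily_dose = 500))
  expect_error(as_cohort(p), class = "pimscreen_validation_error",
               regexp = "below the inclusion threshold 60")
})

test_that("an empty medication list violates the inclusion rule", {
  p <- patient_record("m0", medications = medication(character()))
  expect_error(as_cohort(p), class = "pimscreen_validation_error",
               regexp = "non-empty")
})

test_that("unknown condition and indication codes are rejected by name", {
  p <- patient_record("c1", conditions = "totally_made_up",
                      medications = medication("N02BE01", daily_dose = 500))
  expect_error(as_cohort(p), class = "pimscreen_validation_error",
               regexp = "totally_made_up")
  p2 <- patient_record("c2", medications = medication(
    "N02BE01", daily_dose = 500, indication_code = "martian_flu"))
  expect_error(as_cohort(p2), class = "pimscreen_validation_error",
               regexp = "martian_flu")
})

test_that("duplicate patient ids and bad units are rejected", {
  p <- dplyr::bind_rows(baseline_patient("dup"), baseline_patient("dup"))
  expect_error(as_cohort(p), class = "pimscreen_validation_error",
               regexp = "duplicate")
  bad_unit <- patient_record("u", medications = medication(
    "N02BE01", daily_dose = 1, dose_unit = "mcg"))
  expect_error(as_cohort(bad_unit), class = "pimscreen_validation_error",
               regexp = "dose_unit")
})

test_that("labs must be strictly positive and absent labs stay absent", {
  ok <- as_cohort(patient_record("l1", labs = list(egfr = 40),
                                 medications = medication("N02BE01", daily_dose = 500)))
  expect_identical(ok$labs[[1]]$egfr, 40)
  bad <- patient_record("l2", labs = list(egfr = 0),
                        medications = medication("N02BE01", daily_dose = 500))
  expect_error(as_cohort(bad), class = "pimscreen_validation_error",
               regexp = "strictly positive")
})

test_that("medication-count bands partition every count", {
  expect_identical(as.character(medication_count_category(c(1, 3, 4))),
                   c("low", "low", "low"))
  expect_identical(as.character(medication_count_category(c(5, 6, 9))),
                   c("mid", "mid", "mid"))
  expect_identical(as.character(medication_count_category(c(10, 14))),
                   c("high", "high"))
  # partition property over a simulated cohort: band counts sum to n
  co <- simulate_cohort(cohort_spec(n = 80, seed = 11))
  feats <- cohort_features(co)
  expect_identical(sum(table(feats$med_count_category)), 80L)
  expect_false(anyNA(feats$med_count_category))
})

test_that("cohort features carry the study reference levels first", {
  co <- simulate_cohort(cohort_spec(n = 40, seed = 2))
  feats <- cohort_features(co)
  expect_identical(levels(feats$sex), c("female", "male"))
  expect_identical(levels(feats$med_count_category), c("low", "mid", "high"))
  expect_identical(levels(feats$comorbidity_category),
                   c("none", "comorbidity", "multimorbidity"))
  expect_identical(levels(feats$age_band)[1], "60-64")
})
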