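all_ids <- stopp_criteria()$criterion_id

test_that("the criteria catalog holds all 133 identifiers exactly once", {
  expect_length(all_ids, 133L)
  expect_false(anyDuplicated(all_ids) > 0)
  counts <- table(substr(all_ids, 1, 1))
  expect_identical(
    as.integer(counts[c("A", "B", "C", "D", "E", "F", "G",
                        "H", "I", "J", "K", "L", "M")]),
    c(3L, 21L, 16L, 25L, 10L, 8L, 4L, 9L, 8L, 10L, 12L, 6L, 1L)
  )
})

test_that("every criterion has a triggering fixture", {
  for (id in all_ids) {
    u <- trigger_unit(id)
    out <- evaluate_criterion(unit_to_patient(u), id)
    expect_identical(out$status, "triggered", label = paste0(id, " status"))
    expect_gt(length(out$flags[[1]]), 0)
  }
})

test_that("no criterion triggers on the baseline patient", {
  p <- baseline_patient()
  for (id in all_ids) {
    out <- evaluate_criterion(p, id)
    expect_identical(out$status, "not_triggered", label = paste0(id, " status"))
  }
})

test_that("every lab-gated criterion is not_evaluable when its labs are missing", {
  for (id in pimscreen:::LAB_GATED_CRITERIA) {
    u <- pimscreen:::ne_unit(id)
    out <- evaluate_criterion(unit_to_patient(u), id)
    expect_identical(out$status, "not_evaluable", label = paste0(id, " status"))
    expect_gt(length(out$missing_inputs[[1]]), 0)
  }
})

test_that("an unknown first-line qualifier renders first-line clauses not evaluable", {
  p <- patient_record(
    "fl", conditions = "allergy",
    medications = medication("D04AA16", daily_dose = 25, duration_days = 10L,
                             indication_code = "allergy", first_line = NA)
  )
  out <- evaluate_criterion(p, "D24")
  expect_identical(out$status, "not_evaluable")
  expect_identical(out$missing_inputs[[1]], "first_line")
})

test_that("renal NSAID criterion follows the tri-state contract", {
  nsaid <- medication("M01AB05", daily_dose = 75, duration_days = 30L,
                      indication_code = "pain")
  trig <- patient_record("t", labs = list(egfr = 40), medications = nsaid)
  expect_identical(evaluate_criterion(trig, "E4")$status, "triggered")
  ok <- patient_record("o", labs = list(egfr = 75), medications = nsaid)
  expect_identical(evaluate_criterion(ok, "E4")$status, "not_triggered")
  unk <- patient_record("u", medications = nsaid)
  out <- evaluate_criterion(unk, "E4")
  expect_identical(out$status, "not_evaluable")
  expect_identical(out$missing_inputs[[1]], "egfr")
})

test_that("long-term high-dose aspirin triggers the dose criterion", {
  p <- patient_record("c1", medications = medication(
    "B01AC06", daily_dose = 150, duration_days = 120L,
    indication_code = "coronary_artery_disease"))
  expect_identical(evaluate_criterion(p, "C1")$status, "triggered")
  # at 75 mg, or short-term, it does not
  p75 <- patient_record("c2", medications = medication(
    "B01AC06", daily_dose = 75, duration_days = 120L,
    indication_code = "coronary_artery_disease"))
  expect_identical(evaluate_criterion(p75, "C1")$status, "not_triggered")
})

test_that("a vacuous drug clause yields not_triggered, not an error", {
  p <- baseline_patient()
  expect_identical(evaluate_criterion(p, "B5")$status, "not_triggered")
})

test_that("pheniramine first-line for allergy yields exactly one flag (D24)", {
  p <- unit_to_patient(trigger_unit("D24"))
  flags <- screen_patient(p)
  expect_identical(nrow(flags), 1L)
  expect_identical(flags$criterion_id, "D24")
  expect_identical(flags$atc_codes[[1]], "D04AA16")
})

test_that("two concurrent regular NSAIDs raise the duplicate-class flag", {
  p <- patient_record("a3", labs = list(egfr = 40), medications = dplyr::bind_rows(
    medication("M01AB05", daily_dose = 75, duration_days = 30L,
               indication_code = "pain"),
    medication("M01AE01", daily_dose = 1200, duration_days = 30L,
               indication_code = "pain")
  ))
  flags <- screen_patient(p)
  expect_true("A3" %in% flags$criterion_id)
  # the lab-dependent NSAID flags fire per drug alongside
  expect_identical(sum(flags$criterion_id == "E4"), 2L)
  # but PRN duplicates do not count
  prn <- patient_record("a3p", medications = dplyr::bind_rows(
    medication("M01AB05", daily_dose = 75, prn = TRUE, indication_code = "pain"),
    medication("M01AE01", daily_dose = 1200, prn = TRUE, indication_code = "pain")
  ))
  expect_identical(evaluate_criterion(prn, "A3")$status, "not_triggered")
})

test_that("the anticholinergic-burden criterion needs two regular drugs", {
  p <- unit_to_patient(trigger_unit("M1"))
  out <- evaluate_criterion(p, "M1")
  expect_identical(out$status, "triggered")
  # one flag naming both concomitant anticholinergics
  expect_length(out$flags[[1]], 1L)
  expect_length(out$flags[[1]][[1]], 2L)
  one <- patient_record("m", medications = medication(
    "D04AA16", daily_dose = 25, indication_code = "allergy", first_line = FALSE))
  expect_identical(evaluate_criterion(one, "M1")$status, "not_triggered")
})

test_that("QTc threshold is sex-specific", {
  qtc_drug <- medication("N05AD01", daily_dose = 2, indication_code = "psychosis")
  male460 <- patient_record("m", sex = "male", conditions = "psychosis",
                            labs = list(qtc_ms = 460), medications = qtc_drug)
  female460 <- patient_record("f", sex = "female", conditions = "psychosis",
                              labs = list(qtc_ms = 460), medications = qtc_drug)
  expect_identical(evaluate_criterion(male460, "B15")$status, "triggered")
  expect_identical(evaluate_criterion(female460, "B15")$status, "not_triggered")
})

test_that("unknown criterion ids raise a typed error", {
  expect_error(evaluate_criterion(baseline_patient(), "Z9"),
               class = "pimscreen_criterion_error")
})
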