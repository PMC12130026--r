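test_that("a zero-size or invalid spec is refused", {
  expect_error(cohort_spec(n = 0), class = "pimscreen_validation_error")
  expect_error(cohort_spec(sex_p_male = 1.2),
               class = "pimscreen_validation_error")
  expect_error(cohort_spec(age_band_probs = rep(0.25, 4)),
               class = "pimscreen_validation_error")
  expect_error(cohort_spec(criterion_trigger_rates = c(Z9 = 0.1)),
               class = "pimscreen_validation_error")
})

test_that("the same spec and seed give byte-identical serialized cohorts", {
  spec <- cohort_spec(n = 50, seed = 123)
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_cohort(simulate_cohort(spec), f1)
  write_cohort(simulate_cohort(spec), f2)
  expect_identical(readLines(f1), readLines(f2))
  # a different seed changes the cohort
  f3 <- withr::local_tempfile(fileext = ".json")
  write_cohort(simulate_cohort(cohort_spec(n = 50, seed = 124)), f3)
  expect_false(identical(readLines(f1), readLines(f3)))
})

test_that("generated cohorts satisfy every domain invariant", {
  co <- simulate_cohort(cohort_spec(n = 200, seed = 6))
  expect_true(validate_cohort(co))
  expect_true(all(vapply(co$medications, nrow, integer(1)) >= 1L))
  expect_true(all(co$age_years >= 60L))
})

test_that("marginal frequencies converge to the spec probabilities", {
  co <- simulate_cohort(cohort_spec(n = 10000, seed = 314))
  expect_lt(abs(mean(co$sex == "male") - 0.553), 0.02)
  feats <- cohort_features(co)
  expect_lt(abs(mean(feats$age_band == "60-64") - 114 / 450), 0.02)
  hyper <- mean(vapply(co$conditions, function(x) "hypertension" %in% x,
                       logical(1)))
  # triggers add a few hypertensive contexts on top of the 0.496 baseline
  expect_lt(abs(hyper - 0.496), 0.12)
})

test_that("planted null effects recover odds ratios near one", {
  null_eff <- default_planted_effects()
  null_eff[c("sex_male", "med_mid", "med_high",
             "comorbidity", "multimorbidity")] <- list(0, 0, 0, 0, 0)
  null_eff$age_band[] <- 0
  null_eff$intercept <- 0
  set.seed(77)
  feats <- tibble::tibble(
    sex = factor(sample(c("female", "male"), 5000, TRUE),
                 levels = c("female", "male")),
    age_band = factor("60-64", levels = pimscreen:::AGE_BANDS),
    med_count_category = factor(sample(c("low", "mid", "high"), 5000, TRUE),
                                levels = c("low", "mid", "high")),
    comorbidity_category = factor("none",
                                  levels = c("none", "comorbidity",
                                             "multimorbidity"))
  )
  feats <- plant_pim_exposure(feats, null_eff, seed = 78)
  fit <- fit_pim_logistic(feats, outcome = "pim",
                          terms = c("sex", "med_count_category"))
  ors <- tidy(fit)
  expect_true(all(abs(log(ors$odds_ratio[!ors$reference])) < 0.25))
})

test_that("a large planted medication effect is recovered consistently", {
  eff <- default_planted_effects()
  set.seed(555)
  feats <- tibble::tibble(
    sex = factor(sample(c("female", "male"), 50000, TRUE,
                        prob = c(0.447, 0.553)), levels = c("female", "male")),
    age_band = factor(sample(pimscreen:::AGE_BANDS, 50000, TRUE),
                      levels = pimscreen:::AGE_BANDS),
    med_count_category = factor(sample(c("low", "mid", "high"), 50000, TRUE),
                                levels = c("low", "mid", "high")),
    comorbidity_category = factor(
      sample(c("none", "comorbidity", "multimorbidity"), 50000, TRUE),
      levels = c("none", "comorbidity", "multimorbidity"))
  )
  feats <- plant_pim_exposure(feats, eff, seed = 556)
  fit <- fit_pim_logistic(feats, outcome = "pim",
                          terms = c("sex", "age_band", "med_count_category",
                                    "comorbidity_category"))
  td <- tidy(fit)
  mid <- td$odds_ratio[td$term == "med_count_category" & td$level == "mid"]
  expect_gt(mid, 2.7); expect_lt(mid, 3.1)
})
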