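test_that("crude odds ratios reproduce hand-computed values", {
  # ad/bc on small frozen tables: 2*3/(1*4) = 1.5; 10*10/(10*10) = 1
  expect_equal(tidy(crude_or(2, 1, 4, 3))$odds_ratio, 1.5)
  sym <- crude_or(10, 10, 10, 10)
  expect_equal(sym$odds_ratio, 1)
  # CI symmetric about 1 on the log scale
  expect_equal(sym$ci_low * sym$ci_high, 1, tolerance = 1e-12)
})

test_that("zero cells error and the continuity correction rescues them", {
  expect_error(crude_or(5, 0, 3, 4), class = "pimscreen_zero_cell_error")
  res <- crude_or(5, 0, 3, 4, correction = TRUE)
  expect_equal(res$odds_ratio, (5.5 * 4.5) / (0.5 * 3.5))
})

test_that("crude OR equals a one-covariate logistic fit to 1e-6", {
  tab <- expand.grid(exposed = c(1, 0), pim = c(1, 0))
  tab$n <- c(37, 19, 23, 41)
  rows <- tab[rep(seq_len(4), tab$n), c("exposed", "pim")]
  fit <- fit_pim_logistic(rows, outcome = "pim", terms = "exposed")
  or_glm <- exp(coef(fit$fit)[["exposed"]])
  or_table <- crude_or(37, 23, 19, 41)$odds_ratio
  expect_equal(or_glm, or_table, tolerance = 1e-6)
})

test_that("the bivariate screen selects a perfectly associated exposure", {
  d <- data.frame(x = rep(c("a", "b"), each = 50),
                  y = rep(c(1, 0), each = 50))
  out <- bivariate_screen(d, "y", "x")
  expect_true(out$selected)
  expect_lt(out$p_value, 1e-10)
})

test_that("the screen's type-I rate under independence matches its 0.25 cut", {
  set.seed(99)
  hits <- vapply(1:400, function(i) {
    d <- data.frame(x = sample(c("a", "b"), 200, TRUE),
                    y = rbinom(200, 1, 0.5))
    bivariate_screen(d, "y", "x")$selected
  }, logical(1))
  # nominal 0.25; binomial(400, .25) gives sd ~ 0.022
  expect_gt(mean(hits), 0.17)
  expect_lt(mean(hits), 0.33)
})

test_that("tiny expected cells fall back to the exact test", {
  set.seed(3)
  d <- data.frame(x = c(rep("a", 2), rep("b", 200)),
                  y = c(1, 1, rbinom(200, 1, 0.97)))
  out <- bivariate_screen(d, "y", "x")
  expect_identical(out$test, "fisher_exact")
})

test_that("sample size formula matches its closed form and is monotone", {
  expect_identical(sample_size(0.5, 0.05, 1.96, 0), 385L) # ceiling(384.16)
  expect_identical(sample_size(0.64, 0.05, 1.96, 0.20), 425L)
  # decreasing d, or moving p toward one half, never decreases n
  expect_gte(sample_size(0.64, 0.02), sample_size(0.64, 0.05))
  expect_gte(sample_size(0.5, 0.05), sample_size(0.3, 0.05))
  # degenerate precision bound returns the minimum of one participant
  expect_identical(sample_size(0.5, 1e6), 1L)
  expect_error(sample_size(1.2, 0.05), class = "pimscreen_validation_error")
  expect_error(sample_size(0.5, 0.05, attrition = 1),
               class = "pimscreen_validation_error")
})

test_that("separation raises a diagnostic error rather than silent output", {
  d <- data.frame(x = rep(c(0, 1), each = 20), pim = rep(c(0, 1), each = 20))
  expect_error(fit_pim_logistic(d, outcome = "pim", terms = "x"),
               class = "pimscreen_convergence_error")
})

test_that("reference levels carry OR exactly 1 with no interval", {
  co <- simulate_cohort(cohort_spec(n = 150, seed = 31))
  feats <- plant_pim_exposure(cohort_features(co), seed = 4)
  fit <- fit_pim_logistic(feats, outcome = "pim",
                          terms = c("sex", "med_count_category"))
  td <- tidy(fit)
  refs <- td[td$reference, ]
  expect_identical(refs$level, c("female", "low"))
  expect_true(all(refs$odds_ratio == 1))
  expect_true(all(is.na(refs$ci_low)))
  g <- glance(fit)
  expect_true(g$converged)
  expect_equal(g$n_obs, 150)
})

test_that("cohort summary medians use the study display convention", {
  ages <- as_cohort(dplyr::bind_rows(lapply(1:5, function(i) {
    patient_record(paste0("s", i), age_years = 70L,
                   medications = medication("N02BE01", daily_dose = 500,
                                            indication_code = "pain"))
  })))
  s <- summarize_cohort(ages)
  expect_identical(s$overview$age_median_iqr, "70 (70-70)")
  # percentages within a categorical block sum to 100 up to rounding
  co <- simulate_cohort(cohort_spec(n = 90, seed = 17))
  s2 <- summarize_cohort(co)
  for (block in list(s2$age_bands, s2$sex, s2$medication_bands,
                     s2$comorbidity)) {
    expect_lt(abs(sum(block$percent) - 100), 0.5)
  }
})
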