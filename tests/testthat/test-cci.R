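# Expected scores below were computed independently from the original
# Charlson weight table (MI 1, CHF 1, PVD 1, cerebrovascular 1, dementia 1,
# chronic pulmonary 1, connective tissue 1, ulcer 1, mild liver 1,
# diabetes 1; hemiplegia 2, renal 2, diabetes with end-organ damage 2,
# malignancy 2; severe liver 3; metastatic tumour 6, AIDS 6) and frozen.

test_that("no conditions give score zero and band none", {
  res <- cci_score(character())
  expect_identical(res$score, 0L)
  expect_identical(res$band, "none")
})

test_that("frozen oracle scores reproduce", {
  expect_identical(cci_score(c("myocardial_infarction", "diabetes_t2"))$score, 2L)
  expect_identical(cci_score(c("myocardial_infarction", "diabetes_t2"))$band, "mild")
  expect_identical(cci_score("metastatic_tumor")$score, 6L)
  expect_identical(cci_score("metastatic_tumor")$band, "severe")
  expect_identical(cci_score(c("heart_failure", "copd", "renal_failure"))$score, 4L)
  expect_identical(cci_score(c("hypertension"))$score, 0L) # not a Charlson item
})

test_that("severity hierarchies keep only the heavier member", {
  expect_identical(cci_score(c("diabetes_t2", "diabetes_end_organ"))$score, 2L)
  expect_identical(cci_score(c("chronic_liver_disease", "liver_failure"))$score, 3L)
  expect_identical(cci_score(c("cancer", "metastatic_tumor"))$score, 6L)
  # two codes mapping to one item count once
  expect_identical(cci_score(c("stroke", "cerebrovascular_disease"))$score, 1L)
})

test_that("band mapping is a total function of the score", {
  expect_identical(cci_band(0), "none")
  expect_identical(cci_band(c(1, 2)), c("mild", "mild"))
  expect_identical(cci_band(c(3, 4)), c("moderate", "moderate"))
  expect_identical(cci_band(c(5, 11)), c("severe", "severe"))
})

test_that("score is monotone under adding conditions", {
  vocab <- condition_vocabulary()$code
  set.seed(404)
  for (k in 1:50) {
    base <- sample(vocab, sample(0:6, 1))
    extra <- sample(vocab, 1)
    expect_gte(cci_score(union(base, extra))$score, cci_score(base)$score)
  }
})

test_that("comorbidity trichotomy counts qualifying chronic conditions", {
  expect_identical(comorbidity_category(character()), "none")
  expect_identical(comorbidity_category("hypertension"), "comorbidity")
  expect_identical(comorbidity_category(c("hypertension", "diabetes_t2")),
                   "multimorbidity")
  # acute conditions do not qualify
  expect_identical(comorbidity_category(c("allergy", "gout")), "none")
  expect_identical(comorbidity_category(c("hypertension", "allergy")),
                   "comorbidity")
})
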