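test_that("classify resolves packaged codes to their drug-class tags", {
  expect_setequal(classify("B01AC06"), c("aspirin", "antiplatelet"))
  expect_true("antihistamine_first_gen" %in% classify("D04AA16"))
  expect_true("anticholinergic" %in% classify("D04AA16"))
  # one code may carry several tags
  expect_true(all(c("beta_blocker", "pgp_inhibitor") %in% classify("C07AG02")))
})

test_that("classify is a pure, deterministic lookup", {
  expect_identical(classify("C03CA01"), classify("C03CA01"))
})

test_that("unknown-but-valid codes return an empty set with a warning", {
  expect_warning(tags <- classify("Z99ZZ99"), "not in packaged catalog")
  expect_length(tags, 0)
})

test_that("malformed codes raise a typed error", {
  expect_error(classify("b01ac06"), class = "pimscreen_atc_error")
  expect_error(classify("B1AC06"), class = "pimscreen_atc_error")
  expect_error(classify(""), class = "pimscreen_atc_error")
})

test_that("every drug in the reference attribution table resolves to tags", {
  top20 <- c("A10BB12", "A10BG03", "B01AA03", "B01AB05", "B01AC04",
             "B01AC06", "C01AA05", "C01DA02", "C02DB02", "C03CA01",
             "C07AB03", "C07AB07", "C07AG02", "D04AA16", "H02AB09",
             "M01AB05", "N02AX02", "N03AE01", "N04AA04", "N05AX08")
  tags <- classify(top20)
  expect_true(all(lengths(tags) > 0))
})

test_that("anticholinergic burden counts distinct regular anticholinergics", {
  expect_identical(anticholinergic_burden(medication(character())), 0L)
  two <- medication(c("D04AA16", "N06AA09"), daily_dose = 25)
  expect_identical(anticholinergic_burden(two), 2L)
  prn_only <- medication("D04AA16", daily_dose = 25, prn = TRUE)
  expect_identical(anticholinergic_burden(prn_only), 0L)
  # non-anticholinergic drugs never count
  expect_identical(anticholinergic_burden(medication("N02BE01", daily_dose = 500)), 0L)
})
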