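# Canonical triggering prescriptions ("units") for every criterion.
#
# A unit is the minimal bundle of medication orders, coded conditions and
# laboratory values that satisfies one criterion exactly once.  Units serve
# three masters: the per-criterion unit tests, the synthetic-cohort
# generator (which attaches them at the configured trigger rates), and the
# deterministic benchmark cohort (which places them by direct construction).

unit_spec <- function(criterion, meds, conds = character(), labs = list(),
                      sex = NA_character_, age = NA_integer_) {
  list(criterion = criterion, meds = meds, conds = conds, labs = labs,
       sex = sex, age = age)
}

# shorthand used below
m <- function(atc, dose = 0, unit = "mg", route = "oral", prn = FALSE,
              dur = 30L, ind = NA_character_, fl = NA) {
  medication(atc, daily_dose = dose, dose_unit = unit, route = route,
             prn = prn, duration_days = dur, indication_code = ind,
             first_line = fl)
}

#' Canonical triggering prescription for a criterion
#'
#' Returns the packaged example unit that satisfies the given criterion:
#' the medication orders, conditions and laboratory values involved.  Some
#' criteria have several drug variants (used to spread drug attribution in
#' the benchmark cohort).
#'
#' @param criterion_id Criterion identifier, e.g. `"E4"`.
#' @param variant Integer variant selector (default 1).
#' @return A list with elements `criterion`, `meds`, `conds`, `labs`,
#'   `sex`, `age`.
#' @export
trigger_unit <- function(criterion_id, variant = 1L) {
  v <- variant
  u <- switch(
    criterion_id,
    A1 = unit_spec("A1", m("B01AC06", 75, ind = "none")),
    A2 = unit_spec("A2", m("J01CA04", 1500, dur = 21L, ind = "infection")),
    A3 = switch(v,
      unit_spec("A3", dplyr::bind_rows(
        m("C03CA01", 40, ind = "heart_failure"),
        m("C03CA04", 10, ind = "heart_failure")), conds = "heart_failure"),
      unit_spec("A3", dplyr::bind_rows(
        m("B01AA03", 5, ind = "dvt_history"),
        m("B01AB05", 40, ind = "dvt_history")), conds = "dvt_history"),
      unit_spec("A3", dplyr::bind_rows(
        m("N06AB03", 20, ind = "depression", fl = FALSE),
        m("N06AB06", 50, ind = "depression", fl = FALSE)),
        conds = "depression")
    ),
    B1 = unit_spec("B1", m("C01AA05", 62.5, unit = "ug", ind = "heart_failure"),
                   conds = "heart_failure_preserved_ef"),
    B2 = unit_spec("B2", m("C08DB01", 120, ind = "heart_failure"),
                   conds = "heart_failure_nyha34"),
    B3 = unit_spec("B3", dplyr::bind_rows(
      m("C07AB03", 50, ind = "hypertension"),
      m("C08DA01", 120, ind = "hypertension")), conds = "hypertension"),
    B4 = unit_spec("B4", m("C08DA01", 120, ind = "hypertension"),
                   conds = "bradycardia"),
    B5 = {
      drug <- c("C07AB03", "C07AB07", "C07AG02", "C07AA05", "C07AB02")[[v]]
      dose <- c(50, 5, 12.5, 40, 50)[[v]]
      unit_spec("B5", m(drug, dose, ind = "hypertension"),
                conds = "hypertension")
    },
    B6 = unit_spec("B6", m("C01BD01", 200, ind = "svt", fl = TRUE),
                   conds = "svt"),
    B7 = unit_spec("B7", m("C03CA01", 40, ind = "hypertension", fl = TRUE),
                   conds = "hypertension"),
    B8 = unit_spec("B8", m("C03CA01", 40, ind = "ankle_edema")),
    B9 = unit_spec("B9", m("C03AA03", 25, ind = "hypertension"),
                   conds = "hypertension", labs = list(serum_k = 2.5)),
    B10 = unit_spec("B10", m("C03CA01", 40, ind = "hypertension"),
                    conds = c("hypertension", "urinary_incontinence")),
    B11 = unit_spec("B11", m("C02AB01", 500, ind = "hypertension"),
                    conds = "hypertension"),
    B12 = unit_spec("B12", m("C09AA03", 10, ind = "hypertension"),
                    conds = "hypertension", labs = list(serum_k = 6.0)),
    B13 = unit_spec("B13", dplyr::bind_rows(
      m("C03DA01", 25, ind = "heart_failure"),
      m("C09AA03", 10, ind = "heart_failure")), conds = "heart_failure"),
    B14 = unit_spec("B14", dplyr::bind_rows(
      m("G04BE03", 50, ind = "angina"),
      m("C01DA14", 60, ind = "angina")), conds = "angina"),
    B15 = switch(v,
      unit_spec("B15", m("J01FA09", 500, dur = 7L, ind = "infection"),
                labs = list(qtc_ms = 470), sex = "male"),
      unit_spec("B15", m("N06AB10", 20, ind = "depression", fl = FALSE),
                conds = "depression", labs = list(qtc_ms = 480),
                sex = "female")
    ),
    B16 = unit_spec("B16", m("C10AA05", 20, ind = "primary_cv_prevention"),
                    conds = c("primary_cv_prevention",
                              "frailty_limited_life_expectancy"),
                    age = 86L),
    B17 = unit_spec("B17", m("M01AE01", 1200, dur = 120L, ind = "pain"),
                    conds = "coronary_artery_disease"),
    B18 = unit_spec("B18", m("N05AX08", 2, dur = 100L, ind = "psychosis"),
                    conds = "cerebrovascular_disease"),
    B19 = unit_spec("B19", dplyr::bind_rows(
      m("M01AE01", 1200, ind = "pain"),
      m("C03CA01", 40, ind = "heart_failure")), conds = "heart_failure"),
    B20 = unit_spec("B20", m("C08CA01", 5, ind = "hypertension"),
                    conds = c("hypertension", "severe_aortic_stenosis")),
    B21 = unit_spec("B21", m("C01AA05", 62.5, unit = "ug", dur = 120L,
                             ind = "atrial_fibrillation", fl = TRUE),
                    conds = "atrial_fibrillation"),
    C1 = unit_spec("C1", m("B01AC06", 150, dur = 120L,
                           ind = "coronary_artery_disease")),
    C2 = unit_spec("C2", m("B01AC06", 75, ind = "coronary_artery_disease"),
                   conds = "bleeding_diathesis"),
    C3 = unit_spec("C3", dplyr::bind_rows(
      m("B01AC06", 75, dur = 40L, ind = "stroke_prevention"),
      m("B01AC04", 75, dur = 40L, ind = "stroke_prevention")),
      conds = "stroke"),
    C4 = unit_spec("C4", dplyr::bind_rows(
      m("B01AC06", 75, ind = "stroke_prevention"),
      m("B01AA03", 5, ind = "atrial_fibrillation", fl = FALSE)),
      conds = "atrial_fibrillation"),
    C5 = {
      partner <- c("B01AA03", "B01AF01", "B01AF02", "B01AE07")[[v]]
      pdose <- c(5, 20, 5, 150)[[v]]
      unit_spec("C5", dplyr::bind_rows(
        m("B01AC06", 75, ind = "coronary_artery_disease"),
        m(partner, pdose, ind = "coronary_artery_disease", fl = FALSE)),
        conds = "coronary_artery_disease")
    },
    C6 = unit_spec("C6", m("B01AC05", 500, ind = "stroke_prevention")),
    C7 = unit_spec("C7", m("B01AC06", 75, ind = "stroke_prevention"),
                   conds = "atrial_fibrillation"),
    C8 = unit_spec("C8", m("B01AA03", 5, dur = 200L, ind = "dvt_history"),
                   conds = "dvt_history"),
    C9 = unit_spec("C9", m("B01AA03", 5, dur = 200L, ind = "pe_history"),
                   conds = "pe_history"),
    C10 = unit_spec("C10", dplyr::bind_rows(
      m("M01AE01", 1200, ind = "pain"),
      m("B01AA03", 5, dur = 60L, ind = "dvt_history", fl = FALSE)),
      conds = "dvt_history"),
    C11 = unit_spec("C11", m("B01AA03", 5, ind = "atrial_fibrillation",
                             fl = TRUE),
                    conds = "atrial_fibrillation", labs = list(egfr = 80)),
    C12 = unit_spec("C12", dplyr::bind_rows(
      m("N06AB06", 50, ind = "depression", fl = FALSE),
      m("B01AA03", 5, ind = "dvt_history", fl = FALSE)),
      conds = c("depression", "dvt_history", "major_hemorrhage_history")),
    C13 = unit_spec("C13", dplyr::bind_rows(
      m("B01AE07", 150, ind = "atrial_fibrillation"),
      m("C08DA01", 120, ind = "hypertension")),
      conds = c("atrial_fibrillation", "hypertension")),
    C14 = unit_spec("C14", dplyr::bind_rows(
      m("B01AF01", 20, ind = "atrial_fibrillation"),
      m("C07AG02", 12.5, ind = "heart_failure")),
      conds = c("atrial_fibrillation", "heart_failure")),
    C15 = unit_spec("C15", m("G03CA03", 2, ind = "hormone_replacement"),
                    conds = "dvt_history", sex = "female"),
    C16 = unit_spec("C16", m("B01AC06", 75, ind = "primary_cv_prevention"),
                    conds = "primary_cv_prevention"),
    D1 = unit_spec("D1", m("N06AA09", 25, ind = "depression", fl = FALSE),
                   conds = c("depression", "narrow_angle_glaucoma")),
    D2 = unit_spec("D2", m("N06AA09", 25, ind = "depression", fl = TRUE),
                   conds = "depression"),
    D3 = unit_spec("D3", m("N06AX16", 75, ind = "depression", fl = FALSE),
                   conds = "depression", labs = list(systolic_bp = 190)),
    D4 = unit_spec("D4", m("N05AH03", 10, ind = "psychosis"),
                   conds = c("psychosis", "bph_luts")),
    D5 = unit_spec("D5", m("N05AX08", 1, dur = 100L, ind = "bpsd"),
                   conds = "dementia"),
    D6 = unit_spec("D6", m("N06AB06", 50, ind = "depression", fl = FALSE),
                   conds = "depression", labs = list(serum_na = 125)),
    D7 = unit_spec("D7", m("N06AB06", 50, ind = "depression", fl = FALSE),
                   conds = c("depression", "recent_bleeding")),
    D8 = unit_spec("D8", m("N05BA01", 5, dur = 60L, ind = "anxiety")),
    D9 = unit_spec("D9", m("N05BA06", 1, dur = 10L, ind = "bpsd"),
                   conds = "dementia"),
    D10 = unit_spec("D10", m("N03AE01", 0.5, dur = 20L, ind = "insomnia")),
    D11 = unit_spec("D11", m("N05CF02", 10, dur = 20L, ind = "insomnia")),
    D12 = unit_spec("D12", m("N05AD01", 2, ind = "psychosis"),
                    conds = c("psychosis", "parkinsonism")),
    D13 = unit_spec("D13", dplyr::bind_rows(
      m("N04AA04", 10, ind = "eps"),
      m("N05AD01", 2, ind = "psychosis")), conds = "psychosis"),
    D14 = unit_spec("D14", m("N04AA04", 10, ind = "tremor"),
                    conds = "delirium"),
    D15 = unit_spec("D15", m("N05AX08", 1, dur = 100L, ind = "ncsd"),
                    conds = "dementia"),
    D16 = unit_spec("D16", m("N05AH04", 50, dur = 10L, ind = "insomnia")),
    D17 = unit_spec("D17", m("N06DA02", 10, ind = "dementia"),
                    conds = c("dementia", "bradycardia")),
    D18 = unit_spec("D18", dplyr::bind_rows(
      m("N06DA02", 10, ind = "dementia"),
      m("C07AB03", 50, ind = "hypertension")),
      conds = c("dementia", "hypertension")),
    D19 = unit_spec("D19", m("N06DX01", 10, ind = "dementia"),
                    conds = c("dementia", "seizure_history")),
    D20 = unit_spec("D20", m("N06BX03", 2400, ind = "dementia"),
                    conds = "dementia"),
    D21 = unit_spec("D21", m("N05AA01", 75, ind = "psychosis", fl = TRUE),
                    conds = "psychosis"),
    D22 = unit_spec("D22", m("N04BA02", 300, ind = "tremor"),
                    conds = "essential_tremor"),
    D23 = unit_spec("D23", m("N04BC05", 1, ind = "eps"),
                    conds = "drug_induced_parkinsonism"),
    D24 = unit_spec("D24", m("D04AA16", 25, dur = 10L, ind = "allergy",
                             fl = TRUE), conds = "allergy"),
    D25 = unit_spec("D25", m("R06AA02", 50, dur = 5L, ind = "insomnia")),
    E1 = unit_spec("E1", m("C01AA05", 250, unit = "ug", dur = 120L,
                           ind = "atrial_fibrillation", fl = FALSE),
                   conds = "atrial_fibrillation", labs = list(egfr = 25)),
    E2 = unit_spec("E2", m("B01AE07", 150, ind = "dvt_history"),
                   conds = "dvt_history", labs = list(egfr = 25)),
    E3 = unit_spec("E3", m("B01AF01", 20, ind = "dvt_history"),
                   conds = "dvt_history", labs = list(egfr = 12)),
    E4 = switch(v,
      unit_spec("E4", m("B01AC06", 75, ind = "coronary_artery_disease"),
                conds = "coronary_artery_disease", labs = list(egfr = 40)),
      unit_spec("E4", m("M01AB05", 75, ind = "pain"),
                labs = list(egfr = 40))
    ),
    E5 = unit_spec("E5", m("M04AC01", 1, dur = 10L, ind = "gout_prophylaxis"),
                   conds = "gout", labs = list(egfr = 8)),
    E6 = unit_spec("E6", m("A10BA02", 1000, ind = "diabetes_t2"),
                   conds = "diabetes_t2", labs = list(egfr = 25)),
    E7 = unit_spec("E7", m("C03DA01", 25, ind = "heart_failure"),
                   conds = "heart_failure", labs = list(egfr = 25, serum_k = 4.5)),
    E8 = unit_spec("E8", m("J01XE01", 100, dur = 5L, ind = "infection"),
                   labs = list(egfr = 40)),
    E9 = unit_spec("E9", m("M05BA04", 10, ind = "osteoporosis"),
                   conds = "osteoporosis", labs = list(egfr = 25)),
    E10 = unit_spec("E10", m("L04AX03", 2.5, ind = "rheumatoid_arthritis"),
                    conds = "rheumatoid_arthritis", labs = list(egfr = 25)),
    F1 = unit_spec("F1", m("A03FA01", 30, ind = "nausea"),
                   conds = "parkinsonism"),
    F2 = unit_spec("F2", m("A02BC01", 40, dur = 70L, ind = "peptic_ulcer"),
                   conds = "peptic_ulcer"),
    F3 = unit_spec("F3", m("B03AA07", 200, ind = "anemia"),
                   conds = "chronic_constipation"),
    F4 = unit_spec("F4", m("B03AA07", 900, ind = "anemia"),
                   conds = "anemia"),
    F5 = unit_spec("F5", m("H02AB09", 100, ind = "allergy"),
                   conds = "peptic_ulcer"),
    F6 = unit_spec("F6", m("B01AC06", 75, ind = "coronary_artery_disease"),
                   conds = "gave"),
    F7 = unit_spec("F7", m("N05AX08", 1, ind = "psychosis"),
                   conds = c("psychosis", "dysphagia")),
    F8 = unit_spec("F8", m("L02AB01", 160, ind = "appetite_stimulation")),
    G1 = unit_spec("G1", m("R03DA04", 200, ind = "copd"), conds = "copd"),
    G2 = switch(v,
      unit_spec("G2", m("H02AB09", 100, ind = "copd"), conds = "copd"),
      unit_spec("G2", m("H02AB06", 30, ind = "copd"), conds = "copd")
    ),
    G3 = unit_spec("G3", m("R03BB04", 0.018, route = "inhaled", ind = "copd"),
                   conds = c("copd", "narrow_angle_glaucoma")),
    G4 = unit_spec("G4", m("N05BA01", 5, dur = 5L, ind = "anxiety"),
                   conds = "respiratory_failure"),
    H1 = unit_spec("H1", m("M01AE01", 1200, ind = "pain"),
                   conds = "peptic_ulcer"),
    H2 = unit_spec("H2", m("M01AE01", 1200, ind = "pain"),
                   labs = list(systolic_bp = 180, diastolic_bp = 95)),
    H3 = unit_spec("H3", m("M01AB05", 100, dur = 120L, ind = "osteoarthritis"),
                   conds = "osteoarthritis"),
    H4 = unit_spec("H4", m("H02AB06", 10, dur = 120L,
                           ind = "rheumatoid_arthritis"),
                   conds = "rheumatoid_arthritis"),
    H5 = unit_spec("H5", m("H02AB06", 10, ind = "osteoarthritis"),
                   conds = "osteoarthritis"),
    H6 = unit_spec("H6", m("M01AE02", 500, dur = 120L,
                           ind = "gout_prophylaxis"), conds = "gout"),
    H7 = unit_spec("H7", dplyr::bind_rows(
      m("M01AE01", 1200, ind = "rheumatoid_arthritis"),
      m("H02AB06", 10, ind = "rheumatoid_arthritis")),
      conds = "rheumatoid_arthritis"),
    H8 = unit_spec("H8", m("M05BA04", 10, route = "oral", ind = "osteoporosis"),
                   conds = c("osteoporosis", "peptic_ulcer")),
    H9 = unit_spec("H9", m("N02AX02", 100, dur = 120L, ind = "osteoarthritis",
                           fl = FALSE),
                   conds = "osteoarthritis"),
    I1 = unit_spec("I1", m("G04BD04", 5, ind = "overactive_bladder"),
                   conds = c("overactive_bladder", "dementia")),
    I2 = unit_spec("I2", m("G04BD04", 5, ind = "overactive_bladder"),
                   conds = c("overactive_bladder", "narrow_angle_glaucoma")),
    I3 = unit_spec("I3", m("G04BD04", 5, ind = "overactive_bladder"),
                   conds = c("overactive_bladder", "bph_luts",
                             "high_post_void_residual")),
    I4 = unit_spec("I4", m("G04BD04", 5, ind = "overactive_bladder"),
                   conds = c("overactive_bladder", "chronic_constipation")),
    I5 = unit_spec("I5", m("G04CA02", 0.4, ind = "bph_luts"),
                   conds = c("bph_luts", "orthostatic_hypotension")),
    I6 = unit_spec("I6", m("G04BD12", 50, ind = "overactive_bladder"),
                   conds = c("overactive_bladder",
                             "uncontrolled_hypertension")),
    I7 = unit_spec("I7", m("N06AX21", 40, ind = "urge_incontinence"),
                   conds = "urge_incontinence"),
    I8 = unit_spec("I8", m("J01CA04", 1500, dur = 5L,
                           ind = "asymptomatic_bacteriuria"),
                   conds = "asymptomatic_bacteriuria"),
    J1 = switch(v,
      unit_spec("J1", m("A10BB12", 4, ind = "diabetes_t2"),
                conds = "diabetes_t2"),
      unit_spec("J1", m("A10BB01", 5, ind = "diabetes_t2"),
                conds = "diabetes_t2")
    ),
    J2 = unit_spec("J2", m("A10BG03", 30, ind = "diabetes_t2"),
                   conds = c("diabetes_t2", "heart_failure")),
    J3 = unit_spec("J3", m("C07AA05", 40, ind = "hypertension"),
                   conds = c("diabetes_t2", "frequent_hypoglycemia")),
    J4 = unit_spec("J4", m("A10BK03", 10, ind = "diabetes_t2"),
                   conds = c("diabetes_t2", "symptomatic_hypotension")),
    J5 = unit_spec("J5", m("G03CA03", 2, ind = "hormone_replacement"),
                   conds = "breast_cancer", sex = "female"),
    J6 = unit_spec("J6", m("G03CA03", 2, ind = "hormone_replacement"),
                   conds = "dvt_history", sex = "female"),
    J7 = unit_spec("J7", dplyr::bind_rows(
      m("G03CA03", 2, ind = "hormone_replacement"),
      m("G03DA04", 200, ind = "hormone_replacement")),
      conds = "coronary_artery_disease", sex = "female"),
    J8 = unit_spec("J8", m("G03CA03", 2, ind = "hormone_replacement"),
                   conds = "intact_uterus", sex = "female"),
    J9 = unit_spec("J9", m("H03AA01", 50, unit = "ug", ind = "hypothyroidism"),
                   conds = "hypothyroidism",
                   labs = list(tsh_mu_l = 7, free_t4_status = "normal")),
    J10 = unit_spec("J10", m("H01BA02", 0.2, ind = "urinary_incontinence"),
                    conds = "urinary_incontinence"),
    K1 = unit_spec("K1", m("N03AE01", 0.5, dur = 10L, ind = "anxiety"),
                   conds = "recurrent_falls"),
    K2 = switch(v,
      unit_spec("K2", m("N05AX08", 1, ind = "psychosis"),
                conds = c("psychosis", "recurrent_falls")),
      unit_spec("K2", m("N05AH04", 50, ind = "psychosis"),
                conds = c("psychosis", "recurrent_falls"))
    ),
    K3 = switch(v,
      unit_spec("K3", m("C02DB02", 50, ind = "hypertension"),
                conds = c("hypertension", "recurrent_falls",
                          "orthostatic_hypotension")),
      unit_spec("K3", m("C01DA02", 2.6, ind = "angina"),
                conds = c("angina", "recurrent_falls",
                          "orthostatic_hypotension"))
    ),
    K4 = unit_spec("K4", m("N05CF01", 7.5, dur = 5L, ind = "insomnia"),
                   conds = "recurrent_falls"),
    K5 = switch(v,
      unit_spec("K5", m("N03AF01", 400, ind = "epilepsy"),
                conds = c("epilepsy", "recurrent_falls")),
      unit_spec("K5", m("N03AG01", 500, ind = "epilepsy"),
                conds = c("epilepsy", "recurrent_falls"))
    ),
    K6 = unit_spec("K6", m("R06AB04", 4, dur = 10L, ind = "allergy",
                           fl = FALSE),
                   conds = c("allergy", "recurrent_falls")),
    K7 = unit_spec("K7", dplyr::bind_rows(
      m("N02AX02", 100, ind = "moderate_pain", fl = FALSE),
      m("A06AD11", 20, ind = "chronic_constipation")),
      conds = "recurrent_falls"),
    K8 = unit_spec("K8", m("N06AB06", 50, ind = "depression", fl = FALSE),
                   conds = c("depression", "recurrent_falls")),
    K9 = unit_spec("K9", m("C02CA04", 4, ind = "hypertension"),
                   conds = c("hypertension", "recurrent_falls")),
    K10 = unit_spec("K10", m("G04CA02", 0.4, ind = "bph_luts"),
                    conds = c("bph_luts", "recurrent_falls")),
    K11 = unit_spec("K11", m("C02AC01", 0.1, ind = "hypertension"),
                    conds = c("hypertension", "recurrent_falls")),
    K12 = unit_spec("K12", m("G04BD04", 5, ind = "overactive_bladder"),
                    conds = c("overactive_bladder", "recurrent_falls")),
    L1 = unit_spec("L1", dplyr::bind_rows(
      m("N02AX02", 50, dur = 10L, ind = "mild_pain", fl = TRUE),
      m("A06AD11", 20, ind = "chronic_constipation"))),
    L2 = unit_spec("L2", m("N02AX02", 100, ind = "moderate_pain",
                           fl = FALSE)),
    L3 = unit_spec("L3", dplyr::bind_rows(
      m("N02AB03", 0.6, route = "transdermal", ind = "severe_pain",
        fl = FALSE),
      m("A06AD11", 20, ind = "chronic_constipation"))),
    L4 = unit_spec("L4", m("N01BB02", 700, route = "topical",
                           ind = "osteoarthritis"),
                   conds = "osteoarthritis"),
    L5 = switch(v,
      unit_spec("L5", m("N03AX16", 150, ind = "non_neuropathic_pain")),
      unit_spec("L5", m("N03AX12", 900, ind = "non_neuropathic_pain"))
    ),
    L6 = unit_spec("L6", m("N02BE01", 3000, ind = "pain"),
                   labs = list(bmi = 17)),
    M1 = switch(v,
      unit_spec("M1", dplyr::bind_rows(
        m("N06AA09", 25, ind = "depression", fl = FALSE),
        m("G04BD04", 5, ind = "overactive_bladder")),
        conds = "depression"),
      unit_spec("M1", dplyr::bind_rows(
        m("N04AA04", 10, ind = "tremor"),
        m("N06AA09", 25, ind = "depression", fl = FALSE)),
        conds = "depression"),
      unit_spec("M1", dplyr::bind_rows(
        m("N05AA01", 25, ind = "hiccups"),
        m("G04BD04", 5, ind = "overactive_bladder")))
    ),
    abort(paste0("unknown criterion_id: ", criterion_id),
          class = "pimscreen_criterion_error")
  )
  u
}

# variant of a unit with its laboratory panel removed (and, for criteria
# whose non-lab branch would still fire, the certain branch removed too);
# used to exercise the not_evaluable contract
ne_unit <- function(criterion_id) {
  u <- trigger_unit(criterion_id)
  u$labs <- list()
  if (criterion_id == "B14") u$meds <- u$meds[1, ]
  if (criterion_id == "G4") u$conds <- setdiff(u$conds, "respiratory_failure")
  if (criterion_id == "I6") u$conds <- setdiff(u$conds, "uncontrolled_hypertension")
  if (criterion_id == "B9") u$conds <- setdiff(u$conds, "gout")
  u
}

# identifiers of the criteria whose predicate is gated on laboratory values
LAB_GATED_CRITERIA <- c(
  "B9", "B12", "B14", "B15", "C11", "D3", "D6",
  paste0("E", 1:10), "G4", "H2", "I6", "J9", "L6"
)

unit_patient <- function(units, patient_id = "u1", age = 70L, sex = "male") {
  meds <- dplyr::bind_rows(lapply(units, function(u) u$meds))
  conds <- unique(unlist(lapply(units, function(u) u$conds)))
  labs <- list()
  for (u in units) for (nm in names(u$labs)) labs[[nm]] <- u$labs[[nm]]
  for (u in units) {
    if (!is.na(u$sex)) sex <- u$sex
    if (!is.na(u$age)) age <- u$age
  }
  patient_record(patient_id, age_years = age, sex = sex, conditions = conds,
                 labs = labs, medications = meds)
}
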