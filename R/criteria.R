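# The 133 STOPP version 3 criterion predicates.
#
# Identifiers follow the published numbering: A1-A3 (indication), B1-B21
# (cardiovascular), C1-C16 (coagulation), D1-D25 (central nervous system),
# E1-E10 (renal), F1-F8 (gastrointestinal), G1-G4 (respiratory), H1-H9
# (musculoskeletal), I1-I8 (urogenital), J1-J10 (endocrine), K1-K12
# (falls-risk drugs), L1-L6 (analgesics), M1 (anticholinergic burden).
#
# Conventions, documented in the methods vignette:
#  * condition clauses read the coded condition set (absence = false);
#  * laboratory clauses return not_evaluable when the value is missing;
#  * "first-line" clauses read the per-order first_line qualifier
#    (NA -> not_evaluable once every other clause matches);
#  * indication clauses read the order's indication_code (a missing
#    indication fails the match), except A1 where an explicit "none" is the
#    trigger and a missing indication is not evaluable;
#  * temporal clauses: >3 months = >90 d, >=4 weeks = >=28 d, >=2 weeks =
#    >=14 d, >8 weeks = >56 d, >6 months = >183 d, 12 weeks = >84 d;
#  * the antithrombotic (low-dose) aspirin code carries the aspirin tag but
#    not the nsaid tag; the renal NSAID criterion E4 additionally matches
#    aspirin, the other NSAID criteria do not.

VASC_CONDS <- c("coronary_artery_disease", "cerebrovascular_disease",
                "stroke", "peripheral_vascular_disease",
                "myocardial_infarction")
HF_CONDS <- c("heart_failure", "heart_failure_nyha34",
              "heart_failure_preserved_ef")
BLEED_RISK_CONDS <- c("uncontrolled_hypertension", "bleeding_diathesis",
                      "recent_spontaneous_bleeding")
AC_SPEC <- c("vka", "dti", "fxa")          # anticoagulant classes named by clauses
AC_ANY <- c(AC_SPEC, "heparin")
B5_EXCLUDE <- c("angina", "coronary_artery_disease", "myocardial_infarction",
                HF_CONDS, "atrial_fibrillation", "svt", "aortic_aneurysm")
QTC_DOSE_THR <- c(N06AB04 = 20, N06AB10 = 10)  # citalopram, escitalopram mg/day
PAIN_NON_NEURO <- c("non_neuropathic_pain", "low_back_pain", "osteoarthritis",
                    "mild_pain", "moderate_pain", "pain")

im <- function(ctx, codes) !is.na(ctx$ind) & ctx$ind %in% codes

SYSTEM_GROUPS <- c(
  A = "indication of medication",
  B = "cardiovascular system",
  C = "coagulation system",
  D = "central nervous system",
  E = "renal system",
  F = "gastrointestinal system",
  G = "respiratory system",
  H = "musculoskeletal system",
  I = "urogenital system",
  J = "endocrine system",
  K = "falls-risk drugs",
  L = "analgesic drugs",
  M = "antimuscarinic/anticholinergic drug burden"
)

stopp_registry <- function() {
  if (!is.null(the$registry)) return(the$registry)

  crits <- vector("list", 200L)
  n <- 0L
  add <- function(id, label, fn) {
    n <<- n + 1L
    crits[[n]] <<- list(id = id, label = label, fn = fn)
  }

  # ---- A: indication -----------------------------------------------------
  add("A1", "drug without an evidence-based clinical indication", function(ctx) {
    none <- !is.na(ctx$ind) & ctx$ind == "none"
    if (any(none)) return(o_trig(each(ctx$codes[none])))
    if (anyNA(ctx$ind)) return(o_ne("indication_code"))
    o_not()
  })
  add("A2", "drug continued beyond well-defined treatment duration", function(ctx) {
    i <- mt(ctx, "antibiotic") & ctx$dur > 14L
    if (any(i)) o_trig(each(ctx$codes[i])) else o_not()
  })
  add("A3", "duplicate drug-class prescription for regular use", function(ctx) {
    dup_classes <- list(nsaid = "nsaid", ssri = "ssri",
                        loop_diuretic = "loop_diuretic",
                        ace_inhibitor = "ace_inhibitor",
                        anticoagulant = AC_ANY,
                        antipsychotic = "antipsychotic", opioid = "opioid")
    flags <- list()
    for (cls in dup_classes) {
      i <- mt(ctx, cls) & ctx$reg
      codes <- unique(ctx$codes[i])
      if (length(codes) >= 2L) flags <- c(flags, once(codes))
    }
    if (length(flags)) o_trig(flags) else o_not()
  })

  # ---- B: cardiovascular -------------------------------------------------
  add("B1", "digoxin in heart failure with preserved systolic function", function(ctx) {
    i <- mt(ctx, "digoxin")
    if (any(i) && hc(ctx, "heart_failure_preserved_ef")) o_trig(each(ctx$codes[i])) else o_not()
  })
  add("B2", "verapamil or diltiazem in NYHA class III/IV heart failure", function(ctx) {
    i <- mt(ctx, "verapamil_diltiazem")
    if (any(i) && hc(ctx, "heart_failure_nyha34")) o_trig(each(ctx$codes[i])) else o_not()
  })
  add("B3", "beta-blocker combined with verapamil or diltiazem", function(ctx) {
    i <- mt(ctx, "beta_blocker"); j <- mt(ctx, "verapamil_diltiazem")
    if (any(i) && any(j)) o_trig(once(ctx$codes[i | j])) else o_not()
  })
  add("B4", "rate-limiting drug with bradycardia or heart block", function(ctx) {
    i <- mt(ctx, c("beta_blocker", "verapamil_diltiazem", "digoxin"))
    if (any(i) && hc(ctx, c("bradycardia", "heart_block"))) o_trig(each(ctx$codes[i])) else o_not()
  })
  add("B5", "beta-blocker monotherapy for uncomplicated hypertension", function(ctx) {
    i <- mt(ctx, "beta_blocker") & ctx$reg
    if (!any(i)) return(o_not())
    if (!hc(ctx, "hypertension") || hc(ctx, B5_EXCLUDE)) return(o_not())
    other <- mt(ctx, "antihypertensive") & !mt(ctx, "beta_blocker")
    if (any(other)) return(o_not())
    o_trig(each(ctx$codes[i]))
  })
  add("B6", "amiodarone first-line for supraventricular tachyarrhythmia", function(ctx) {
    i <- mt(ctx, "amiodarone")
    if (!any(i) || !hc(ctx, c("atrial_fibrillation", "svt"))) return(o_not())
    first_line_gate(ctx, i)
  })
  add("B7", "loop diuretic first-line for hypertension", function(ctx) {
    i <- mt(ctx, "loop_diuretic") & im(ctx, "hypertension")
    if (!any(i) || hc(ctx, HF_CONDS)) return(o_not())
    first_line_gate(ctx, i)
  })
  add("B8", "loop diuretic for dependent ankle oedema without cardiac, hepatic or renal disease", function(ctx) {
    i <- mt(ctx, "loop_diuretic") & im(ctx, "ankle_edema")
    if (!any(i)) return(o_not())
    if (hc(ctx, c(HF_CONDS, "chronic_liver_disease", "liver_failure",
                  "nephrotic_syndrome", "renal_failure"))) return(o_not())
    o_trig(each(ctx$codes[i]))
  })
  add("B9", "thiazide with hypokalaemia, hyponatraemia, hypercalcaemia or gout", function(ctx) {
    i <- mt(ctx, "thiazide")
    if (!any(i)) return(o_not())
    hit <- or_unknown(
      lab_cmp(ctx, "serum_k", `<`, 3.0),
      lab_cmp(ctx, "serum_na", `<`, 130),
      lab_cmp(ctx, "corrected_ca", `>`, 2.65),
      hc(ctx, "gout")
    )
    if (isTRUE(hit)) o_trig(each(ctx$codes[i]))
    else if (is.na(hit)) o_ne("serum_k", "serum_na", "corrected_ca")
    else o_not()
  })
  add("B10", "loop diuretic for hypertension with urinary incontinence", function(ctx) {
    i <- mt(ctx, "loop_diuretic") & im(ctx, "hypertension")
    if (any(i) && hc(ctx, c("urinary_incontinence", "urge_incontinence"))) o_trig(each(ctx$codes[i])) else o_not()
  })
  add("B11", "centrally acting antihypertensive without documented need", function(ctx) {
    i <- mt(ctx, "centrally_acting_antihypertensive")
    if (any(i) && !hc(ctx, "antihypertensive_intolerance")) o_trig(each(ctx$codes[i])) else o_not()
  })
  add("B12", "ACE inhibitor or ARB with hyperkalaemia", function(ctx) {
    drug_lab(ctx, mt(ctx, c("ace_inhibitor", "arb")), "serum_k", `>`, 5.5)
  })
  add("B13", "aldosterone antagonist plus potassium-conserving drug without potassium monitoring", function(ctx) {
    i <- mt(ctx, "aldosterone_antagonist")
    if (!any(i)) return(o_not())
    j <- mt(ctx, c("ace_inhibitor", "arb", "potassium_sparing")) & !i
    if (!any(j)) return(o_not())
    # a missing serum potassium IS the finding (no monitoring documented)
    if (is.null(lb(ctx, "serum_k"))) o_trig(each(ctx$codes[i])) else o_not()
  })
  add("B14", "PDE5 inhibitor in severe heart failure or with nitrate therapy", function(ctx) {
    i <- mt(ctx, "pde5_inhibitor")
    if (!any(i)) return(o_not())
    hit <- or_unknown(any(mt(ctx, "nitrate")), lab_cmp(ctx, "systolic_bp", `<`, 90))
    if (isTRUE(hit)) o_trig(each(ctx$codes[i]))
    else if (is.na(hit)) o_ne("systolic_bp")
    else o_not()
  })
  add("B15", "QTc-prolonging drug with known QTc prolongation", function(ctx) {
    thr <- unname(QTC_DOSE_THR[ctx$codes])
    cond_ok <- mt(ctx, "qtc_dose_conditional") & !is.na(thr) & ctx$dose_mg > ifelse(is.na(thr), Inf, thr)
    i <- mt(ctx, "qtc_prolonging") | cond_ok
    if (!any(i)) return(o_not())
    v <- lb(ctx, "qtc_ms")
    if (is.null(v)) return(o_ne("qtc_ms"))
    lim <- if (ctx$sex == "male") 450 else 470
    if (v > lim) o_trig(each(ctx$codes[i])) else o_not()
  })
  add("B16", "statin for primary prevention at age 85+ with limited life expectancy", function(ctx) {
    i <- mt(ctx, "statin")
    if (any(i) && ctx$age >= 85L && hc(ctx, "primary_cv_prevention") &&
        hc(ctx, "frailty_limited_life_expectancy")) o_trig(each(ctx$codes[i])) else o_not()
  })
  add("B17", "long-term systemic NSAID with vascular disease", function(ctx) {
    i <- mt(ctx, "nsaid") & ctx$route != "topical" & ctx$dur > 90L
    if (any(i) && hc(ctx, VASC_CONDS)) o_trig(each(ctx$codes[i])) else o_not()
  })
  add("B18", "long-term antipsychotic with vascular disease", function(ctx) {
    i <- mt(ctx, "antipsychotic") & ctx$dur > 90L
    if (any(i) && hc(ctx, VASC_CONDS)) o_trig(each(ctx$codes[i])) else o_not()
  })
  add("B19", "NSAID or systemic corticosteroid in heart failure on loop diuretic", function(ctx) {
    i <- mt(ctx, c("nsaid", "corticosteroid_systemic"))
    if (any(i) && hc(ctx, HF_CONDS) && any(mt(ctx, "loop_diuretic"))) o_trig(each(ctx$codes[i])) else o_not()
  })
  add("B20", "non-RAS antihypertensive in severe symptomatic aortic stenosis", function(ctx) {
    i <- mt(ctx, "antihypertensive") & !mt(ctx, c("ace_inhibitor", "arb"))
    if (any(i) && hc(ctx, "severe_aortic_stenosis")) o_trig(each(ctx$codes[i])) else o_not()
  })
  add("B21", "digoxin first-line for long-term rate control in atrial fibrillation", function(ctx) {
    i <- mt(ctx, "digoxin") & im(ctx, "atrial_fibrillation") & ctx$dur > 90L
    if (!any(i)) return(o_not())
    first_line_gate(ctx, i)
  })

  # ---- C: coagulation ----------------------------------------------------
  add("C1", "long-term aspirin above 100 mg daily", function(ctx) {
    i <- mt(ctx, "aspirin") & ctx$dose_mg > 100 & ctx$dur > 90L
    if (any(i)) o_trig(each(ctx$codes[i])) else o_not()
  })
  add("C2", "antithrombotic with significant bleeding risk", function(ctx) {
    i <- mt(ctx, c("antiplatelet", AC_SPEC))
    if (any(i) && hc(ctx, BLEED_RISK_CONDS)) o_trig(each(ctx$codes[i])) else o_not()
  })
  add("C3", "aspirin plus clopidogrel beyond 4 weeks for secondary stroke prevention", function(ctx) {
    i <- mt(ctx, "aspirin"); j <- ctx$codes == "B01AC04"
    if (!any(i) || !any(j)) return(o_not())
    if (!hc(ctx, c("stroke", "cerebrovascular_disease"))) return(o_not())
    if (hc(ctx, c("coronary_stent_recent", "acute_coronary_syndrome",
                  "carotid_stenosis"))) return(o_not())
    if (min(ctx$dur[i | j]) > 28L) o_trig(once(ctx$codes[i | j])) else o_not()
  })
  add("C4", "antiplatelet plus anticoagulant in chronic atrial fibrillation", function(ctx) {
    i <- mt(ctx, "antiplatelet"); j <- mt(ctx, AC_SPEC)
    if (!any(i) || !any(j) || !hc(ctx, "atrial_fibrillation")) return(o_not())
    if (hc(ctx, c("coronary_stent_recent", "coronary_stenosis_high_grade"))) return(o_not())
    o_trig(once(ctx$codes[i | j]))
  })
  add("C5", "antiplatelet plus anticoagulant in stable arterial disease", function(ctx) {
    i <- mt(ctx, "antiplatelet"); j <- mt(ctx, AC_SPEC)
    if (!any(i) || !any(j) || !hc(ctx, VASC_CONDS)) return(o_not())
    if (hc(ctx, c("atrial_fibrillation", "dvt_history", "pe_history",
                  "metallic_heart_valve", "mitral_stenosis"))) return(o_not())
    o_trig(once(ctx$codes[i | j]))
  })
  add("C6", "ticlopidine in any circumstances", function(ctx) {
    i <- mt(ctx, "ticlopidine")
    if (any(i)) o_trig(each(ctx$codes[i])) else o_not()
  })
  add("C7", "antiplatelet instead of anticoagulant for stroke prevention in atrial fibrillation", function(ctx) {
    i <- mt(ctx, "antiplatelet") & im(ctx, "stroke_prevention")
    if (any(i) && hc(ctx, "atrial_fibrillation") && !any(mt(ctx, AC_SPEC))) o_trig(each(ctx$codes[i])) else o_not()
  })
  add("C8", "anticoagulation beyond 6 months for first provoked deep venous thrombosis", function(ctx) {
    i <- mt(ctx, AC_SPEC) & ctx$dur > 183L
    if (any(i) && hc(ctx, "dvt_history") &&
        !hc(ctx, "thrombosis_risk_persistent")) o_trig(each(ctx$codes[i])) else o_not()
  })
  add("C9", "anticoagulation beyond 6 months for first provoked pulmonary embolus", function(ctx) {
    i <- mt(ctx, AC_SPEC) & ctx$dur > 183L
    if (any(i) && hc(ctx, "pe_history") &&
        !hc(ctx, "thrombosis_risk_persistent")) o_trig(each(ctx$codes[i])) else o_not()
  })
  add("C10", "NSAID combined with anticoagulant", function(ctx) {
    i <- mt(ctx, "nsaid"); j <- mt(ctx, AC_SPEC)
    if (any(i) && any(j)) o_trig(once(ctx$codes[i | j])) else o_not()
  })
  add("C11", "vitamin K antagonist first-line for atrial fibrillation", function(ctx) {
    i <- mt(ctx, "vka")
    if (!any(i) || !hc(ctx, "atrial_fibrillation")) return(o_not())
    if (hc(ctx, c("metallic_heart_valve", "mitral_stenosis"))) return(o_not())
    g <- lb(ctx, "egfr")
    if (is.null(g)) return(o_ne("egfr"))
    if (g < 15) return(o_not())
    first_line_gate(ctx, i)
  })
  add("C12", "SSRI plus anticoagulant with previous major haemorrhage", function(ctx) {
    i <- mt(ctx, "ssri"); j <- mt(ctx, AC_SPEC)
    if (any(i) && any(j) && hc(ctx, "major_hemorrhage_history")) o_trig(once(ctx$codes[i | j])) else o_not()
  })
  add("C13", "direct thrombin inhibitor with verapamil or diltiazem", function(ctx) {
    i <- mt(ctx, "dti"); j <- mt(ctx, "verapamil_diltiazem")
    if (any(i) && any(j)) o_trig(once(ctx$codes[i | j])) else o_not()
  })
  add("C14", "direct oral anticoagulant with P-glycoprotein inhibitor", function(ctx) {
    i <- mt(ctx, c("fxa", "dti")); j <- mt(ctx, "pgp_inhibitor")
    if (any(i) && any(j)) o_trig(once(ctx$codes[i | j])) else o_not()
  })
  add("C15", "systemic estrogen or androgen with venous thromboembolism history", function(ctx) {
    i <- mt(ctx, c("estrogen_systemic", "androgen"))
    if (any(i) && hc(ctx, c("dvt_history", "pe_history"))) o_trig(each(ctx$codes[i])) else o_not()
  })
  add("C16", "aspirin for primary cardiovascular prevention", function(ctx) {
    i <- mt(ctx, "aspirin")
    if (any(i) && hc(ctx, "primary_cv_prevention")) o_trig(each(ctx$codes[i])) else o_not()
  })

  # ---- D: central nervous system ----------------------------------------
  add("D1", "tricyclic antidepressant with an aggravating comorbidity", function(ctx) {
    i <- mt(ctx, "tca")
    if (any(i) && hc(ctx, c("dementia", "narrow_angle_glaucoma", "heart_block",
                            "bph_luts", "chronic_constipation",
                            "recurrent_falls", "urinary_retention_history"))) o_trig(each(ctx$codes[i])) else o_not()
  })
  add("D2", "tricyclic antidepressant first-line for major depression", function(ctx) {
    i <- mt(ctx, "tca") & im(ctx, "depression")
    if (!any(i)) return(o_not())
    first_line_gate(ctx, i)
  })
  add("D3", "SNRI with severe hypertension", function(ctx) {
    i <- mt(ctx, "snri")
    if (!any(i)) return(o_not())
    hit <- or_unknown(lab_cmp(ctx, "systolic_bp", `>`, 180),
                      lab_cmp(ctx, "diastolic_bp", `>`, 105))
    if (isTRUE(hit)) o_trig(each(ctx$codes[i]))
    else if (is.na(hit)) o_ne("systolic_bp", "diastolic_bp")
    else o_not()
  })
  add("D4", "antimuscarinic antipsychotic with prostatic symptoms or urinary retention", function(ctx) {
    i <- mt(ctx, "antipsychotic_antimuscarinic")
    if (any(i) && hc(ctx, c("bph_luts", "urinary_retention_history"))) o_trig(each(ctx$codes[i])) else o_not()
  })
  add("D5", "antipsychotic for BPSD beyond 3 months without review", function(ctx) {
    i <- mt(ctx, "antipsychotic") & im(ctx, "bpsd") & ctx$dur > 90L
    if (any(i)) o_trig(each(ctx$codes[i])) else o_not()
  })
  add("D6", "SSRI with significant hyponatraemia", function(ctx) {
    drug_lab(ctx, mt(ctx, "ssri"), "serum_na", `<`, 130)
  })
  add("D7", "SSRI with current or recent significant bleeding", function(ctx) {
    i <- mt(ctx, "ssri")
    if (any(i) && hc(ctx, "recent_bleeding")) o_trig(each(ctx$codes[i])) else o_not()
  })
  add("D8", "benzodiazepine for 4 weeks or longer", function(ctx) {
    i <- mt(ctx, "benzodiazepine") & ctx$dur >= 28L
    if (any(i)) o_trig(each(ctx$codes[i])) else o_not()
  })
  add("D9", "benzodiazepine for agitated behaviour or non-cognitive symptoms of dementia", function(ctx) {
    i <- mt(ctx, "benzodiazepine") & im(ctx, c("bpsd", "agitation", "ncsd"))
    if (any(i) && hc(ctx, c("dementia", "lewy_body_dementia"))) o_trig(each(ctx$codes[i])) else o_not()
  })
  add("D10", "benzodiazepine for insomnia for 2 weeks or longer", function(ctx) {
    i <- mt(ctx, "benzodiazepine") & im(ctx, "insomnia") & ctx$dur >= 14L
    if (any(i)) o_trig(each(ctx$codes[i])) else o_not()
  })
  add("D11", "Z-drug for insomnia for 2 weeks or longer", function(ctx) {
    i <- mt(ctx, "z_drug") & im(ctx, "insomnia") & ctx$dur >= 14L
    if (any(i)) o_trig(each(ctx$codes[i])) else o_not()
  })
  add("D12", "antipsychotic (other than clozapine or quetiapine) in parkinsonism or Lewy body disease", function(ctx) {
    i <- mt(ctx, "antipsychotic") & !(ctx$codes %in% c("N05AH02", "N05AH04"))
    if (any(i) && hc(ctx, c("parkinsonism", "lewy_body_dementia"))) o_trig(each(ctx$codes[i])) else o_not()
  })
  add("D13", "anticholinergic to treat extrapyramidal side effects of antipsychotics", function(ctx) {
    i <- mt(ctx, "antiparkinson_anticholinergic") & im(ctx, "eps")
    if (any(i) && any(mt(ctx, "antipsychotic"))) o_trig(each(ctx$codes[i])) else o_not()
  })
  add("D14", "potent anticholinergic in delirium or dementia", function(ctx) {
    i <- mt(ctx, "anticholinergic")
    if (any(i) && hc(ctx, c("delirium", "dementia", "lewy_body_dementia"))) o_trig(each(ctx$codes[i])) else o_not()
  })
  add("D15", "neuroleptic for non-cognitive symptoms of dementia beyond 12 weeks", function(ctx) {
    i <- mt(ctx, "antipsychotic") & im(ctx, "ncsd") & ctx$dur > 84L
    if (any(i) && hc(ctx, c("dementia", "lewy_body_dementia"))) o_trig(each(ctx$codes[i])) else o_not()
  })
  add("D16", "neuroleptic as hypnotic without psychotic sleep disorder", function(ctx) {
    i <- mt(ctx, "antipsychotic") & im(ctx, "insomnia")
    if (any(i) && !hc(ctx, c("psychosis", "ncsd"))) o_trig(each(ctx$codes[i])) else o_not()
  })
  add("D17", "acetylcholinesterase inhibitor with bradycardia, heart block or syncope", function(ctx) {
    i <- mt(ctx, "ache_inhibitor")
    if (any(i) && hc(ctx, c("bradycardia", "heart_block", "syncope"))) o_trig(each(ctx$codes[i])) else o_not()
  })
  add("D18", "acetylcholinesterase inhibitor with rate-limiting drug", function(ctx) {
    i <- mt(ctx, "ache_inhibitor")
    j <- mt(ctx, c("beta_blocker", "digoxin", "verapamil_diltiazem"))
    if (any(i) && any(j)) o_trig(once(ctx$codes[i | j])) else o_not()
  })
  add("D19", "memantine with seizure disorder", function(ctx) {
    i <- mt(ctx, "memantine")
    if (any(i) && hc(ctx, c("epilepsy", "seizure_history"))) o_trig(each(ctx$codes[i])) else o_not()
  })
  add("D20", "nootropic in dementia", function(ctx) {
    i <- mt(ctx, "nootropic")
    if (any(i) && hc(ctx, c("dementia", "lewy_body_dementia"))) o_trig(each(ctx$codes[i])) else o_not()
  })
  add("D21", "phenothiazine first-line for psychosis or non-cognitive symptoms of dementia", function(ctx) {
    i <- mt(ctx, "phenothiazine") & im(ctx, c("psychosis", "ncsd"))
    if (!any(i)) return(o_not())
    first_line_gate(ctx, i)
  })
  add("D22", "levodopa or dopamine agonist for benign essential tremor", function(ctx) {
    i <- mt(ctx, "levodopa_dopamine_agonist")
    if (any(i) && hc(ctx, "essential_tremor")) o_trig(each(ctx$codes[i])) else o_not()
  })
  add("D23", "levodopa or dopamine agonist for drug-induced parkinsonism", function(ctx) {
    i <- mt(ctx, "levodopa_dopamine_agonist")
    if (any(i) && (hc(ctx, "drug_induced_parkinsonism") || any(i & im(ctx, "eps")))) o_trig(each(ctx$codes[i])) else o_not()
  })
  add("D24", "first-generation antihistamine first-line for allergy or pruritus", function(ctx) {
    i <- mt(ctx, "antihistamine_first_gen") & im(ctx, c("allergy", "pruritus"))
    if (!any(i)) return(o_not())
    first_line_gate(ctx, i)
  })
  add("D25", "first-generation antihistamine for insomnia", function(ctx) {
    i <- mt(ctx, "antihistamine_first_gen") & im(ctx, "insomnia")
    if (any(i)) o_trig(each(ctx$codes[i])) else o_not()
  })

  # ---- E: renal ----------------------------------------------------------
  add("E1", "high-dose long-term digoxin with eGFR below 30", function(ctx) {
    i <- mt(ctx, "digoxin") & (ctx$dose_mg * 1000) >= 125 & ctx$dur > 90L
    drug_lab(ctx, i, "egfr", `<`, 30)
  })
  add("E2", "direct thrombin inhibitor with eGFR below 30", function(ctx) {
    drug_lab(ctx, mt(ctx, "dti"), "egfr", `<`, 30)
  })
  add("E3", "factor Xa inhibitor with eGFR below 15", function(ctx) {
    drug_lab(ctx, mt(ctx, "fxa"), "egfr", `<`, 15)
  })
  add("E4", "NSAID with eGFR below 50", function(ctx) {
    drug_lab(ctx, mt(ctx, c("nsaid", "aspirin")), "egfr", `<`, 50)
  })
  add("E5", "colchicine with eGFR below 10", function(ctx) {
    drug_lab(ctx, mt(ctx, "colchicine"), "egfr", `<`, 10)
  })
  add("E6", "metformin with eGFR below 30", function(ctx) {
    drug_lab(ctx, mt(ctx, "metformin"), "egfr", `<`, 30)
  })
  add("E7", "mineralocorticoid receptor antagonist with eGFR below 30", function(ctx) {
    drug_lab(ctx, mt(ctx, "aldosterone_antagonist"), "egfr", `<`, 30)
  })
  add("E8", "nitrofurantoin with eGFR below 45", function(ctx) {
    drug_lab(ctx, mt(ctx, "nitrofurantoin"), "egfr", `<`, 45)
  })
  add("E9", "bisphosphonate with eGFR below 30", function(ctx) {
    drug_lab(ctx, mt(ctx, "bisphosphonate"), "egfr", `<`, 30)
  })
  add("E10", "methotrexate with eGFR below 30", function(ctx) {
    drug_lab(ctx, mt(ctx, "methotrexate"), "egfr", `<`, 30)
  })

  # ---- F: gastrointestinal ----------------------------------------------
  add("F1", "prochlorperazine or metoclopramide with parkinsonism", function(ctx) {
    i <- mt(ctx, "metoclopramide_prochlorperazine")
    if (any(i) && hc(ctx, c("parkinsonism", "lewy_body_dementia"))) o_trig(each(ctx$codes[i])) else o_not()
  })
  add("F2", "PPI beyond 8 weeks for uncomplicated peptic ulcer or oesophagitis", function(ctx) {
    i <- mt(ctx, "ppi") & ctx$dur > 56L
    if (any(i) && hc(ctx, c("peptic_ulcer", "erosive_esophagitis"))) o_trig(each(ctx$codes[i])) else o_not()
  })
  add("F3", "constipating drug in chronic constipation", function(ctx) {
    i <- mt(ctx, c("constipating", "anticholinergic"))
    if (any(i) && hc(ctx, "chronic_constipation")) o_trig(each(ctx$codes[i])) else o_not()
  })
  add("F4", "oral elemental iron above 200 mg daily", function(ctx) {
    salt_thr <- c(B03AA07 = 600)  # mg of salt equivalent to 200 mg elemental
    thr <- salt_thr[ctx$codes]
    thr[is.na(thr)] <- 200
    i <- mt(ctx, "oral_iron") & ctx$route == "oral" & ctx$dose_mg > unname(thr)
    if (any(i)) o_trig(each(ctx$codes[i])) else o_not()
  })
  add("F5", "systemic corticosteroid with ulcer history and no gastroprotection", function(ctx) {
    i <- mt(ctx, "corticosteroid_systemic")
    if (any(i) && hc(ctx, c("peptic_ulcer", "erosive_esophagitis")) &&
        !any(mt(ctx, "ppi"))) o_trig(each(ctx$codes[i])) else o_not()
  })
  add("F6", "antiplatelet or anticoagulant with gastric antral vascular ectasia", function(ctx) {
    i <- mt(ctx, c("antiplatelet", AC_ANY))
    if (any(i) && hc(ctx, "gave")) o_trig(each(ctx$codes[i])) else o_not()
  })
  add("F7", "antipsychotic with dysphagia", function(ctx) {
    i <- mt(ctx, "antipsychotic")
    if (any(i) && hc(ctx, "dysphagia")) o_trig(each(ctx$codes[i])) else o_not()
  })
  add("F8", "megestrol acetate to increase appetite", function(ctx) {
    i <- mt(ctx, "megestrol")
    if (any(i)) o_trig(each(ctx$codes[i])) else o_not()
  })

  # ---- G: respiratory ----------------------------------------------------
  add("G1", "theophylline as monotherapy for COPD", function(ctx) {
    i <- mt(ctx, "theophylline")
    if (!any(i) || !hc(ctx, "copd")) return(o_not())
    if (any(mt(ctx, "respiratory_maintenance") & !i)) return(o_not())
    o_trig(each(ctx$codes[i]))
  })
  add("G2", "systemic instead of inhaled corticosteroid for COPD maintenance", function(ctx) {
    i <- mt(ctx, "corticosteroid_systemic") & ctx$route %in% c("oral", "parenteral") &
      im(ctx, "copd")
    if (any(i) && hc(ctx, "copd") && !any(mt(ctx, "corticosteroid_inhaled"))) o_trig(each(ctx$codes[i])) else o_not()
  })
  add("G3", "long-acting muscarinic antagonist with glaucoma or bladder outflow obstruction", function(ctx) {
    i <- mt(ctx, "lama")
    if (any(i) && hc(ctx, c("narrow_angle_glaucoma", "bph_luts",
                            "urinary_retention_history"))) o_trig(each(ctx$codes[i])) else o_not()
  })
  add("G4", "benzodiazepine with respiratory failure", function(ctx) {
    i <- mt(ctx, "benzodiazepine")
    if (!any(i)) return(o_not())
    hit <- or_unknown(hc(ctx, "respiratory_failure"),
                      lab_cmp(ctx, "po2_kpa", `<`, 8),
                      lab_cmp(ctx, "pco2_kpa", `>`, 6.5))
    if (isTRUE(hit)) o_trig(each(ctx$codes[i]))
    else if (is.na(hit)) o_ne("po2_kpa", "pco2_kpa")
    else o_not()
  })

  # ---- H: musculoskeletal -------------------------------------------------
  add("H1", "non-selective NSAID with ulcer history and no gastroprotection", function(ctx) {
    i <- mt(ctx, "nsaid") & !mt(ctx, "cox2_selective")
    if (any(i) && hc(ctx, c("peptic_ulcer", "gi_bleed_history")) &&
        !any(mt(ctx, c("ppi", "h2_antagonist")))) o_trig(each(ctx$codes[i])) else o_not()
  })
  add("H2", "NSAID with severe hypertension", function(ctx) {
    i <- mt(ctx, "nsaid")
    if (!any(i)) return(o_not())
    hit <- or_unknown(lab_cmp(ctx, "systolic_bp", `>`, 170),
                      lab_cmp(ctx, "diastolic_bp", `>`, 100))
    if (isTRUE(hit)) o_trig(each(ctx$codes[i]))
    else if (is.na(hit)) o_ne("systolic_bp", "diastolic_bp")
    else o_not()
  })
  add("H3", "long-term NSAID for osteoarthritis pain without trying paracetamol", function(ctx) {
    i <- mt(ctx, "nsaid") & ctx$dur > 90L
    if (any(i) && hc(ctx, "osteoarthritis") && !any(mt(ctx, "paracetamol"))) o_trig(each(ctx$codes[i])) else o_not()
  })
  add("H4", "long-term corticosteroid monotherapy for rheumatoid arthritis", function(ctx) {
    i <- mt(ctx, "corticosteroid_systemic") & ctx$dur > 90L
    if (any(i) && hc(ctx, "rheumatoid_arthritis") &&
        !any(mt(ctx, "methotrexate"))) o_trig(each(ctx$codes[i])) else o_not()
  })
  add("H5", "systemic corticosteroid for osteoarthritis", function(ctx) {
    i <- mt(ctx, "corticosteroid_systemic") & im(ctx, "osteoarthritis") &
      ctx$route %in% c("oral", "parenteral")
    if (any(i) && hc(ctx, "osteoarthritis")) o_trig(each(ctx$codes[i])) else o_not()
  })
  add("H6", "long-term NSAID or colchicine for gout prophylaxis", function(ctx) {
    i <- mt(ctx, c("nsaid", "colchicine")) & ctx$dur > 90L & im(ctx, "gout_prophylaxis")
    if (any(i) && hc(ctx, "gout") && !hc(ctx, "xoi_contraindication")) o_trig(each(ctx$codes[i])) else o_not()
  })
  add("H7", "NSAID with corticosteroid for arthritis", function(ctx) {
    i <- mt(ctx, "nsaid"); j <- mt(ctx, "corticosteroid_systemic")
    if (any(i) && any(j) && hc(ctx, c("osteoarthritis", "rheumatoid_arthritis",
                                      "gout"))) o_trig(once(ctx$codes[i | j])) else o_not()
  })
  add("H8", "oral bisphosphonate with upper gastrointestinal disease", function(ctx) {
    i <- mt(ctx, "bisphosphonate") & ctx$route == "oral"
    if (any(i) && hc(ctx, c("dysphagia", "erosive_esophagitis", "gastritis",
                            "peptic_ulcer", "gi_bleed_history"))) o_trig(each(ctx$codes[i])) else o_not()
  })
  add("H9", "long-term opioid for osteoarthritis", function(ctx) {
    i <- mt(ctx, "opioid") & ctx$dur > 90L & im(ctx, "osteoarthritis")
    if (any(i) && hc(ctx, "osteoarthritis")) o_trig(each(ctx$codes[i])) else o_not()
  })

  # ---- I: urogenital -----------------------------------------------------
  add("I1", "systemic antimuscarinic in dementia or chronic cognitive impairment", function(ctx) {
    i <- mt(ctx, "antimuscarinic_urological")
    if (any(i) && hc(ctx, c("dementia", "lewy_body_dementia",
                            "chronic_cognitive_impairment"))) o_trig(each(ctx$codes[i])) else o_not()
  })
  add("I2", "systemic antimuscarinic with narrow-angle glaucoma", function(ctx) {
    i <- mt(ctx, "antimuscarinic_urological")
    if (any(i) && hc(ctx, "narrow_angle_glaucoma")) o_trig(each(ctx$codes[i])) else o_not()
  })
  add("I3", "systemic antimuscarinic with prostatic symptoms and high residual volume", function(ctx) {
    i <- mt(ctx, "antimuscarinic_urological")
    if (any(i) && hc(ctx, "bph_luts") && hc(ctx, "high_post_void_residual")) o_trig(each(ctx$codes[i])) else o_not()
  })
  add("I4", "systemic antimuscarinic with constipation", function(ctx) {
    i <- mt(ctx, "antimuscarinic_urological")
    if (any(i) && hc(ctx, "chronic_constipation")) o_trig(each(ctx$codes[i])) else o_not()
  })
  add("I5", "alpha-1 blocker (other than silodosin) with orthostatic hypotension or syncope", function(ctx) {
    i <- mt(ctx, "alpha1_blocker") & !mt(ctx, "silodosin_exempt")
    if (any(i) && hc(ctx, c("orthostatic_hypotension", "syncope"))) o_trig(each(ctx$codes[i])) else o_not()
  })
  add("I6", "mirabegron in labile or severe hypertension", function(ctx) {
    i <- mt(ctx, "mirabegron")
    if (!any(i)) return(o_not())
    hit <- or_unknown(hc(ctx, "uncontrolled_hypertension"),
                      lab_cmp(ctx, "systolic_bp", `>`, 180))
    if (isTRUE(hit)) o_trig(each(ctx$codes[i]))
    else if (is.na(hit)) o_ne("systolic_bp")
    else o_not()
  })
  add("I7", "duloxetine with urinary urgency or urge incontinence", function(ctx) {
    i <- ctx$codes == "N06AX21"
    if (any(i) && hc(ctx, "urge_incontinence")) o_trig(each(ctx$codes[i])) else o_not()
  })
  add("I8", "antibiotic for asymptomatic bacteriuria", function(ctx) {
    i <- mt(ctx, "antibiotic")
    if (any(i) && hc(ctx, "asymptomatic_bacteriuria")) o_trig(each(ctx$codes[i])) else o_not()
  })

  # ---- J: endocrine ------------------------------------------------------
  add("J1", "long-acting sulfonylurea in type 2 diabetes", function(ctx) {
    i <- mt(ctx, "sulfonylurea_long_acting")
    if (any(i) && hc(ctx, c("diabetes_t2", "diabetes_end_organ"))) o_trig(each(ctx$codes[i])) else o_not()
  })
  add("J2", "thiazolidinedione in heart failure", function(ctx) {
    i <- mt(ctx, "thiazolidinedione")
    if (any(i) && hc(ctx, HF_CONDS)) o_trig(each(ctx$codes[i])) else o_not()
  })
  add("J3", "non-selective beta-blocker in diabetes with frequent hypoglycaemia", function(ctx) {
    i <- mt(ctx, "beta_blocker_nonselective")
    if (any(i) && hc(ctx, c("diabetes_t2", "diabetes_end_organ")) &&
        hc(ctx, "frequent_hypoglycemia")) o_trig(each(ctx$codes[i])) else o_not()
  })
  add("J4", "SGLT2 inhibitor with symptomatic hypotension", function(ctx) {
    i <- mt(ctx, "sglt2")
    if (any(i) && hc(ctx, "symptomatic_hypotension")) o_trig(each(ctx$codes[i])) else o_not()
  })
  add("J5", "systemic estrogen with breast cancer history", function(ctx) {
    i <- mt(ctx, "estrogen_systemic")
    if (any(i) && hc(ctx, "breast_cancer")) o_trig(each(ctx$codes[i])) else o_not()
  })
  add("J6", "systemic estrogen with venous thromboembolism history", function(ctx) {
    i <- mt(ctx, "estrogen_systemic")
    if (any(i) && hc(ctx, c("dvt_history", "pe_history"))) o_trig(each(ctx$codes[i])) else o_not()
  })
  add("J7", "combined hormone therapy with arterial disease", function(ctx) {
    i <- mt(ctx, "estrogen_systemic"); j <- mt(ctx, "progestogen")
    if (any(i) && any(j) && hc(ctx, VASC_CONDS)) o_trig(once(ctx$codes[i | j])) else o_not()
  })
  add("J8", "unopposed systemic estrogen with intact uterus", function(ctx) {
    i <- mt(ctx, "estrogen_systemic")
    if (any(i) && hc(ctx, "intact_uterus") && !any(mt(ctx, "progestogen"))) o_trig(each(ctx$codes[i])) else o_not()
  })
  add("J9", "levothyroxine in subclinical hypothyroidism", function(ctx) {
    i <- mt(ctx, "levothyroxine")
    if (!any(i)) return(o_not())
    tsh <- lb(ctx, "tsh_mu_l"); t4 <- lb(ctx, "free_t4_status")
    missing <- c("tsh_mu_l", "free_t4_status")[c(is.null(tsh), is.null(t4))]
    if (length(missing)) return(o_ne(missing))
    if (tsh > 4 && tsh < 10 && t4 == "normal") o_trig(each(ctx$codes[i])) else o_not()
  })
  add("J10", "vasopressin analog for urinary incontinence or frequency", function(ctx) {
    i <- mt(ctx, "vasopressin_analog") &
      im(ctx, c("urinary_incontinence", "urge_incontinence", "urinary_frequency"))
    if (any(i)) o_trig(each(ctx$codes[i])) else o_not()
  })

  # ---- K: falls-risk drugs ----------------------------------------------
  falls <- function(ctx) hc(ctx, "recurrent_falls")
  add("K1", "benzodiazepine with recurrent falls", function(ctx) {
    i <- mt(ctx, "benzodiazepine")
    if (any(i) && falls(ctx)) o_trig(each(ctx$codes[i])) else o_not()
  })
  add("K2", "antipsychotic with recurrent falls", function(ctx) {
    i <- mt(ctx, "antipsychotic")
    if (any(i) && falls(ctx)) o_trig(each(ctx$codes[i])) else o_not()
  })
  add("K3", "vasodilator with recurrent falls and postural hypotension", function(ctx) {
    i <- mt(ctx, "vasodilator")
    if (any(i) && falls(ctx) && hc(ctx, "orthostatic_hypotension")) o_trig(each(ctx$codes[i])) else o_not()
  })
  add("K4", "hypnotic Z-drug with recurrent falls", function(ctx) {
    i <- mt(ctx, "z_drug")
    if (any(i) && falls(ctx)) o_trig(each(ctx$codes[i])) else o_not()
  })
  add("K5", "antiepileptic with recurrent falls", function(ctx) {
    i <- mt(ctx, "antiepileptic")
    if (any(i) && falls(ctx)) o_trig(each(ctx$codes[i])) else o_not()
  })
  add("K6", "first-generation antihistamine with recurrent falls", function(ctx) {
    i <- mt(ctx, "antihistamine_first_gen")
    if (any(i) && falls(ctx)) o_trig(each(ctx$codes[i])) else o_not()
  })
  add("K7", "opioid with recurrent falls", function(ctx) {
    i <- mt(ctx, "opioid")
    if (any(i) && falls(ctx)) o_trig(each(ctx$codes[i])) else o_not()
  })
  add("K8", "antidepressant with recurrent falls", function(ctx) {
    i <- mt(ctx, "antidepressant")
    if (any(i) && falls(ctx)) o_trig(each(ctx$codes[i])) else o_not()
  })
  add("K9", "alpha blocker as antihypertensive with recurrent falls", function(ctx) {
    i <- mt(ctx, "alpha1_blocker") & im(ctx, "hypertension")
    if (any(i) && falls(ctx)) o_trig(each(ctx$codes[i])) else o_not()
  })
  add("K10", "alpha blocker for prostatic symptoms with recurrent falls", function(ctx) {
    i <- mt(ctx, "alpha1_blocker") & !mt(ctx, "silodosin_exempt") &
      im(ctx, "bph_luts")
    if (any(i) && falls(ctx)) o_trig(each(ctx$codes[i])) else o_not()
  })
  add("K11", "centrally acting antihypertensive with recurrent falls", function(ctx) {
    i <- mt(ctx, "centrally_acting_antihypertensive")
    if (any(i) && falls(ctx)) o_trig(each(ctx$codes[i])) else o_not()
  })
  add("K12", "bladder antimuscarinic for overactive bladder with recurrent falls", function(ctx) {
    i <- mt(ctx, "antimuscarinic_urological") &
      im(ctx, c("overactive_bladder", "urge_incontinence"))
    if (any(i) && falls(ctx)) o_trig(each(ctx$codes[i])) else o_not()
  })

  # ---- L: analgesics -----------------------------------------------------
  add("L1", "strong opioid first-line for mild pain", function(ctx) {
    i <- mt(ctx, "opioid_strong") & ctx$route %in% c("oral", "transdermal") &
      im(ctx, "mild_pain")
    if (!any(i)) return(o_not())
    first_line_gate(ctx, i)
  })
  add("L2", "regular opioid without concomitant laxative", function(ctx) {
    i <- mt(ctx, "opioid") & ctx$reg
    if (any(i) && !any(mt(ctx, "laxative"))) o_trig(each(ctx$codes[i])) else o_not()
  })
  add("L3", "long-acting opioid without short-acting opioid for breakthrough pain", function(ctx) {
    i <- mt(ctx, "opioid_long_acting")
    if (any(i) && !any(mt(ctx, "opioid_short_acting"))) o_trig(each(ctx$codes[i])) else o_not()
  })
  add("L4", "topical lidocaine patch for chronic osteoarthritis pain", function(ctx) {
    i <- mt(ctx, "lidocaine_patch") & ctx$route %in% c("topical", "transdermal") &
      im(ctx, "osteoarthritis")
    if (any(i) && hc(ctx, "osteoarthritis")) o_trig(each(ctx$codes[i])) else o_not()
  })
  add("L5", "gabapentinoid for non-neuropathic pain", function(ctx) {
    i <- mt(ctx, "gabapentinoid") & im(ctx, PAIN_NON_NEURO)
    if (any(i)) o_trig(each(ctx$codes[i])) else o_not()
  })
  add("L6", "high-dose paracetamol with poor nutritional status or liver disease", function(ctx) {
    i <- mt(ctx, "paracetamol") & ctx$dose_mg >= 3000
    if (!any(i)) return(o_not())
    hit <- or_unknown(hc(ctx, "chronic_liver_disease"),
                      lab_cmp(ctx, "bmi", `<`, 18))
    if (isTRUE(hit)) o_trig(each(ctx$codes[i]))
    else if (is.na(hit)) o_ne("bmi")
    else o_not()
  })

  # ---- M: anticholinergic burden -----------------------------------------
  add("M1", "concomitant use of two or more anticholinergic drugs", function(ctx) {
    i <- mt(ctx, "anticholinergic") & ctx$reg
    codes <- unique(ctx$codes[i])
    if (length(codes) >= 2L) o_trig(once(codes)) else o_not()
  })

  crits <- crits[seq_len(n)]
  ids <- vapply(crits, function(x) x$id, character(1))
  letters1 <- substr(ids, 1, 1)
  the$registry <- tibble::tibble(
    criterion_id = ids,
    system_letter = letters1,
    system_group = unname(SYSTEM_GROUPS[letters1]),
    label = vapply(crits, function(x) x$label, character(1)),
    fn = lapply(crits, function(x) x$fn)
  )
  the$registry
}

#' Catalog of the 133 screening criteria
#'
#' @return A tibble with `criterion_id`, `system_letter`, `system_group` and
#'   a short `label` for each of the 133 rules.
#' @export
#' @examples
#' stopp_criteria()
stopp_criteria <- function() {
  dplyr::select(stopp_registry(), -"fn")
}
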