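# pimscreen

Explicit-criteria screening of older-adult prescriptions for potentially
inappropriate medications (PIMs), with the downstream epidemiology that
usually accompanies it.

## What problem this solves

Hospitalized adults aged 60+ commonly accumulate complex drug regimens;
some prescriptions carry risks that outweigh their benefit in this
population (first-generation antihistamines, NSAIDs in renal impairment,
long-term benzodiazepines, aspirin without an indication, ...).  The STOPP
criteria (Screening Tool of Older Persons' Prescriptions), version 3, make
that judgement explicit as 133 rules organised by physiological system.
`pimscreen` is for pharmacoepidemiologists and clinical-pharmacy
researchers who need to apply every one of those rules to structured
patient records and then analyse the results the way PIM-prevalence
studies do.

The package provides:

* **A rule engine** — all 133 criteria as decidable predicates over coded
  conditions, laboratory values and ATC level-5 medication orders, with a
  tri-state outcome per criterion: `triggered`, `not_triggered`, or
  `not_evaluable` when a required input (an eGFR, a QTc, a first-line
  qualifier) is missing.  One flag = one (patient, criterion, drug-set)
  instance.
* **A drug knowledge base** — a versioned ATC catalog tagging each code
  with the pharmacological classes the rules reference (`classify()`,
  `anticholinergic_burden()`).
* **Comorbidity scoring** — the original Charlson Comorbidity Index with
  the severity bands none / mild (1–2) / moderate (3–4) / severe (≥5), and
  the none / comorbidity / multimorbidity trichotomy.
* **Association statistics** — crude odds ratios from 2×2 tables
  (OR = ad/bc with Woolf confidence intervals
  exp(ln OR ± z·√(1/a+1/b+1/c+1/d))), a p < 0.25 bivariate screen, a
  multivariable logistic model reported as adjusted odds ratios, and the
  single-proportion sample size n₀ = z²p(1−p)/d² with attrition
  inflation.
* **Synthetic cohorts** — a seeded generator reproducing the marginal
  structure of a 450-patient hospital cohort, plus a deterministic
  benchmark cohort whose screening output is known exactly.

Everything is tidyverse-shaped: data frames in, tibbles out, `tidy()` /
`glance()` methods on fitted objects, `autoplot()`/`plot_*()` helpers.

## Worked example

```r
library(pimscreen)

patient <- patient_record(
  "pt-007", age_years = 74, sex = "female",
  conditions = c("hypertension", "allergy"),
  labs = list(egfr = 40),
  medications = dplyr::bind_rows(
    medication("D04AA16", daily_dose = 25, duration_days = 10,
               indication_code = "allergy", first_line = TRUE),  # pheniramine
    medication("M01AB05", daily_dose = 75, duration_days = 30,
               indication_code = "pain")                          # diclofenac
  )
)
screen_patient(patient)
#> # A tibble: 2 × 4
#>   patient_id criterion_id system_group           atc_codes
#>   <chr>      <chr>        <chr>                  <list>
#> 1 pt-007     D24          central nervous system <chr [1]>
#> 2 pt-007     E4           renal system           <chr [1]>
```

The patient collects two flags: a first-generation antihistamine used
first-line for allergy (D24) and an NSAID despite an eGFR below
50 mL/min/1.73 m² (E4).  Remove the eGFR measurement and E4 becomes
`not_evaluable` instead of silently disappearing:

```r
evaluate_criterion(patient_record("pt-008", medications =
  medication("M01AB05", daily_dose = 75, indication_code = "pain")), "E4")
#> # A tibble: 1 × 4
#>   criterion_id status        flags      missing_inputs
#>   <chr>        <chr>         <list>     <list>
#> 1 E4           not_evaluable <list [0]> <chr [1]>
```

At cohort scale, the bundled deterministic benchmark cohort exercises the
whole pipeline:

```r
cohort <- reference_cohort()          # 450 patients, built by placement
scr    <- screen_cohort(cohort)
scr
#> <pim_screen> 388 PIM flag(s) in 255 of 450 patients
pim_prevalence(scr)
#> # A tibble: 1 × 4
#>   n_flagged     n proportion percent
#> 1       255   450      0.567    56.7
head(tally_flags(scr, "drug"), 3)
#> # A tibble: 3 × 3
#>   atc_code name                     n
#> 1 B01AC06  Acetylsalicylic acid    70
#> 2 D04AA16  Pheniramine             44
#> 3 H02AB09  Hydrocortisone          28
```

Association analysis mirrors the usual study workflow:

```r
feats <- cohort_features(cohort)
feats$pim <- as.integer(feats$patient_id %in% scr$flags$patient_id)
keep <- bivariate_screen(feats, "pim",
          c("sex", "age_band", "med_count_category", "comorbidity_category"))
fit  <- fit_pim_logistic(feats, outcome = "pim",
                         terms = keep$variable[keep$selected])
tidy(fit)     # adjusted ORs with Wald 95% CIs; reference rows carry OR 1
```

And the design-stage sample size:

```r
sample_size(p = 0.64, d = 0.05, z = 1.96, attrition = 0.20)
#> [1] 425
```

## Command line

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/pimscreen.R simulate --n 450 --seed 1 --outdir out/
Rscript inst/cli/pimscreen.R screen --input out/cohort.json --outdir out/
Rscript inst/cli/pimscreen.R regress --input out/cohort.json --outdir out/
Rscript inst/cli/pimscreen.R sample-size --p 0.64 --d 0.05 --attrition 0.2
```

Exit codes: 0 success, 2 validation failure, 3 convergence/feasibility
failure.

## Documentation

The methods vignette (`vignettes/pim-screening-methods.Rmd`) documents the
rule semantics (tri-state evaluation, temporal thresholds, indication and
first-line qualifiers), the knowledge-base design, the statistical
conventions, what the synthetic generator does and does not emulate, and
the construction and limits of the benchmark cohort.
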