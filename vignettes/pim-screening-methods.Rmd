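---
title: "Methods: explicit-criteria PIM screening and its companion statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: explicit-criteria PIM screening and its companion statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pimscreen)
```

# The screening model

`pimscreen` implements the 133 explicit STOPP version 3 rules as decidable
predicates over a structured patient record: an age and sex, a set of coded
clinical conditions, a laboratory panel, and a list of medication orders
coded to ATC level 5 with daily dose, route, PRN flag, duration of use, an
optional indication code, and an optional first-line qualifier.

Each predicate combines up to four kinds of clauses:

* **drug-class clauses**, resolved through the packaged ATC catalog
  (`atc_catalog()`), in which each level-5 code carries a set of
  pharmacological class tags.  Where a rule enumerates its own membership
  (the P-glycoprotein inhibitor list, the QTc-prolonging list, the
  antimuscarinic antipsychotics), the enumeration is authoritative;
  otherwise tags follow the ATC level-3/4 subtree the class corresponds to.
  Whether a drug counts as "systemic" or "topical" is decided by the
  order's route, never by the ATC code alone.
* **condition clauses**, evaluated against the closed, versioned condition
  vocabulary.  Because the vocabulary is closed, an absent condition means
  *absent*, not *unknown*.
* **laboratory clauses**, where an absent measurement means *unknown*: a
  criterion whose drug clause matches but whose laboratory input is missing
  returns `not_evaluable` together with the names of the missing fields.
  Not-evaluable outcomes are excluded from all tallies, so "no data" is
  never conflated with "appropriate" (or "inappropriate").
* **prescribing-context clauses** — the order's indication code and the
  logical first-line qualifier.  A missing indication simply fails an
  indication match; a missing (NA) first-line qualifier makes a first-line
  rule `not_evaluable` once every other clause matches.  The one inversion
  of the missing-lab convention is the potassium-monitoring rule (B13),
  where the *absence* of a serum potassium measurement is itself the
  finding: aldosterone antagonist plus a potassium-conserving co-drug
  without a documented potassium is flagged.

## Instance counting

One flag is one (patient, criterion, triggering drug-set) instance.  Rules
whose hazard attaches to each drug separately (an NSAID in renal
impairment) emit one flag per qualifying drug; rules about a combination
(aspirin plus clopidogrel, two concomitant anticholinergics) emit a single
flag naming the whole set.  Overlapping criteria are all reported — a
single drug may legitimately generate several flags — and per-criterion,
per-system and total tallies are conserved by construction.

## Fixed interpretation choices

The published rule texts leave some clauses qualitative.  The engine fixes
them once, as follows:

* Temporal clauses: ">3 months" = >90 days, "≥4 weeks" = ≥28 days,
  "≥2 weeks" = ≥14 days, ">8 weeks" = >56 days, ">6 months" = >183 days,
  "12 weeks" = >84 days; "long-term" with no stated horizon = >90 days.
* "First-line" (amiodarone for SVT, loop diuretics for hypertension,
  digoxin for rate control, vitamin K antagonists for AF, TCAs for
  depression, phenothiazines for psychosis, first-generation
  antihistamines for allergy, strong opioids for mild pain) reads the
  per-order qualifier, since prescription-sequence history is not part of
  the record.  This is a documented simplification: the record holder
  asserts, per order, that no alternative class was tried first.
* Duplicate-class screening (A3) covers the enumerated classes — NSAIDs,
  SSRIs, loop diuretics, ACE inhibitors, anticoagulants, antipsychotics,
  opioids — over regular (non-PRN) orders only, as does the
  anticholinergic-burden count (M1).
* "Monotherapy" clauses (beta-blocker monotherapy for hypertension,
  theophylline monotherapy for COPD) are decided by the absence of any
  other drug of the relevant therapeutic group in the record.
* Sex-specific QTc limits are 450 ms (male) and 470 ms (female); the
  dose-conditional QTc drugs use 20 mg/day (citalopram) and 10 mg/day
  (escitalopram) thresholds.
* The subclinical-hypothyroidism rule takes "elevated TSH" as above a
  packaged reference limit of 4.0 mU/L (and below 10 mU/L, with normal
  free T4).
* The duration-defined-course rule (A2) is implemented for the one class
  with a packaged course convention, systemic antibiotics beyond 14 days;
  other "well-defined duration" cases are not decidable from the record.
* Antithrombotic low-dose aspirin carries the `aspirin` and `antiplatelet`
  tags but not the `nsaid` tag, so the aspirin-specific and combination
  rules of the coagulation section govern it.  The renal NSAID rule (E4)
  additionally matches aspirin: renal clearance risk applies to aspirin
  regardless of the indication for which it is prescribed, and drug-level
  screening tallies in this field attribute renal flags to aspirin.  All
  other NSAID rules (duplicate class, vascular disease, heart failure,
  anticoagulant combination, the musculoskeletal section) deliberately do
  not, to avoid double-governing the same aspirin order that the
  coagulation rules already cover.

Criteria with no instances in the benchmark workload are implemented and
unit-tested all the same; engine coverage is the full set of 133.

# Comorbidity scoring

`cci_score()` uses the original (un-age-adjusted) Charlson weights,
packaged as a data file with the same loading conventions as the drug
catalog.  Within the diabetes, liver-disease and malignancy families only
the heavier member scores.  The severity bands are mild (1–2), moderate
(3–4) and severe (≥5); a score of zero is its own band rather than being
folded into "severe", matching the reference-category structure of the
association analysis (the alternative reading — grouping unscored patients
with the severe band — contradicts the use of "no comorbidity" as a
regression reference level and is not implemented).

The none/comorbidity/multimorbidity trichotomy counts distinct chronic
conditions: diabetes, malignancies, hypertension, coronary artery disease,
and the cardio-/cerebrovascular group (MI, heart failure, peripheral
vascular disease, atrial fibrillation, cerebrovascular disease).  The
qualifying set is marked in the packaged vocabulary (`chronic` column).

# Statistical conventions

* **Crude odds ratios**: OR = ad/bc with the Woolf log-normal interval
  exp(ln OR ± z·√(1/a + 1/b + 1/c + 1/d)) and a two-sided Wald p-value on
  the log scale.  Zero cells raise a typed error; an explicit
  `correction = TRUE` applies the 0.5 continuity correction to all cells.
* **Bivariate screen**: Pearson chi-square without continuity correction
  on each k×2 table (the default of the major commercial statistics
  packages), selecting candidates at p < 0.25 for the multivariable model;
  if any expected cell is below 1 the test falls back to Fisher's exact
  test.
* **Multivariable model**: maximum-likelihood logistic regression via
  `stats::glm` (IRLS; default convergence tolerance 1e-8, up to 25
  iterations), reported as adjusted odds ratios with Wald intervals.
  Reference levels are female sex, age 60–64, the 1–4 medication band, and
  no comorbidity; reference rows carry OR exactly 1 with no interval.
  Non-convergence or suspected separation (a coefficient beyond ±15 or a
  standard error above 100 on the log scale) raises a diagnostic error
  rather than returning silent output.  Significance is flagged at
  p < 0.05.
* **Sample size**: n₀ = z²p(1−p)/d², inflated multiplicatively by the
  anticipated attrition fraction (n = n₀(1+a)) and rounded up.  The
  multiplicative form is used because it reproduces the published design
  arithmetic (0.64/0.05/1.96 plus 20% → 354.04 × 1.2 = 424.85 → 425); the
  divisor form n₀/(1−a) would give 443.
* **Display rounding** is half-up: two decimals for odds ratios, one for
  percentages.  Medians display as "median (Q3–Q1)", the convention of the
  descriptive tables this package mirrors.  Note that 255/450 = 56.67%
  rounds to 56.7%; the widely quoted 56.6% for this proportion is a
  truncation, and the package reports the computed value.

# Medication-count bands

The descriptive bands "<4", "5–9", ">10" leave counts of exactly 4 and 10
unassigned.  The package closes the partition minimally: low = 1–4,
mid = 5–9, high = ≥10.  Polypharmacy (four or more medications) therefore
spans the top of the low band plus the mid and high bands.

# The synthetic cohort generator

`simulate_cohort()` emulates the *marginal* structure of a 450-patient
older-adult inpatient cohort: 55.3% male; age bands with probabilities
(114, 135, 95, 35, 33, 38)/450; medication bands (91, 309, 50)/450 with
counts uniform within band (1–4, 5–9, 10–14); background hypertension
(0.496) and type-2 diabetes (0.338); and per-criterion trigger rates equal
to the reference instance counts over 450.  A triggered criterion attaches
its canonical prescription bundle (`trigger_unit()`) — drug orders plus the
conditions and just-past-threshold laboratory values the rule needs (for
example eGFR 40 for the renal NSAID rule) — so triggers are unambiguous.
Remaining medication slots are filled from a neutral list that satisfies
no rule.

What the generator does **not** emulate: the joint dependence structure of
real prescribing (comorbidity clusters, co-prescription correlations,
ward effects), longitudinal prescribing histories, and trigger-bundle
interactions (a bundle is skipped when its laboratory demands conflict
with one already attached, so realized trigger frequencies sit slightly
below nominal rates).  Tests that pass on synthetic cohorts therefore
validate the *bookkeeping and estimation machinery* under known
conditions, not the epidemiology of any real population.

`plant_pim_exposure()` serves the parameter-recovery simulation: it draws
a binary PIM-exposure outcome from a logistic model with planted log-odds
— by default the published adjusted odds ratios (male 1.31; age bands
1.35, 1.38, 1.76, 1.54, 0.77; medication bands 2.89 and 8.42; comorbidity
3.12 and multimorbidity 2.11) and an intercept of −1.70, chosen once so
that the implied overall exposure prevalence under the study marginals is
near 56%.  `recovery_simulation()` refits the model on each replicate and
reports empirical coverage of the 95% Wald intervals; at n = 450 over 500
replicates coverage sits near 0.95 (slightly below for the sparsest
cells, as expected of Wald intervals at these counts).

# The deterministic benchmark cohort

`reference_cohort()` is the package's fixed screening workload: 450
patients built by direct placement so that screening reproduces exactly a
reference profile of 388 flag instances across 44 active criteria, 255
flagged patients with per-patient counts distributed 163/62/22/5/3 over
1–5 flags, and a drug attribution led by acetylsalicylic acid (70
instances, 18% of flags), pheniramine (44), hydrocortisone (28), tramadol
(23), hydralazine (22) and diclofenac (18).

Construction assigns triggering units to patients greedily, largest
patients first.  Every candidate placement is verified by *screening the
assembled patient* and requiring the flag multiset to equal the union of
the units' standalone flags — so no two placed units can interact to
create or suppress a flag, whatever subtleties the rule set contains.  One
deliberate multi-flag unit exists: clonazepam in a faller is both a
benzodiazepine and an antiepileptic and correctly fires both falls-risk
rules at once.  The construction uses no random numbers; rebuilding yields
the identical object.

Two reconstruction limits are worth knowing.  First, the per-patient
assignment of flags to multi-flag patients is one valid arrangement among
many; only the counts are pinned.  Second, a handful of drug-attribution
rows cannot be made consistent with the per-criterion profile under any
arrangement — the digoxin-specific rate-control criterion alone
contributes 7 instances, and reaching 12 clopidogrel or 7 enoxaparin
instances would require flags that the active criteria cannot attribute to
those drugs without breaking the aspirin total of 70.  The benchmark
therefore pins the top attribution rows and the complete criterion
profile, and treats the remaining attribution tail as free.

# Problem sizes used by the test suite

The shipped suite runs the full 133-criterion coverage matrix, screens the
450-patient benchmark twice, sweeps the conservation and order-invariance
invariants over 1,000 simulated 10-patient cohorts, and runs the recovery
simulation at n = 450 with 500 replicates — sizes chosen so the whole
suite completes in a few minutes on one core while keeping Monte-Carlo
noise well inside the asserted bands.

# Known limitations

* First-line and indication semantics rely on per-order qualifiers; a
  record without them yields `not_evaluable` (first-line) or a failed
  indication match rather than a clinical inference.
* The antimuscarinic-burden tag list follows the drugs enumerated in the
  rule texts; no graded anticholinergic-potency scale is applied.
* The packaged ATC catalog is a curated subset sufficient for the rule
  set, not the full WHO index; unknown codes classify to an empty tag set
  with a warning.
* The engine reports all overlapping flags; it does not rank severity or
  suggest alternatives.
* START (omission) screening is out of scope.
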