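# The deterministic benchmark cohort.
#
# A 450-patient cohort constructed by direct placement (not sampling) so
# that screening it reproduces, exactly, the package's reference screening
# workload: a fixed per-criterion instance profile (388 flags over 44
# active criteria), 255 flagged patients with per-patient PIM counts
# distributed as 163/62/22/5/3 for 1/2/3/4/5 flags, and the drug
# attribution of the leading inappropriately prescribed medications
# (acetylsalicylic acid 70 instances, pheniramine 44, hydrocortisone 28,
# tramadol 23, hydralazine 22, diclofenac 18, ...).
#
# Units are assigned to patients greedily; every candidate combination is
# verified by actually screening the assembled patient, so no pair of
# placed units can interact to create or suppress a flag.

# reference per-criterion instance counts (zero-count criteria omitted)
REFERENCE_COUNTS <- c(
  A1 = 3, A3 = 3,
  B2 = 2, B4 = 2, B5 = 23, B6 = 1, B7 = 12, B8 = 9, B13 = 1, B15 = 6,
  B16 = 1, B17 = 1, B18 = 2, B19 = 4, B21 = 7,
  C1 = 5, C2 = 4, C3 = 4, C4 = 2, C5 = 13, C10 = 3, C11 = 3, C12 = 1,
  C14 = 2, C16 = 15,
  D7 = 4, D8 = 7, D9 = 2, D10 = 4, D12 = 2, D13 = 7, D14 = 1, D24 = 44,
  E4 = 39, E6 = 1,
  F2 = 5, F6 = 3,
  G1 = 1, G2 = 29,
  H2 = 1,
  I5 = 1, I8 = 5,
  J1 = 12, J2 = 6, J4 = 1, J8 = 1, J9 = 2,
  K1 = 6, K2 = 5, K3 = 27, K5 = 7, K6 = 2, K7 = 1,
  L1 = 6, L2 = 16, L5 = 8,
  M1 = 3
)

# per-patient PIM count distribution: 163 patients with one flag, 62 with
# two, 22 with three, 5 with four, 3 with five (255 flagged, 388 flags)
REFERENCE_PIM_DISTRIBUTION <- c(`1` = 163, `2` = 62, `3` = 22, `4` = 5, `5` = 3)
REFERENCE_N <- 450L

#' Reference per-criterion instance counts
#'
#' The per-criterion flag counts of the package's benchmark screening
#' workload (zero for criteria outside the active set).  [reference_cohort()]
#' is constructed to reproduce these exactly.
#'
#' @return Tibble with `criterion_id`, `system_group`, `n`.
#' @export
reference_criterion_counts <- function() {
  reg <- stopp_criteria()
  n <- REFERENCE_COUNTS[reg$criterion_id]
  n[is.na(n)] <- 0L
  tibble::tibble(
    criterion_id = reg$criterion_id,
    system_group = reg$system_group,
    n = as.integer(n)
  )
}

# (criterion, variant, count) allocation realising the reference profile
fixture_allocation <- function() {
  al <- list(
    c("A1", 1, 3), c("A3", 1, 1), c("A3", 2, 1), c("A3", 3, 1),
    c("B2", 1, 2), c("B4", 1, 2),
    c("B5", 1, 6), c("B5", 2, 5), c("B5", 3, 5), c("B5", 4, 4), c("B5", 5, 3),
    c("B6", 1, 1), c("B7", 1, 12), c("B8", 1, 9), c("B13", 1, 1),
    c("B15", 1, 3), c("B15", 2, 3), c("B16", 1, 1), c("B17", 1, 1),
    c("B18", 1, 2), c("B19", 1, 4), c("B21", 1, 7),
    c("C1", 1, 5), c("C2", 1, 4), c("C3", 1, 4), c("C4", 1, 2),
    c("C5", 1, 2), c("C5", 2, 4), c("C5", 3, 4), c("C5", 4, 3),
    c("C10", 1, 3), c("C11", 1, 3), c("C12", 1, 1), c("C14", 1, 2),
    c("C16", 1, 15),
    c("D7", 1, 4), c("D8", 1, 7), c("D9", 1, 2), c("D10", 1, 4),
    c("D12", 1, 2), c("D13", 1, 7), c("D14", 1, 1), c("D24", 1, 44),
    c("E4", 1, 21), c("E4", 2, 18), c("E6", 1, 1),
    c("F2", 1, 5), c("F6", 1, 3),
    c("G1", 1, 1), c("G2", 1, 28), c("G2", 2, 1),
    c("H2", 1, 1),
    c("I5", 1, 1), c("I8", 1, 5),
    c("J1", 1, 8), c("J1", 2, 4), c("J2", 1, 6), c("J4", 1, 1),
    c("J8", 1, 1), c("J9", 1, 2),
    # a clonazepam-with-falls unit fires both the benzodiazepine and the
    # antiepileptic falls criteria (the drug belongs to both classes)
    c("K1", 1, 6), c("K2", 1, 4), c("K2", 2, 1),
    c("K3", 1, 22), c("K3", 2, 5),
    c("K5", 1, 1), c("K6", 1, 2), c("K7", 1, 1),
    c("L1", 1, 6), c("L2", 1, 16), c("L5", 1, 4), c("L5", 2, 4),
    c("M1", 1, 1), c("M1", 2, 1), c("M1", 3, 1)
  )
  tibble::tibble(
    criterion = vapply(al, `[`, character(1), 1),
    variant = as.integer(vapply(al, `[`, character(1), 2)),
    count = as.integer(vapply(al, `[`, character(1), 3))
  )
}

fixture_units <- function() {
  al <- fixture_allocation()
  units <- list()
  for (r in seq_len(nrow(al))) {
    u <- trigger_unit(al$criterion[[r]], al$variant[[r]])
    # the flags a unit produces on its own; placement preserves this set
    u$flags0 <- sort(screen_patient(unit_patient(list(u)))$criterion_id)
    for (k in seq_len(al$count[[r]])) units[[length(units) + 1L]] <- u
  }
  # interleave by criterion (k-th unit of each criterion in turn) so that
  # the greedy packer always sees a diverse pool
  crit <- vapply(units, function(u) u$criterion, character(1))
  rank_within <- stats::ave(seq_along(units), crit, FUN = seq_along)
  units[order(rank_within, match(crit, unique(crit)))]
}

# static incompatibilities that make screening pointless: a shared drug
# code, conflicting lab values, or conflicting sex/age demands
units_mergeable <- function(units, candidate) {
  codes <- unlist(lapply(units, function(u) u$meds$atc_code))
  if (any(candidate$meds$atc_code %in% codes)) return(FALSE)
  labs <- list()
  for (u in units) for (nm in names(u$labs)) labs[[nm]] <- u$labs[[nm]]
  for (nm in names(candidate$labs)) {
    if (!is.null(labs[[nm]]) && !identical(labs[[nm]], candidate$labs[[nm]])) {
      return(FALSE)
    }
  }
  sexes <- c(vapply(units, function(u) u$sex, character(1)), candidate$sex)
  sexes <- unique(sexes[!is.na(sexes)])
  if (length(sexes) > 1L) return(FALSE)
  ages <- c(vapply(units, function(u) u$age, integer(1)), candidate$age)
  ages <- unique(ages[!is.na(ages)])
  if (length(ages) > 1L) return(FALSE)
  TRUE
}

# does the assembled patient screen to exactly the union of the units'
# standalone flag multisets (no interaction created or suppressed a flag)?
units_consistent <- function(units, id, age, sex) {
  patient <- unit_patient(units, id, age, sex)
  got <- sort(screen_patient(patient)$criterion_id)
  want <- sort(unlist(lapply(units, function(u) u$flags0)))
  identical(got, want)
}

#' Deterministic benchmark cohort
#'
#' Builds (and caches) the 450-patient cohort whose screening output
#' reproduces the package's reference workload exactly: 388 flags, the
#' per-criterion profile of [reference_criterion_counts()], 255 flagged
#' patients distributed 163/62/22/5/3 over 1-5 flags each, and the
#' reference drug attribution.  Construction is by direct placement and is
#' fully deterministic; no random numbers are involved.
#'
#' @return A validated `pim_cohort` of 450 patients.
#' @export
reference_cohort <- function() {
  if (!is.null(the$reference_cohort)) return(the$reference_cohort)
  pool <- fixture_units()
  taken <- rep(FALSE, length(pool))
  sizes <- rep(as.integer(names(REFERENCE_PIM_DISTRIBUTION)),
               REFERENCE_PIM_DISTRIBUTION)
  sizes <- sort(sizes, decreasing = TRUE)
  patients <- vector("list", REFERENCE_N)

  base_age <- function(i) 60L + (i * 7L) %% 26L
  base_sex <- function(i) if (i %% 2L == 0L) "female" else "male"

  weights <- vapply(pool, function(u) length(u$flags0), integer(1))
  for (p in seq_along(sizes)) {
    k <- sizes[[p]]
    id <- sprintf("P%03d", p)
    age <- base_age(p); sex <- base_sex(p)
    placed <- integer()
    remaining <- k
    while (remaining > 0L) {
      found <- FALSE
      for (j in which(!taken)) {
        if (weights[[j]] > remaining) next
        cand <- pool[[j]]
        if (length(placed) &&
            !units_mergeable(pool[placed], cand)) next
        if (!units_consistent(c(pool[placed], list(cand)), id, age, sex)) next
        placed <- c(placed, j)
        taken[[j]] <- TRUE
        remaining <- remaining - weights[[j]]
        found <- TRUE
        break
      }
      if (!found) {
        abort(paste0("benchmark cohort construction failed at patient ", p,
                     " (", remaining, " flag(s) unfilled)"),
              class = "pimscreen_internal_error")
      }
    }
    patients[[p]] <- unit_patient(pool[placed], id, age, sex)
  }

  # 195 patients with no inappropriate prescription
  fillers <- list(
    medication("N02BE01", daily_dose = 500, duration_days = 5L,
               indication_code = "pain"),
    dplyr::bind_rows(
      medication("N02BE01", daily_dose = 500, duration_days = 5L,
                 indication_code = "pain"),
      medication("R06AE07", daily_dose = 10, duration_days = 10L,
                 indication_code = "allergy", first_line = FALSE)
    ),
    dplyr::bind_rows(
      medication("A11GA01", daily_dose = 100, duration_days = 30L,
                 indication_code = "anemia"),
      medication("N02BE01", daily_dose = 1000, duration_days = 5L,
                 indication_code = "pain")
    )
  )
  for (p in seq.int(length(sizes) + 1L, REFERENCE_N)) {
    patients[[p]] <- patient_record(
      sprintf("P%03d", p), age_years = base_age(p), sex = base_sex(p),
      conditions = if (p %% 3L == 0L) "hypertension" else character(),
      medications = fillers[[(p %% 3L) + 1L]]
    )
  }

  cohort <- as_cohort(
    dplyr::bind_rows(patients),
    metadata = list(source = "pimscreen reference workload",
                    versions = as.list(knowledge_versions()))
  )
  the$reference_cohort <- cohort
  cohort
}

#' Reference exposure-by-outcome counts
#'
#' The published cross-tabulation of PIM exposure (yes/no) against the four
#' study covariates, used as printed-count input to the odds-ratio examples
#' and the bivariate screen.  `reference` marks each covariate's baseline
#' level.
#'
#' @return Tibble with `variable`, `level`, `pim_yes`, `pim_no`,
#'   `reference`.
#' @export
reference_exposure_counts <- function() {
  tibble::tribble(
    ~variable, ~level, ~pim_yes, ~pim_no, ~reference,
    "sex", "female", 110L, 91L, TRUE,
    "sex", "male", 145L, 104L, FALSE,
    "age_band", "60-64", 63L, 51L, TRUE,
    "age_band", "65-69", 77L, 58L, FALSE,
    "age_band", "70-74", 55L, 40L, FALSE,
    "age_band", "75-79", 22L, 13L, FALSE,
    "age_band", "80-84", 21L, 12L, FALSE,
    "age_band", "85+", 17L, 21L, FALSE,
    "med_count_category", "low", 30L, 61L, TRUE,
    "med_count_category", "mid", 184L, 125L, FALSE,
    "med_count_category", "high", 41L, 9L, FALSE,
    "comorbidity_category", "none", 53L, 85L, TRUE,
    "comorbidity_category", "comorbidity", 106L, 52L, FALSE,
    "comorbidity_category", "multimorbidity", 96L, 58L, FALSE
  )
}
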