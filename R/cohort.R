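# Domain types: medication orders, patient records, cohorts.
#
# A cohort is a tibble with one row per patient and list-columns for the
# nested parts (conditions, labs, medications), so the whole object pipes
# through dplyr verbs while keeping the nested structure intact.

LAB_FIELDS_NUM <- c(
  "egfr", "serum_k", "serum_na", "corrected_ca", "systolic_bp",
  "diastolic_bp", "heart_rate", "qtc_ms", "po2_kpa", "pco2_kpa",
  "tsh_mu_l", "bmi"
)
LAB_FIELDS <- c(LAB_FIELDS_NUM, "free_t4_status")
ROUTES <- c("oral", "parenteral", "topical", "transdermal", "inhaled", "other")
DOSE_UNITS <- c("mg", "ug", "g")
SEXES <- c("male", "female")

MED_COLS <- c(
  "atc_code", "name", "daily_dose", "dose_unit", "route", "prn",
  "duration_days", "indication_code", "first_line"
)

validation_error <- function(...) {
  abort(paste0(...), class = "pimscreen_validation_error")
}

#' Build medication-order rows
#'
#' Convenience constructor for the medication table consumed by
#' [as_cohort()] and the screening engine.  Vectorised over all arguments.
#'
#' @param atc_code ATC level-5 code (7 characters, e.g. `"B01AC06"`).
#' @param name Optional free-text drug name; defaults to the catalog name.
#' @param daily_dose Non-negative daily dose in `dose_unit`.
#' @param dose_unit One of `"mg"`, `"ug"`, `"g"`.
#' @param route One of oral, parenteral, topical, transdermal, inhaled, other.
#' @param prn Logical; `TRUE` for as-needed orders, `FALSE` for regular use.
#' @param duration_days Non-negative integer days of continuous use to date.
#' @param indication_code Optional condition code the drug was prescribed
#'   for; the special code `"none"` records an explicitly absent indication.
#' @param first_line Logical qualifier: is this drug first-line therapy for
#'   its indication (no alternative class tried)?  `NA` when unknown.
#' @return A tibble with one row per order.
#' @export
#' @examples
#' medication("M01AB05", daily_dose = 75, duration_days = 30)
medication <- function(atc_code, name = NULL, daily_dose = 0, dose_unit = "mg",
                       route = "oral", prn = FALSE, duration_days = 0L,
                       indication_code = NA_character_, first_line = NA) {
  n <- length(atc_code)
  if (is.null(name)) {
    cat <- atc_catalog()
    name <- cat$name[match(atc_code, cat$code)]
    name[is.na(name)] <- atc_code[is.na(name)]
  }
  tibble::tibble(
    atc_code = as.character(atc_code),
    name = rep_len(as.character(name), n),
    daily_dose = rep_len(as.numeric(daily_dose), n),
    dose_unit = rep_len(as.character(dose_unit), n),
    route = rep_len(as.character(route), n),
    prn = rep_len(as.logical(prn), n),
    duration_days = rep_len(as.integer(duration_days), n),
    indication_code = rep_len(as.character(indication_code), n),
    first_line = rep_len(as.logical(first_line), n)
  )
}

#' Build a single patient record
#'
#' @param patient_id Opaque identifier, unique within a cohort.
#' @param age_years Integer age, at least 60 (study inclusion rule).
#' @param sex `"male"` or `"female"`.
#' @param conditions Character vector of condition codes from
#'   [condition_vocabulary()].
#' @param labs Named list of laboratory values (see the lab panel fields in
#'   the package vignette); absent labs are simply omitted, which is distinct
#'   from a value of zero.
#' @param medications Medication tibble from [medication()]; must be
#'   non-empty.
#' @return A one-row cohort tibble (unvalidated; see [as_cohort()]).
#' @export
patient_record <- function(patient_id, age_years = 70L, sex = "male",
                           conditions = character(), labs = list(),
                           medications) {
  tibble::tibble(
    patient_id = as.character(patient_id),
    age_years = as.integer(age_years),
    sex = as.character(sex),
    conditions = list(as.character(conditions)),
    labs = list(labs),
    medications = list(medications)
  )
}

new_cohort <- function(patients, metadata = list()) {
  structure(
    patients,
    metadata = metadata,
    class = c("pim_cohort", class(tibble::tibble()))
  )
}

#' Assemble and validate a cohort
#'
#' Accepts either a nested patient tibble (list-columns `conditions`, `labs`,
#' `medications`) or a flat patient table plus a long-format medication table
#' keyed by `patient_id` (the CSV interchange layout, in which lab values are
#' ordinary columns and `conditions` is a semicolon-separated string).
#'
#' @param patients Patient data frame.
#' @param medications Optional long-format medication data frame.
#' @param metadata Optional list (source label, creation seed, ...).
#' @param validate Run [validate_cohort()] (default `TRUE`).
#' @return A `pim_cohort` tibble.
#' @export
as_cohort <- function(patients, medications = NULL, metadata = list(),
                      validate = TRUE) {
  patients <- tibble::as_tibble(patients)
  if (!is.null(medications)) {
    medications <- tibble::as_tibble(medications)
    med_split <- split(medications[MED_COLS], factor(medications$patient_id, levels = patients$patient_id))
    patients$medications <- unname(med_split[patients$patient_id])
  }
  if (!is.list(patients$conditions)) {
    conds <- as.character(patients$conditions)
    patients$conditions <- lapply(conds, function(x) {
      if (is.na(x) || !nzchar(x)) character() else strsplit(x, ";", fixed = TRUE)[[1]]
    })
  }
  if (!("labs" %in% names(patients)) || !is.list(patients$labs)) {
    present <- intersect(LAB_FIELDS, names(patients))
    patients$labs <- lapply(seq_len(nrow(patients)), function(i) {
      vals <- as.list(patients[i, present, drop = FALSE])
      vals[!vapply(vals, function(v) is.na(v), logical(1))]
    })
    patients <- patients[setdiff(names(patients), present)]
  }
  keep <- c("patient_id", "age_years", "sex", "conditions", "labs", "medications")
  missing_cols <- setdiff(keep, names(patients))
  if (length(missing_cols)) {
    validation_error("patient table lacks required column(s): ",
                     paste(missing_cols, collapse = ", "))
  }
  patients$patient_id <- as.character(patients$patient_id)
  patients$age_years <- as.integer(patients$age_years)
  cohort <- new_cohort(patients[keep], metadata)
  if (validate) validate_cohort(cohort)
  cohort
}

#' Validate a cohort against the domain invariants
#'
#' Validation is total: every violation raises a typed condition
#' (`pimscreen_validation_error`) naming the offending record and field;
#' nothing is silently coerced.
#'
#' @param cohort A `pim_cohort`.
#' @return Invisibly `TRUE` when the cohort is valid.
#' @export
validate_cohort <- function(cohort) {
  if (nrow(cohort) == 0L) validation_error("cohort is empty")
  ids <- cohort$patient_id
  if (anyDuplicated(ids)) {
    validation_error("duplicate patient_id: ",
                     paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  vocab <- condition_vocabulary()$code
  for (i in seq_len(nrow(cohort))) {
    id <- ids[[i]]
    age <- cohort$age_years[[i]]
    if (is.na(age) || age < 60L) {
      validation_error("patient ", id, ": age_years ", age,
                       " is below the inclusion threshold 60")
    }
    if (!(cohort$sex[[i]] %in% SEXES)) {
      validation_error("patient ", id, ": sex must be one of ",
                       paste(SEXES, collapse = ", "))
    }
    conds <- cohort$conditions[[i]]
    unknown <- setdiff(conds, vocab)
    if (length(unknown)) {
      validation_error("patient ", id, ": unknown condition code(s): ",
                       paste(unknown, collapse = ", "))
    }
    labs <- cohort$labs[[i]]
    if (length(labs)) {
      bad_name <- setdiff(names(labs), LAB_FIELDS)
      if (length(bad_name)) {
        validation_error("patient ", id, ": unknown lab field(s): ",
                         paste(bad_name, collapse = ", "))
      }
      for (f in intersect(names(labs), LAB_FIELDS_NUM)) {
        v <- labs[[f]]
        if (!is.numeric(v) || is.na(v) || v <= 0) {
          validation_error("patient ", id, ": lab ", f,
                           " must be a strictly positive number")
        }
      }
      if ("free_t4_status" %in% names(labs) &&
          !(labs$free_t4_status %in% c("low", "normal", "high"))) {
        validation_error("patient ", id,
                         ": free_t4_status must be low, normal or high")
      }
    }
    meds <- cohort$medications[[i]]
    if (is.null(meds) || nrow(meds) == 0L) {
      validation_error("patient ", id,
                       ": medications must be non-empty (inclusion rule: ",
                       "at least one prescribed medication)")
    }
    bad_atc <- !grepl(ATC_CODE_REGEX, meds$atc_code)
    if (any(bad_atc)) {
      validation_error("patient ", id, ": malformed atc_code: ",
                       paste(meds$atc_code[bad_atc], collapse = ", "))
    }
    if (any(is.na(meds$daily_dose) | meds$daily_dose < 0)) {
      validation_error("patient ", id, ": daily_dose must be non-negative")
    }
    if (!all(meds$dose_unit %in% DOSE_UNITS)) {
      validation_error("patient ", id, ": dose_unit must be one of ",
                       paste(DOSE_UNITS, collapse = ", "),
                       " (no silent unit conversion)")
    }
    if (!all(meds$route %in% ROUTES)) {
      validation_error("patient ", id, ": route must be one of ",
                       paste(ROUTES, collapse = ", "))
    }
    if (any(is.na(meds$prn))) {
      validation_error("patient ", id, ": prn flag must be TRUE or FALSE")
    }
    if (any(is.na(meds$duration_days) | meds$duration_days < 0L)) {
      validation_error("patient ", id, ": duration_days must be non-negative")
    }
    ind <- meds$indication_code
    unknown_ind <- setdiff(ind[!is.na(ind)], vocab)
    if (length(unknown_ind)) {
      validation_error("patient ", id, ": unknown indication code(s): ",
                       paste(unknown_ind, collapse = ", "))
    }
  }
  invisible(TRUE)
}

#' Medication-count band of the study
#'
#' Bands: low = 1-4 medications, mid = 5-9, high = 10 or more.  The printed
#' band labels ("<4", "5-9", ">10") leave 4 and 10 unassigned; the package
#' closes the partition by assigning 4 to the low band and 10 to the high
#' band, so the three bands are exhaustive and mutually exclusive.
#'
#' @param n_medications Integer vector of per-patient medication counts.
#' @return Factor with levels `low`, `mid`, `high`.
#' @export
#' @examples
#' medication_count_category(c(3, 6, 10))
medication_count_category <- function(n_medications) {
  stopifnot(all(n_medications >= 1L))
  cut(n_medications, breaks = c(0, 4, 9, Inf), labels = c("low", "mid", "high"))
}

AGE_BANDS <- c("60-64", "65-69", "70-74", "75-79", "80-84", "85+")

age_band <- function(age_years) {
  cut(age_years, breaks = c(59, 64, 69, 74, 79, 84, Inf), labels = AGE_BANDS)
}

#' Per-patient analysis features
#'
#' Flattens a cohort into the per-patient covariate table used by the
#' summary and regression stages: age band, medication-count band, Charlson
#' score and band, and the comorbidity trichotomy.
#'
#' @param cohort A validated `pim_cohort`.
#' @return A tibble with one row per patient.
#' @export
cohort_features <- function(cohort) {
  n_meds <- vapply(cohort$medications, nrow, integer(1))
  cci <- lapply(cohort$conditions, cci_score)
  tibble::tibble(
    patient_id = cohort$patient_id,
    age_years = cohort$age_years,
    age_band = age_band(cohort$age_years),
    sex = factor(cohort$sex, levels = c("female", "male")),
    n_medications = n_meds,
    med_count_category = medication_count_category(n_meds),
    cci_score = vapply(cci, function(x) x$score, integer(1)),
    cci_band = factor(vapply(cci, function(x) x$band, character(1)),
                      levels = c("none", "mild", "moderate", "severe")),
    comorbidity_category = factor(
      vapply(cohort$conditions, comorbidity_category, character(1)),
      levels = c("none", "comorbidity", "multimorbidity")
    )
  )
}

#' @export
print.pim_cohort <- function(x, ...) {
  meta <- attr(x, "metadata")
  cat("<pim_cohort> ", nrow(x), " patients", sep = "")
  if (!is.null(meta$source)) cat(" | source: ", meta$source, sep = "")
  if (!is.null(meta$seed)) cat(" | seed: ", meta$seed, sep = "")
  cat("\n")
  NextMethod()
}
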