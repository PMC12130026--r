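# Cohort interchange formats.
#
# JSON is the canonical format: one object per patient with nested
# medication and condition arrays and a labs object (absent labs are simply
# missing keys, never zero).  The CSV layout is a directory holding
# patients.csv (labs as columns, conditions semicolon-joined) and
# medications.csv (long format keyed by patient_id).  A machine-readable
# schema for the JSON layout ships in inst/extdata/cohort-schema.json.

MED_DEFAULTS <- list(
  name = NA_character_, daily_dose = 0, dose_unit = "mg", route = "oral",
  prn = FALSE, duration_days = 0L, indication_code = NA_character_,
  first_line = NA
)

normalize_medications <- function(meds) {
  meds <- tibble::as_tibble(meds)
  for (col in names(MED_DEFAULTS)) {
    if (!col %in% names(meds)) meds[[col]] <- MED_DEFAULTS[[col]]
  }
  meds$atc_code <- as.character(meds$atc_code)
  meds$name <- as.character(meds$name)
  meds$daily_dose <- as.numeric(meds$daily_dose)
  meds$dose_unit <- as.character(meds$dose_unit)
  meds$route <- as.character(meds$route)
  meds$prn <- as.logical(meds$prn)
  meds$duration_days <- as.integer(meds$duration_days)
  meds$indication_code <- as.character(meds$indication_code)
  meds$first_line <- as.logical(meds$first_line)
  meds[, MED_COLS]
}

#' Read a cohort from JSON or CSV
#'
#' @param path For JSON, the file path; for CSV, the directory containing
#'   `patients.csv` and `medications.csv`.
#' @param format `"json"` (canonical) or `"csv"`.
#' @return A validated [as_cohort()] object.
#' @export
read_cohort <- function(path, format = c("json", "csv")) {
  format <- match.arg(format)
  if (format == "json") {
    if (!file.exists(path)) abort(paste0("no such file: ", path))
    doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    pats <- doc$patients
    rows <- lapply(pats, function(p) {
      meds <- normalize_medications(
        dplyr::bind_rows(lapply(p$medications, function(m) {
          tibble::as_tibble(m[!vapply(m, is.null, logical(1))])
        }))
      )
      labs <- p$labs %||% list()
      for (nm in intersect(names(labs), LAB_FIELDS_NUM)) {
        labs[[nm]] <- as.numeric(labs[[nm]])
      }
      patient_record(
        patient_id = p$patient_id,
        age_years = p$age_years,
        sex = p$sex,
        conditions = unlist(p$conditions) %||% character(),
        labs = labs,
        medications = meds
      )
    })
    meta <- doc$metadata %||% list()
    as_cohort(dplyr::bind_rows(rows), metadata = meta)
  } else {
    pfile <- file.path(path, "patients.csv")
    mfile <- file.path(path, "medications.csv")
    if (!file.exists(pfile) || !file.exists(mfile)) {
      abort(paste0("CSV cohort directory must contain patients.csv and ",
                   "medications.csv: ", path))
    }
    hdr <- names(readr::read_csv(pfile, n_max = 0,
                                 col_types = readr::cols(.default = readr::col_character()),
                                 progress = FALSE))
    char_cols <- intersect(c("patient_id", "sex", "conditions",
                             "free_t4_status"), hdr)
    spec <- c(
      setNames(lapply(char_cols, function(x) readr::col_character()), char_cols),
      list(age_years = readr::col_integer())
    )
    patients <- readr::read_csv(
      pfile,
      col_types = do.call(readr::cols,
                          c(spec, list(.default = readr::col_double()))),
      progress = FALSE
    )
    meds <- readr::read_csv(mfile, col_types = readr::cols(
      patient_id = readr::col_character(),
      atc_code = readr::col_character(),
      name = readr::col_character(),
      daily_dose = readr::col_double(),
      dose_unit = readr::col_character(),
      route = readr::col_character(),
      prn = readr::col_logical(),
      duration_days = readr::col_integer(),
      indication_code = readr::col_character(),
      first_line = readr::col_logical()
    ), progress = FALSE)
    meds_norm <- normalize_medications(meds)
    meds_norm$patient_id <- meds$patient_id
    as_cohort(patients, medications = meds_norm,
              metadata = list(source = path))
  }
}

#' Write a cohort to JSON or CSV
#'
#' The emitted file round-trips: reading it back yields a cohort equal
#' field-by-field, with numbers preserved at full precision.
#'
#' @param cohort A validated `pim_cohort`.
#' @param path Output file (JSON) or directory (CSV; created if needed).
#' @param format `"json"` or `"csv"`.
#' @return Invisibly, `path`.
#' @export
write_cohort <- function(cohort, path, format = c("json", "csv")) {
  format <- match.arg(format)
  validate_cohort(cohort)
  if (format == "json") {
    pats <- lapply(seq_len(nrow(cohort)), function(i) {
      meds <- cohort$medications[[i]]
      list(
        patient_id = cohort$patient_id[[i]],
        age_years = cohort$age_years[[i]],
        sex = cohort$sex[[i]],
        conditions = as.list(cohort$conditions[[i]]),
        labs = cohort$labs[[i]],
        medications = lapply(seq_len(nrow(meds)), function(j) {
          row <- as.list(meds[j, ])
          row[!vapply(row, function(v) is.na(v) && !is.logical(v), logical(1))]
        })
      )
    })
    meta <- attr(cohort, "metadata")
    doc <- list(metadata = if (length(meta)) meta else NULL, patients = pats)
    doc <- doc[!vapply(doc, is.null, logical(1))]
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         pretty = FALSE, null = "null")
  } else {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    labs_wide <- dplyr::bind_rows(lapply(cohort$labs, function(l) {
      if (!length(l)) return(tibble::tibble(.rows = 1))
      tibble::as_tibble(l)
    }))
    patients <- tibble::tibble(
      patient_id = cohort$patient_id,
      age_years = cohort$age_years,
      sex = cohort$sex,
      conditions = vapply(cohort$conditions, paste, character(1), collapse = ";")
    )
    patients <- dplyr::bind_cols(patients, labs_wide)
    meds <- dplyr::bind_rows(
      lapply(seq_len(nrow(cohort)), function(i) {
        dplyr::mutate(cohort$medications[[i]],
                      patient_id = cohort$patient_id[[i]], .before = 1)
      })
    )
    readr::write_csv(patients, file.path(path, "patients.csv"), na = "")
    readr::write_csv(meds, file.path(path, "medications.csv"), na = "")
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
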