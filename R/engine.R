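# Rule-engine core: patient evaluation context, tri-state outcome
# constructors, and the screening/tally operations.
#
# Every criterion predicate is a pure function of the evaluation context and
# returns one of three outcomes: triggered (with the ATC code set(s) that
# satisfy the drug clause), not_triggered, or not_evaluable with the names
# of the missing inputs.  Condition codes are a closed set, so an absent
# condition means "absent", while an absent laboratory value means
# "unknown" and renders lab-gated criteria not evaluable.

DOSE_FACTOR <- c(mg = 1, g = 1000, ug = 0.001)

build_ctx <- function(cohort, i) {
  meds <- cohort$medications[[i]]
  list(
    id = cohort$patient_id[[i]],
    age = cohort$age_years[[i]],
    sex = cohort$sex[[i]],
    conds = cohort$conditions[[i]],
    labs = cohort$labs[[i]],
    tg = tags_of(meds$atc_code),
    codes = meds$atc_code,
    dose_mg = meds$daily_dose * unname(DOSE_FACTOR[meds$dose_unit]),
    route = meds$route,
    reg = !meds$prn,
    dur = meds$duration_days,
    ind = meds$indication_code,
    fl = meds$first_line
  )
}

# --- outcome constructors -------------------------------------------------

o_trig <- function(flags) list(status = "triggered", flags = flags,
                               missing = character())
o_not <- function() list(status = "not_triggered", flags = list(),
                         missing = character())
o_ne <- function(...) list(status = "not_evaluable", flags = list(),
                           missing = c(...))

each <- function(codes) as.list(unique(codes))
once <- function(codes) list(sort(unique(codes)))

# --- predicate helpers ----------------------------------------------------

mt <- function(ctx, tags) {
  vapply(ctx$tg, function(x) any(x %in% tags), logical(1))
}

hc <- function(ctx, conds) any(conds %in% ctx$conds)

lb <- function(ctx, field) {
  v <- ctx$labs[[field]]
  if (is.null(v)) return(NULL)
  if (is.numeric(v) && is.na(v)) return(NULL)
  v
}

# lab comparison that propagates "unknown" as NA
lab_cmp <- function(ctx, field, op, thr) {
  v <- lb(ctx, field)
  if (is.null(v)) NA else op(v, thr)
}

# disjunction over TRUE/FALSE/NA branches: TRUE wins, else NA if any
# branch is undetermined, else FALSE
or_unknown <- function(...) {
  vals <- c(...)
  if (any(vals %in% TRUE)) TRUE else if (anyNA(vals)) NA else FALSE
}

# per-drug trigger gated on one lab threshold
drug_lab <- function(ctx, i, field, op, thr) {
  if (!any(i)) return(o_not())
  v <- lb(ctx, field)
  if (is.null(v)) return(o_ne(field))
  if (op(v, thr)) o_trig(each(ctx$codes[i])) else o_not()
}

# per-drug trigger gated on the first-line qualifier (NA -> not evaluable)
first_line_gate <- function(ctx, i) {
  yes <- i & (ctx$fl %in% TRUE)
  unk <- i & is.na(ctx$fl)
  if (any(yes)) o_trig(each(ctx$codes[yes]))
  else if (any(unk)) o_ne("first_line")
  else o_not()
}

# --- evaluation and screening --------------------------------------------

#' Evaluate one STOPP criterion against one patient
#'
#' @param patient A one-row `pim_cohort` (e.g. from [patient_record()] or a
#'   slice of a cohort).
#' @param criterion_id Criterion identifier such as `"E4"`.
#' @return A tibble with columns `criterion_id`, `status` (`triggered`,
#'   `not_triggered`, `not_evaluable`), `flags` (list of triggering ATC code
#'   sets, one element per flag) and `missing_inputs` (list column).
#' @export
#' @examples
#' p <- patient_record("x", 70, "male",
#'   labs = list(egfr = 40),
#'   medications = medication("M01AB05", daily_dose = 75, duration_days = 30,
#'                            indication_code = "pain"))
#' evaluate_criterion(p, "E4")
evaluate_criterion <- function(patient, criterion_id) {
  reg <- stopp_registry()
  k <- match(criterion_id, reg$criterion_id)
  if (is.na(k)) {
    abort(paste0("unknown criterion_id: ", criterion_id),
          class = "pimscreen_criterion_error")
  }
  ctx <- build_ctx(patient, 1L)
  out <- reg$fn[[k]](ctx)
  tibble::tibble(
    criterion_id = criterion_id,
    status = out$status,
    flags = list(out$flags),
    missing_inputs = list(out$missing)
  )
}

screen_ctx <- function(ctx, reg) {
  res <- lapply(reg$fn, function(f) f(ctx))
  status <- vapply(res, function(x) x$status, character(1))
  flags <- lapply(res, function(x) x$flags)
  nfl <- lengths(flags)
  trig <- which(nfl > 0L)
  flag_tbl <- if (length(trig)) {
    tibble::tibble(
      patient_id = ctx$id,
      criterion_id = rep(reg$criterion_id[trig], nfl[trig]),
      system_group = rep(reg$system_group[trig], nfl[trig]),
      atc_codes = unlist(flags[trig], recursive = FALSE)
    )
  } else {
    tibble::tibble(
      patient_id = character(), criterion_id = character(),
      system_group = character(), atc_codes = list()
    )
  }
  list(status = status, flags = flag_tbl)
}

#' Screen a single patient against all 133 criteria
#'
#' @param patient A one-row `pim_cohort`.
#' @return Tibble of PIM flags: `patient_id`, `criterion_id`,
#'   `system_group`, `atc_codes` (list column; one row per flag instance).
#' @export
screen_patient <- function(patient) {
  screen_ctx(build_ctx(patient, 1L), stopp_registry())$flags
}

#' Screen a cohort
#'
#' Evaluates every criterion for every patient.  Per-patient results are
#' independent, so the result is invariant (up to row order) under
#' permutation of the cohort.
#'
#' @param cohort A validated `pim_cohort`.
#' @return A `pim_screen` object: list with `flags` (tibble of PIM flag
#'   instances), `outcomes` (patient x criterion status matrix in long
#'   form), `n_patients`, and the knowledge-base versions used.
#' @export
screen_cohort <- function(cohort) {
  reg <- stopp_registry()
  per <- lapply(seq_len(nrow(cohort)), function(i) {
    screen_ctx(build_ctx(cohort, i), reg)
  })
  flags <- dplyr::bind_rows(lapply(per, function(x) x$flags))
  status <- vapply(per, function(x) x$status, character(nrow(reg)))
  outcomes <- tibble::tibble(
    patient_id = rep(cohort$patient_id, each = nrow(reg)),
    criterion_id = rep(reg$criterion_id, times = nrow(cohort)),
    status = as.vector(status)
  )
  structure(
    list(
      flags = flags,
      outcomes = outcomes,
      n_patients = nrow(cohort),
      patient_ids = cohort$patient_id,
      versions = knowledge_versions()
    ),
    class = "pim_screen"
  )
}

#' @export
print.pim_screen <- function(x, ...) {
  flagged <- length(unique(x$flags$patient_id))
  cat("<pim_screen> ", nrow(x$flags), " PIM flag(s) in ", flagged, " of ",
      x$n_patients, " patients\n", sep = "")
  invisible(x)
}

#' Tally PIM flags by criterion, system, drug or patient
#'
#' Counts are conserved: the per-criterion tallies sum to the per-system
#' tallies sum to the total number of flags.  `by = "patient"` returns the
#' distribution of PIM counts per patient (including zero).
#'
#' @param screen A `pim_screen` from [screen_cohort()].
#' @param by One of `"criterion"`, `"system"`, `"drug"`, `"patient"`.
#' @return A tibble of counts.  For `by = "drug"`, one row per ATC code with
#'   the number of flag instances naming that drug (a flag naming several
#'   drugs counts once for each).
#' @export
tally_flags <- function(screen, by = c("criterion", "system", "drug", "patient")) {
  by <- tryCatch(match.arg(by), error = function(e) {
    abort(paste0("unknown tally axis: ", by[[1]]),
          class = "pimscreen_tally_error")
  })
  flags <- screen$flags
  reg <- stopp_registry()
  switch(by,
    criterion = {
      n <- table(factor(flags$criterion_id, levels = reg$criterion_id))
      tibble::tibble(
        criterion_id = reg$criterion_id,
        system_group = reg$system_group,
        n = as.integer(n)
      )
    },
    system = {
      lv <- unique(reg$system_group)
      n <- table(factor(flags$system_group, levels = lv))
      tibble::tibble(system_group = lv, n = as.integer(n))
    },
    drug = {
      codes <- unlist(flags$atc_codes)
      if (is.null(codes)) codes <- character()
      n <- sort(table(codes), decreasing = TRUE)
      cat <- atc_catalog()
      tibble::tibble(
        atc_code = names(n),
        name = cat$name[match(names(n), cat$code)],
        n = as.integer(n)
      )
    },
    patient = {
      per <- table(factor(flags$patient_id, levels = screen$patient_ids))
      dist <- table(as.integer(per))
      tibble::tibble(
        n_pims = as.integer(names(dist)),
        n_patients = as.integer(dist)
      )
    }
  )
}

#' PIM prevalence in a screened cohort
#'
#' Proportion of patients with at least one triggered flag.  The displayed
#' percentage rounds half-up to one decimal place.
#'
#' @param screen A `pim_screen`.
#' @return Tibble with `n_flagged`, `n`, `proportion`, `percent`.
#' @export
pim_prevalence <- function(screen) {
  n <- screen$n_patients
  if (n == 0L) abort("cohort size is zero", class = "pimscreen_validation_error")
  flagged <- length(unique(screen$flags$patient_id))
  prop <- flagged / n
  tibble::tibble(
    n_flagged = flagged,
    n = n,
    proportion = prop,
    percent = round_half_up(100 * prop, 1)
  )
}

# round half away from zero, the display convention used throughout
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
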