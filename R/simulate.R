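# Synthetic cohort generation.
#
# The generator reproduces the marginal structure the analysis assumes:
# the study's sex split (55.3% male), its six age bands, the three
# medication-count bands with uniform within-band counts, the leading
# comorbidity prevalences (hypertension 49.6%, diabetes 33.8%), and
# per-criterion trigger rates equal to the reference instance counts over
# 450.  Patient-level joint structure beyond these marginals is modelled as
# independence - the simplest generative model consistent with the reported
# marginals - and triggering prescriptions carry their own required
# conditions and just-past-threshold laboratory values so triggers are
# unambiguous.

NEUTRAL_MEDS <- list(
  list("N02BE01", 500, "pain"), list("R06AE07", 10, "allergy"),
  list("A11GA01", 100, "anemia"), list("A10AB01", 40, "diabetes_t2"),
  list("R03AC02", 0.4, "copd"), list("A02BC01", 20, "gastritis"),
  list("A02BA03", 40, "gastritis"), list("C10AA05", 20, "coronary_artery_disease"),
  list("J01DD04", 2000, "infection"), list("A06AB02", 10, "chronic_constipation"),
  list("A02BC02", 40, "gastritis"), list("C10AA01", 20, "coronary_artery_disease"),
  list("A10BB09", 80, "diabetes_t2"), list("J01CA04", 1500, "infection")
)

default_trigger_rates <- function() {
  REFERENCE_COUNTS / REFERENCE_N
}

default_planted_effects <- function() {
  list(
    intercept = -1.70,
    sex_male = log(1.31),
    age_band = c(`65-69` = log(1.35), `70-74` = log(1.38),
                 `75-79` = log(1.76), `80-84` = log(1.54),
                 `85+` = log(0.77)),
    med_mid = log(2.89), med_high = log(8.42),
    comorbidity = log(3.12), multimorbidity = log(2.11)
  )
}

#' Specification of a synthetic cohort
#'
#' Defaults are the study conditions: n = 450, the published sex, age-band
#' and medication-band marginals, hypertension/diabetes prevalences, the
#' reference per-criterion trigger rates, and planted covariate effects
#' equal to the published adjusted odds ratios (used by the
#' parameter-recovery simulation).
#'
#' @param n Cohort size (positive integer).
#' @param seed Integer seed; the seed fully determines the cohort.
#' @param sex_p_male Probability of male sex.
#' @param age_band_probs Probabilities of the six age bands 60-64, ...,
#'   85+; must sum to 1.
#' @param med_count_probs Probabilities of the low (1-4), mid (5-9) and
#'   high (10+) medication bands.
#' @param condition_prevalences Named probabilities of background chronic
#'   conditions attached independently per patient.
#' @param criterion_trigger_rates Named per-patient probabilities of
#'   receiving each criterion's triggering prescription bundle.
#' @param planted_effects Log-odds structure for [plant_pim_exposure()].
#' @return A validated `cohort_spec` list.
#' @export
cohort_spec <- function(n = 450L, seed = 1L,
                        sex_p_male = 0.553,
                        age_band_probs = c(114, 135, 95, 35, 33, 38) / 450,
                        med_count_probs = c(91, 309, 50) / 450,
                        condition_prevalences = c(hypertension = 0.496,
                                                  diabetes_t2 = 0.338),
                        criterion_trigger_rates = default_trigger_rates(),
                        planted_effects = default_planted_effects()) {
  if (length(n) != 1L || is.na(n) || n < 1) {
    abort("cohort size n must be a positive integer",
          class = "pimscreen_validation_error")
  }
  probs <- c(sex_p_male, age_band_probs, med_count_probs,
             condition_prevalences, criterion_trigger_rates)
  if (any(probs < 0 | probs > 1)) {
    abort("all probabilities must lie in [0, 1]",
          class = "pimscreen_validation_error")
  }
  if (abs(sum(age_band_probs) - 1) > 1e-8 || length(age_band_probs) != 6L) {
    abort("age_band_probs must be 6 probabilities summing to 1",
          class = "pimscreen_validation_error")
  }
  if (abs(sum(med_count_probs) - 1) > 1e-8 || length(med_count_probs) != 3L) {
    abort("med_count_probs must be 3 probabilities summing to 1",
          class = "pimscreen_validation_error")
  }
  unknown <- setdiff(names(criterion_trigger_rates),
                     stopp_criteria()$criterion_id)
  if (length(unknown)) {
    abort(paste0("trigger rate for unknown criterion: ",
                 paste(unknown, collapse = ", ")),
          class = "pimscreen_validation_error")
  }
  structure(
    list(n = as.integer(n), seed = as.integer(seed),
         sex_p_male = sex_p_male, age_band_probs = age_band_probs,
         med_count_probs = med_count_probs,
         condition_prevalences = condition_prevalences,
         criterion_trigger_rates = criterion_trigger_rates,
         planted_effects = planted_effects),
    class = "cohort_spec"
  )
}

AGE_BAND_RANGES <- list(60:64, 65:69, 70:74, 75:79, 80:84, 85:94)

#' Generate a synthetic cohort
#'
#' Identical (spec, seed) pairs give identical cohorts; marginal
#' frequencies converge to the specified probabilities as n grows.
#'
#' @param spec A [cohort_spec()] (or arguments forwarded to it).
#' @param ... Forwarded to [cohort_spec()] when `spec` is not supplied.
#' @return A validated `pim_cohort` with the spec and seed recorded in its
#'   metadata.
#' @export
#' @examples
#' co <- simulate_cohort(cohort_spec(n = 30, seed = 7))
#' nrow(co)
simulate_cohort <- function(spec = cohort_spec(...), ...) {
  stopifnot(inherits(spec, "cohort_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)

  n <- spec$n
  sexes <- ifelse(runif(n) < spec$sex_p_male, "male", "female")
  bands <- sample.int(6L, n, replace = TRUE, prob = spec$age_band_probs)
  ages <- vapply(bands, function(b) {
    r <- AGE_BAND_RANGES[[b]]
    r[[sample.int(length(r), 1L)]]
  }, integer(1))
  med_band <- sample.int(3L, n, replace = TRUE, prob = spec$med_count_probs)
  med_target <- vapply(med_band, function(b) {
    switch(b, sample(1:4, 1L), sample(5:9, 1L), sample(10:14, 1L))
  }, integer(1))

  rates <- spec$criterion_trigger_rates
  rates <- rates[rates > 0]
  if (is.null(the$trigger_units)) the$trigger_units <- list()
  missing_units <- setdiff(names(rates), names(the$trigger_units))
  for (cr in missing_units) the$trigger_units[[cr]] <- trigger_unit(cr)
  unit_cache <- the$trigger_units[names(rates)]
  if (is.null(the$neutral_rows)) {
    the$neutral_rows <- lapply(NEUTRAL_MEDS, function(x) {
      medication(x[[1]], daily_dose = x[[2]], duration_days = 7L,
                 indication_code = x[[3]])
    })
    the$neutral_codes <- vapply(NEUTRAL_MEDS, `[[`, character(1), 1)
  }

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    conds <- names(spec$condition_prevalences)[
      runif(length(spec$condition_prevalences)) < spec$condition_prevalences
    ]
    labs <- list()
    meds <- list()
    sex_i <- sexes[[i]]
    age_i <- ages[[i]]
    hit <- names(rates)[runif(length(rates)) < rates]
    for (cr in hit) {
      u <- unit_cache[[cr]]
      # skip a trigger whose laboratory demands conflict with ones already
      # attached (rates are approximate by design)
      conflict <- any(vapply(names(u$labs), function(nm) {
        !is.null(labs[[nm]]) && !identical(labs[[nm]], u$labs[[nm]])
      }, logical(1)))
      if (conflict) next
      if (any(u$meds$atc_code %in% unlist(lapply(meds, `[[`, "atc_code")))) next
      meds[[length(meds) + 1L]] <- u$meds
      conds <- union(conds, u$conds)
      for (nm in names(u$labs)) labs[[nm]] <- u$labs[[nm]]
      if (!is.na(u$sex)) sex_i <- u$sex
      if (!is.na(u$age)) age_i <- u$age
    }
    meds <- if (length(meds)) dplyr::bind_rows(meds) else medication(character())
    # pad with neutral orders up to the drawn medication count
    if (nrow(meds) < med_target[[i]]) {
      avail <- which(!(the$neutral_codes %in% meds$atc_code))
      take <- utils::head(sample(avail), med_target[[i]] - nrow(meds))
      meds <- dplyr::bind_rows(c(list(meds), the$neutral_rows[take]))
    }
    if (nrow(meds) == 0L) {
      meds <- medication("N02BE01", daily_dose = 500, duration_days = 5L,
                         indication_code = "pain")
    }
    rows[[i]] <- patient_record(
      sprintf("S%05d", i), age_years = age_i, sex = sex_i,
      conditions = conds, labs = labs, medications = meds
    )
  }
  as_cohort(dplyr::bind_rows(rows),
            metadata = list(source = "pimscreen synthetic cohort",
                            seed = spec$seed, n = n))
}

#' Parameter-recovery simulation for the adjusted odds ratios
#'
#' Repeatedly draws cohorts of covariates from the study marginals, plants
#' a PIM-exposure outcome with the log-odds of `effects`, refits the
#' multivariable logistic model, and reports how often each planted effect
#' is covered by its Wald confidence interval.  With a correctly
#' implemented estimator the coverage of a 95 percent interval is close to
#' 95 percent.
#'
#' @param n Patients per replicate.
#' @param replicates Number of replicates.
#' @param seed Integer seed.
#' @param effects Planted log-odds structure.
#' @return Tibble with one row per non-reference covariate level: the
#'   planted odds ratio, the empirical CI `coverage`, and the number of
#'   converged replicates.
#' @export
recovery_simulation <- function(n = 450L, replicates = 500L, seed = 1L,
                                effects = default_planted_effects()) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  rep_seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                                 2L * replicates), ncol = 2L)
  comorb_probs <- c(138, 158, 154) / 450
  truth <- tibble::tibble(
    term = c("sex", "age_band", "age_band", "age_band", "age_band",
             "age_band", "med_count_category", "med_count_category",
             "comorbidity_category", "comorbidity_category"),
    level = c("male", "65-69", "70-74", "75-79", "80-84", "85+",
              "mid", "high", "comorbidity", "multimorbidity"),
    true_or = exp(c(effects$sex_male, effects$age_band,
                    effects$med_mid, effects$med_high,
                    effects$comorbidity, effects$multimorbidity))
  )
  covered <- matrix(NA, nrow = replicates, ncol = nrow(truth))
  for (r in seq_len(replicates)) {
    set.seed(rep_seeds[r, 1L])
    feats <- tibble::tibble(
      sex = factor(sample(c("female", "male"), n, TRUE,
                          prob = c(1 - 0.553, 0.553)),
                   levels = c("female", "male")),
      age_band = factor(sample(AGE_BANDS, n, TRUE,
                               prob = c(114, 135, 95, 35, 33, 38) / 450),
                        levels = AGE_BANDS),
      med_count_category = factor(sample(c("low", "mid", "high"), n, TRUE,
                                         prob = c(91, 309, 50) / 450),
                                  levels = c("low", "mid", "high")),
      comorbidity_category = factor(
        sample(c("none", "comorbidity", "multimorbidity"), n, TRUE,
               prob = comorb_probs),
        levels = c("none", "comorbidity", "multimorbidity"))
    )
    feats <- plant_pim_exposure(feats, effects, seed = rep_seeds[r, 2L])
    fit <- tryCatch(
      fit_pim_logistic(feats, outcome = "pim",
                       terms = c("sex", "age_band", "med_count_category",
                                 "comorbidity_category")),
      pimscreen_convergence_error = function(e) NULL
    )
    if (is.null(fit)) next
    td <- tidy(fit)
    td <- td[!td$reference, ]
    key <- paste(td$term, td$level)
    idx <- match(paste(truth$term, truth$level), key)
    covered[r, ] <- td$ci_low[idx] <= truth$true_or &
      truth$true_or <= td$ci_high[idx]
  }
  truth$coverage <- colMeans(covered, na.rm = TRUE)
  truth$n_reps <- colSums(!is.na(covered))
  truth
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Plant a PIM-exposure outcome with known log-odds structure
#'
#' Draws a binary PIM-exposure indicator for each patient from the logistic
#' model implied by `effects`, given the patient's covariates.  Used by the
#' parameter-recovery simulation: the fitted adjusted odds ratios should
#' recover the planted effects as n grows.
#'
#' @param features Per-patient covariate tibble from [cohort_features()].
#' @param effects Log-odds list as in [default_planted_effects()].
#' @param seed Integer seed.
#' @return `features` with added columns `linear_predictor` and `pim`
#'   (0/1).
#' @export
plant_pim_exposure <- function(features, effects = default_planted_effects(),
                               seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  ab <- unname(effects$age_band[as.character(features$age_band)])
  ab[is.na(ab)] <- 0
  lp <- rep(effects$intercept, nrow(features)) +
    effects$sex_male * (features$sex == "male") +
    ab +
    effects$med_mid * (features$med_count_category == "mid") +
    effects$med_high * (features$med_count_category == "high") +
    effects$comorbidity * (features$comorbidity_category == "comorbidity") +
    effects$multimorbidity * (features$comorbidity_category == "multimorbidity")
  features$linear_predictor <- as.numeric(lp)
  features$pim <- rbinom(nrow(features), 1L, stats::plogis(features$linear_predictor))
  features
}
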