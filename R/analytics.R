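# Association statistics: crude odds ratios with Woolf intervals, the
# p < 0.25 bivariate screen, the multivariable logistic model of PIM
# exposure, and the single-proportion sample-size formula.

#' Crude odds ratio from a 2x2 table
#'
#' OR = (a*d)/(b*c) with the Woolf (log-normal) 95 percent confidence
#' interval exp(log OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d)) and a two-sided
#' Wald p-value on the log scale.
#'
#' @param a Exposed with outcome.
#' @param b Exposed without outcome.
#' @param c Unexposed with outcome.
#' @param d Unexposed without outcome.
#' @param conf_level Confidence level (default 0.95).
#' @param correction Add 0.5 to every cell (Haldane-Anscombe); required when
#'   any cell is zero, off by default so that zero cells fail loudly.
#' @return An `or_result` object; see [tidy.or_result()].
#' @export
#' @examples
#' crude_or(145, 104, 110, 91) # 1.15
crude_or <- function(a, b, c, d, conf_level = 0.95, correction = FALSE) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || sum(cells) == 0) {
    abort("2x2 cells must be non-negative with a positive total",
          class = "pimscreen_validation_error")
  }
  if (any(cells == 0) && !correction) {
    abort(paste0("zero cell in 2x2 table; re-run with correction = TRUE ",
                 "to apply the 0.5 continuity correction"),
          class = "pimscreen_zero_cell_error")
  }
  if (correction) cells <- cells + 0.5
  or <- (cells[["a"]] * cells[["d"]]) / (cells[["b"]] * cells[["c"]])
  se <- sqrt(sum(1 / cells))
  z <- qnorm(1 - (1 - conf_level) / 2)
  ci <- exp(log(or) + c(-1, 1) * z * se)
  p <- 2 * pnorm(-abs(log(or) / se))
  structure(
    list(odds_ratio = or, ci_low = ci[[1]], ci_high = ci[[2]],
         p_value = p, se_log = se, conf_level = conf_level,
         cells = cells, method = "crude"),
    class = "or_result"
  )
}

#' @export
print.or_result <- function(x, ...) {
  cat(sprintf("OR %.2f (%.2f-%.2f), p = %.3g [%s, Woolf %d%% CI]\n",
              x$odds_ratio, x$ci_low, x$ci_high, x$p_value, x$method,
              round(100 * x$conf_level)))
  invisible(x)
}

#' Tidy an odds-ratio result
#'
#' @param x An `or_result`.
#' @param ... Unused.
#' @return One-row tibble with `odds_ratio`, `ci_low`, `ci_high`, `p_value`,
#'   `method`.
#' @method tidy or_result
#' @export
tidy.or_result <- function(x, ...) {
  tibble::tibble(
    odds_ratio = x$odds_ratio, ci_low = x$ci_low, ci_high = x$ci_high,
    p_value = x$p_value, method = x$method
  )
}

#' Bivariate screen of candidate exposures against a binary outcome
#'
#' Pearson chi-square test of independence on each k x 2 cross-tabulation
#' (no continuity correction, mirroring common statistical-package
#' defaults); candidates with p below the cut (0.25) are selected for the
#' multivariable model.  When any expected cell count falls below 1 the
#' test falls back to Fisher's exact test.
#'
#' @param data Per-patient data frame.
#' @param outcome Name of the binary outcome column.
#' @param candidates Character vector of candidate covariate columns.
#' @param p_cut Selection threshold (default 0.25).
#' @return Tibble with one row per candidate: test used, statistic, df,
#'   `p_value` and logical `selected`.
#' @export
bivariate_screen <- function(data, outcome, candidates, p_cut = 0.25) {
  rows <- lapply(candidates, function(v) {
    tab <- table(data[[v]], data[[outcome]])
    tab <- tab[rowSums(tab) > 0, , drop = FALSE]
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expected < 1)) {
      ft <- fisher.test(tab)
      tibble::tibble(variable = v, test = "fisher_exact",
                     statistic = NA_real_, df = NA_integer_,
                     p_value = ft$p.value)
    } else {
      ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
      tibble::tibble(variable = v, test = "pearson_chisq",
                     statistic = unname(ct$statistic),
                     df = as.integer(ct$parameter),
                     p_value = ct$p.value)
    }
  })
  out <- dplyr::bind_rows(rows)
  out$selected <- out$p_value < p_cut
  out
}

#' Multivariable logistic model of PIM exposure
#'
#' Maximum-likelihood logistic regression (iteratively reweighted least
#' squares via [stats::glm()]) of a binary outcome on categorical
#' covariates, with Wald confidence intervals on the odds-ratio scale.
#' Reference levels follow the study's coding: female sex, the youngest age
#' band, the low medication band, no comorbidity - i.e. the first factor
#' level of each covariate.
#'
#' @param data Per-patient data frame; factor covariates should have their
#'   reference level first (as produced by [cohort_features()]).
#' @param outcome Name of the binary (0/1 or logical) outcome column.
#' @param terms Character vector of covariate column names.
#' @param conf_level Confidence level for the Wald intervals.
#' @return A `pim_logit` object; see [tidy.pim_logit()] and
#'   [glance.pim_logit()].
#' @export
fit_pim_logistic <- function(data, outcome = "pim", terms, conf_level = 0.95) {
  fml <- stats::as.formula(paste(outcome, "~", paste(terms, collapse = " + ")))
  fit <- glm(fml, data = data, family = binomial())
  if (!fit$converged) {
    abort("logistic model did not converge",
          class = "pimscreen_convergence_error")
  }
  se <- sqrt(diag(vcov(fit)))
  if (any(!is.finite(se)) || any(se > 100) || any(abs(coef(fit)) > 15)) {
    abort(paste0("separation suspected: a coefficient or its standard error ",
                 "is diverging; reconsider the model terms"),
          class = "pimscreen_convergence_error")
  }
  structure(
    list(fit = fit, terms = terms, outcome = outcome,
         conf_level = conf_level, n_obs = stats::nobs(fit)),
    class = "pim_logit"
  )
}

#' Tidy a fitted PIM logistic model into an adjusted odds-ratio table
#'
#' One row per covariate level, including the reference levels, whose odds
#' ratio is exactly 1 with no interval (the study's table convention).
#'
#' @param x A `pim_logit`.
#' @param ... Unused.
#' @return Tibble with `term`, `level`, `reference`, `odds_ratio`, `ci_low`,
#'   `ci_high`, `p_value`, `significant` (p below 0.05).
#' @method tidy pim_logit
#' @export
tidy.pim_logit <- function(x, ...) {
  fit <- x$fit
  cf <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  z <- qnorm(1 - (1 - x$conf_level) / 2)
  rows <- list()
  for (term in x$terms) {
    v <- fit$model[[term]]
    lv <- if (is.factor(v)) levels(v) else sort(unique(v))
    for (k in seq_along(lv)) {
      nm <- paste0(term, lv[[k]])
      if (k == 1L) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          term = term, level = as.character(lv[[k]]), reference = TRUE,
          odds_ratio = 1, ci_low = NA_real_, ci_high = NA_real_,
          p_value = NA_real_, significant = NA
        )
      } else if (nm %in% names(cf)) {
        est <- cf[[nm]]; s <- se[[nm]]
        p <- 2 * pnorm(-abs(est / s))
        rows[[length(rows) + 1L]] <- tibble::tibble(
          term = term, level = as.character(lv[[k]]), reference = FALSE,
          odds_ratio = exp(est), ci_low = exp(est - z * s),
          ci_high = exp(est + z * s), p_value = p, significant = p < 0.05
        )
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' One-row summary of a fitted PIM logistic model
#'
#' @param x A `pim_logit`.
#' @param ... Unused.
#' @return Tibble with `n_obs`, `converged`, `iterations`, `deviance`,
#'   `null_deviance`, `aic`.
#' @method glance pim_logit
#' @export
glance.pim_logit <- function(x, ...) {
  fit <- x$fit
  tibble::tibble(
    n_obs = x$n_obs,
    converged = fit$converged,
    iterations = fit$iter,
    deviance = fit$deviance,
    null_deviance = fit$null.deviance,
    aic = fit$aic
  )
}

#' @export
print.pim_logit <- function(x, ...) {
  cat("<pim_logit> n =", x$n_obs, "| terms:",
      paste(x$terms, collapse = ", "), "\n")
  print(tidy(x))
  invisible(x)
}

#' Single-proportion sample size with attrition inflation
#'
#' n0 = z^2 p (1 - p) / d^2, inflated by the anticipated attrition fraction
#' (n = n0 * (1 + attrition)) and rounded up to the next whole participant.
#' With p = 0.64, d = 0.05, z = 1.96 and 20 percent attrition this yields
#' 425.
#'
#' @param p Expected prevalence (0 < p < 1).
#' @param d Absolute precision (> 0).
#' @param z Normal quantile for the confidence level (default 1.96).
#' @param attrition Anticipated loss fraction in [0, 1).
#' @return Integer sample size (at least 1).
#' @export
#' @examples
#' sample_size(0.64, 0.05, 1.96, attrition = 0.20)
sample_size <- function(p, d = 0.05, z = 1.96, attrition = 0) {
  if (!(p > 0 && p < 1)) abort("p must lie strictly between 0 and 1",
                               class = "pimscreen_validation_error")
  if (d <= 0) abort("d must be positive", class = "pimscreen_validation_error")
  if (attrition < 0 || attrition >= 1) {
    abort("attrition must lie in [0, 1)", class = "pimscreen_validation_error")
  }
  n0 <- z^2 * p * (1 - p) / d^2
  max(1L, as.integer(ceiling(n0 * (1 + attrition))))
}

# display convention for medians: "median (Q3-Q1)"
median_iqr_label <- function(x) {
  q <- quantile(x, c(0.25, 0.5, 0.75), type = 2)
  sprintf("%g (%g-%g)", q[[2]], q[[3]], q[[1]])
}

#' Descriptive summary of a screened cohort
#'
#' Demographics (median age with quartiles displayed as "median (Q3-Q1)"),
#' category counts with percentages, comorbidity severity bands, and - when
#' a screen result is supplied - the top inappropriately prescribed drugs
#' with their share of all flags.
#'
#' @param cohort A validated `pim_cohort`.
#' @param screen Optional `pim_screen` for the same cohort.
#' @param top_k Number of drugs in the attribution table (default 20).
#' @return A `cohort_summary` list of tibbles: `overview`, `age_bands`,
#'   `sex`, `medication_bands`, `cci_bands`, `comorbidity`, and (with a
#'   screen) `top_drugs` and `system_tally`.
#' @export
summarize_cohort <- function(cohort, screen = NULL, top_k = 20L) {
  feats <- cohort_features(cohort)
  n <- nrow(feats)
  count_tbl <- function(f) {
    tb <- table(f)
    pct <- round_half_up(100 * as.integer(tb) / n, 1)
    tibble::tibble(level = names(tb), n = as.integer(tb), percent = pct)
  }
  out <- list(
    overview = tibble::tibble(
      n_patients = n,
      age_median_iqr = median_iqr_label(feats$age_years),
      total_medications = sum(feats$n_medications),
      meds_median_iqr = median_iqr_label(feats$n_medications)
    ),
    age_bands = count_tbl(feats$age_band),
    sex = count_tbl(feats$sex),
    medication_bands = count_tbl(feats$med_count_category),
    cci_bands = count_tbl(feats$cci_band),
    comorbidity = count_tbl(feats$comorbidity_category)
  )
  if (!is.null(screen)) {
    drugs <- tally_flags(screen, by = "drug")
    total <- nrow(screen$flags)
    drugs$percent_of_flags <- round_half_up(100 * drugs$n / total, 0)
    drugs$atc_level2 <- substr(drugs$atc_code, 1, 3)
    out$top_drugs <- head(drugs, top_k)
    out$system_tally <- tally_flags(screen, by = "system")
    out$prevalence <- pim_prevalence(screen)
  }
  structure(out, class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Cohort summary\n==============\n")
  print(x$overview)
  for (nm in setdiff(names(x), "overview")) {
    cat("\n--", nm, "--\n")
    print(x[[nm]], n = 25)
  }
  invisible(x)
}
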