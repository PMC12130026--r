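# Charlson Comorbidity Index (original weights) and the comorbidity
# trichotomy used by the association analysis.

CCI_BANDS <- c(none = 0L, mild = 1L, moderate = 3L, severe = 5L)

# Charlson item hierarchy: when both members are present only the heavier
# one scores (diabetes vs diabetes with end-organ damage, mild vs severe
# liver disease, malignancy vs metastatic disease).
CCI_HIERARCHY <- list(
  c(drop = "dm", keep = "dm_end_organ"),
  c(drop = "liver_mild", keep = "liver_severe"),
  c(drop = "malignancy", keep = "mets")
)

#' Charlson Comorbidity Index score
#'
#' Sums the original Charlson weights over the distinct index items present
#' in a patient's coded conditions.  Conditions outside the Charlson item
#' set contribute zero.  The score is not age-adjusted: the severity bands
#' used downstream (mild 1-2, moderate 3-4, severe >= 5) read as the raw
#' index.
#'
#' @param conditions Character vector of condition codes.
#' @return A list with `score` (integer), `band` (`none`/`mild`/`moderate`/
#'   `severe`) and `contributing_conditions`.
#' @export
#' @examples
#' cci_score(c("myocardial_infarction", "diabetes_t2"))
cci_score <- function(conditions) {
  wt <- cci_weight_table()
  hit <- wt[wt$condition_code %in% conditions, ]
  # one weight per distinct item, then apply the severity hierarchy
  items <- hit[!duplicated(hit$item), c("item", "weight")]
  for (h in CCI_HIERARCHY) {
    if (all(c(h[["drop"]], h[["keep"]]) %in% items$item)) {
      items <- items[items$item != h[["drop"]], ]
    }
  }
  score <- as.integer(sum(items$weight))
  list(
    score = score,
    band = cci_band(score),
    contributing_conditions = intersect(conditions, hit$condition_code)
  )
}

#' Map a Charlson score to the study's severity band
#'
#' @param score Non-negative integer score(s).
#' @return Character vector: `none` (0), `mild` (1-2), `moderate` (3-4),
#'   `severe` (5 or more).
#' @export
cci_band <- function(score) {
  stopifnot(all(score >= 0))
  c("none", "mild", "moderate", "severe")[
    findInterval(score, c(0, 1, 3, 5))
  ]
}

#' Comorbidity trichotomy: none / comorbidity / multimorbidity
#'
#' Counts distinct chronic conditions (the packaged vocabulary marks which
#' codes qualify: diabetes, malignancies, hypertension, and the cardio- and
#' cerebrovascular disease group).  Zero qualifying conditions map to
#' `none`, exactly one to `comorbidity`, two or more to `multimorbidity`.
#'
#' @param conditions Character vector of condition codes.
#' @return One of `"none"`, `"comorbidity"`, `"multimorbidity"`.
#' @export
#' @examples
#' comorbidity_category(c("hypertension", "diabetes_t2"))
comorbidity_category <- function(conditions) {
  vocab <- condition_vocabulary()
  k <- length(intersect(conditions, vocab$code[vocab$chronic == 1L]))
  if (k == 0L) "none" else if (k == 1L) "comorbidity" else "multimorbidity"
}
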