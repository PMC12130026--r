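# Packaged drug and condition knowledge bases.
#
# The ATC catalog is a curated subset of the WHO ATC index covering every
# pharmacological class referenced by a STOPP v3 predicate.  Class membership
# is expressed as tags; one level-5 code may carry several tags.  Where a
# criterion enumerates its own members (e.g. the P-glycoprotein inhibitor
# list) the enumeration is authoritative; otherwise membership follows the
# ATC level-3/4 subtree the class corresponds to.

ATC_CODE_REGEX <- "^[A-Z][0-9]{2}[A-Z]{2}[0-9]{2}$"

#' Load the packaged ATC drug-class catalog
#'
#' @return A tibble with columns `code` (ATC level-5), `name` and `tags`
#'   (list-column of drug-class tags).
#' @export
#' @examples
#' atc_catalog()
atc_catalog <- function() {
  if (is.null(the$catalog)) {
    path <- system.file("extdata", "atc_catalog.tsv", package = "pimscreen")
    raw <- readr::read_tsv(
      path,
      col_types = readr::cols(.default = readr::col_character()),
      progress = FALSE
    )
    tags <- ifelse(is.na(raw$tags), "", raw$tags)
    raw$tags <- lapply(tags, function(x) {
      if (nzchar(x)) strsplit(x, ";", fixed = TRUE)[[1]] else character()
    })
    the$catalog <- tibble::as_tibble(raw)
    the$catalog_index <- setNames(the$catalog$tags, the$catalog$code)
  }
  the$catalog
}

#' Classify an ATC level-5 code into drug-class tags
#'
#' Pure lookup against the packaged catalog: deterministic, idempotent, no
#' I/O after the catalog is first loaded.  A syntactically valid code that is
#' absent from the catalog returns an empty tag set with a warning, so that
#' screening can proceed (the drug simply matches no class clause).
#'
#' @param atc_code Character vector of 7-character ATC level-5 codes.
#' @return A list of character vectors (one tag set per input code); for a
#'   single code, the bare character vector.
#' @export
#' @examples
#' classify("B01AC06") # aspirin: antiplatelet
#' classify("D04AA16") # pheniramine: first-generation antihistamine
classify <- function(atc_code) {
  bad <- !grepl(ATC_CODE_REGEX, atc_code)
  if (any(bad)) {
    abort(
      paste0("malformed ATC level-5 code: ", paste(atc_code[bad], collapse = ", ")),
      class = "pimscreen_atc_error"
    )
  }
  atc_catalog()
  out <- the$catalog_index[atc_code]
  unknown <- vapply(out, is.null, logical(1))
  if (any(unknown)) {
    warn(paste0(
      "ATC code(s) not in packaged catalog (returning empty tag set): ",
      paste(atc_code[unknown], collapse = ", ")
    ))
    out[unknown] <- list(character())
  }
  names(out) <- atc_code
  if (length(out) == 1L) out[[1L]] else out
}

# tag lookup that never warns; internal fast path used by the rule engine
tags_of <- function(atc_codes) {
  atc_catalog()
  out <- the$catalog_index[atc_codes]
  out[vapply(out, is.null, logical(1))] <- list(character())
  out
}

#' Count the anticholinergic burden of a medication list
#'
#' Number of distinct regular (non-PRN) medications carrying the
#' antimuscarinic/anticholinergic burden tag.  Two or more such drugs trigger
#' the drug-burden criterion (M1).
#'
#' @param medications A medication-order tibble as built by [medication()].
#' @return Integer count.
#' @export
#' @examples
#' anticholinergic_burden(medication("D04AA16", daily_dose = 25))
anticholinergic_burden <- function(medications) {
  if (is.null(medications) || nrow(medications) == 0L) return(0L)
  tg <- tags_of(medications$atc_code)
  hit <- vapply(tg, function(x) "anticholinergic" %in% x, logical(1))
  length(unique(medications$atc_code[hit & !medications$prn]))
}

#' The packaged condition vocabulary
#'
#' Closed, versioned vocabulary of coded clinical states and prescribing
#' contexts referenced by the rule predicates.  `chronic` marks the
#' conditions counted by the none/comorbidity/multimorbidity trichotomy.
#'
#' @return A tibble with columns `code`, `label` and `chronic`.
#' @export
condition_vocabulary <- function() {
  if (is.null(the$vocab)) {
    path <- system.file("extdata", "condition_vocabulary.tsv", package = "pimscreen")
    the$vocab <- readr::read_tsv(
      path,
      col_types = readr::cols(
        code = readr::col_character(),
        label = readr::col_character(),
        chronic = readr::col_integer()
      ),
      progress = FALSE
    )
  }
  the$vocab
}

# internal: Charlson item weights keyed by condition code
cci_weight_table <- function() {
  if (is.null(the$cci)) {
    path <- system.file("extdata", "cci_weights.tsv", package = "pimscreen")
    the$cci <- readr::read_tsv(
      path,
      col_types = readr::cols(
        condition_code = readr::col_character(),
        item = readr::col_character(),
        weight = readr::col_integer()
      ),
      progress = FALSE
    )
  }
  the$cci
}
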