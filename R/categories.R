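#' @keywords internal
"_PACKAGE"

# Ordinal Banff lesion-score fields carried on every biopsy record.
# t/i/v/g/ptc are acute lesions, cg/cv/ci/ct/ptcbm chronic lesions,
# t_ifta/i_ifta are tubulitis and inflammation scored inside fibrotic cortex.
BANFF_SCORE_FIELDS <- c(
  "t", "t_ifta", "i", "i_ifta", "v", "g", "ptc",
  "c4d", "cg", "cv", "ci", "ct", "ptcbm"
)

ABO_LEVELS <- c("compatible", "incompatible")
DSA_LEVELS <- c("+", "-", "unknown")
BX_TYPE_LEVELS <- c("protocol", "for-cause", "follow-up")

REJECTION_CATEGORIES <- c("A-AMR", "CA-AMR", "equivocal-AMR", "A-TCMR", "CA-TCMR")

A_TCMR_GRADES <- c("IA", "IB", "IIA", "IIB", "III")
IFTA_GRADES <- c("I", "II", "III")

#' Diagnosis category vocabulary
#'
#' The closed set of base categories the rule engine can assign to a biopsy:
#' active and chronic active antibody-mediated rejection (`"A-AMR"`,
#' `"CA-AMR"`), `"equivocal-AMR"`, acute and chronic active T-cell-mediated
#' rejection (`"A-TCMR"`, `"CA-TCMR"`), chronic AMR without activity
#' (`"C-AMR-inactive"`), borderline changes (`"BC"`), interstitial fibrosis
#' and tubular atrophy (`"IFTA"`), C4d staining without evidence of rejection
#' (`"C4d-no-rejection"`), and `"no-rejection"`.
#'
#' @return Character vector of the ten base categories.
#' @export
#' @examples
#' diagnosis_categories()
diagnosis_categories <- function() {
  c(REJECTION_CATEGORIES, "C-AMR-inactive", "BC", "IFTA",
    "C4d-no-rejection", "no-rejection")
}

#' Primary-category priority order
#'
#' When several categories apply to one biopsy, the primary diagnosis is the
#' highest-priority applicable category. Active AMR outranks everything
#' (equivocal AMR shares its slot), followed by chronic active AMR, acute
#' then chronic active TCMR, inactive chronic AMR, borderline changes, IFTA,
#' C4d staining without rejection, and finally no rejection.
#'
#' @return Character vector of categories, highest priority first.
#' @export
category_priority <- function() {
  c("A-AMR", "equivocal-AMR", "CA-AMR", "A-TCMR", "CA-TCMR",
    "C-AMR-inactive", "BC", "IFTA", "C4d-no-rejection", "no-rejection")
}

#' Rejection level of a diagnosis category
#'
#' Collapses the category vocabulary to the two-level split used for
#' stratified concordance: the five AMR/TCMR categories count as rejection;
#' borderline changes, IFTA, C4d without rejection, inactive chronic AMR and
#' no rejection count as non-rejection.
#'
#' @param category Character vector of base categories
#'   (see [diagnosis_categories()]).
#' @return Character vector, `"rejection"` or `"non-rejection"`.
#' @export
#' @examples
#' rejection_level(c("A-TCMR", "BC", "no-rejection"))
rejection_level <- function(category) {
  bad <- setdiff(unique(category[!is.na(category)]), diagnosis_categories())
  if (length(bad) > 0) {
    stop("unknown diagnosis category: ", paste(bad, collapse = ", "))
  }
  ifelse(category %in% REJECTION_CATEGORIES, "rejection", "non-rejection")
}

#' Category family (AMR / TCMR / none)
#'
#' @param category Character vector of categories or canonical pathologist
#'   labels (`"other"` is allowed and maps to `"none"`).
#' @return Character vector in `{"AMR", "TCMR", "none"}`.
#' @export
category_family <- function(category) {
  ifelse(category %in% c("A-AMR", "CA-AMR", "equivocal-AMR", "C-AMR-inactive"),
    "AMR",
    ifelse(category %in% c("A-TCMR", "CA-TCMR"), "TCMR", "none")
  )
}

#' Canonicalize a pathologist diagnosis label
#'
#' Pathology reports use variable spellings ("A-TCMR 1A", "IF/TA", "No
#' rejection") and free-text non-rejection entities (recurrent
#' glomerulonephritis, BK virus nephropathy, thrombotic microangiopathy,
#' toxic tubulopathy, ...). This maps each label to the engine vocabulary
#' where possible and to the `"other"` bucket otherwise; non-rejection
#' disease entities are never engine outputs, so they all land in `"other"`.
#'
#' @param x Character vector of raw labels; `NA` passes through.
#' @return Character vector of canonical categories or `"other"`.
#' @export
#' @examples
#' parse_diagnosis_label(c("A-TCMR 1A", "IF/TA", "BKV nephropathy"))
parse_diagnosis_label <- function(x) {
  up <- toupper(trimws(as.character(x)))
  up <- gsub("[[:space:]]+", " ", up)
  out <- rep(NA_character_, length(x))
  hit <- function(pattern) !is.na(up) & grepl(pattern, up)
  out[!is.na(up)] <- "other"
  out[hit("^C4D")] <- "C4d-no-rejection"
  out[hit("^(NO[ -]?REJECTION|NO EVIDENCE)")] <- "no-rejection"
  out[hit("^(IFTA|IF/TA)")] <- "IFTA"
  out[hit("^(BC|BORDERLINE)")] <- "BC"
  out[hit("^CA-?TCMR|^CHRONIC ACTIVE T")] <- "CA-TCMR"
  out[hit("^A-?TCMR|^ACUTE T|^TCMR")] <- "A-TCMR"
  out[hit("^CA-?AMR|^CHRONIC ACTIVE A")] <- "CA-AMR"
  out[hit("^EQUIVOCAL")] <- "equivocal-AMR"
  out[hit("^A-?AMR|^ACTIVE A|^AMR")] <- "A-AMR"
  out
}
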