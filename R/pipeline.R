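# Integration of the AMR and TCMR axes with IFTA and the C4d-without-
# rejection category, and selection of the primary diagnosis by priority.

#' IFTA grade
#'
#' Interstitial fibrosis and tubular atrophy graded by the worse of ci and
#' ct (missing counts 0): grade I/II/III for 1/2/3, none at 0.
#'
#' @param ci,ct Interstitial fibrosis and tubular atrophy scores.
#' @return Character vector `"I"`, `"II"`, `"III"` or `NA`.
#' @export
#' @examples
#' ifta_grade(ci = 1, ct = 2)
ifta_grade <- function(ci, ct) {
  m <- pmax(score0(ci), score0(ct))
  c(NA_character_, "I", "II", "III")[m + 1L]
}

#' C4d staining without evidence of rejection
#'
#' Linear C4d staining in >= 50% of cortical peritubular capillaries
#' (score >= 2) with no histologic evidence of tissue injury: applies only
#' in ABO-compatible grafts when neither a rejection category nor IFTA is
#' applicable. In ABO-incompatible grafts the category is suppressed and
#' such biopsies report no rejection.
#'
#' @param c4d C4d score (0--3 or `NA`).
#' @param abo `"compatible"` or `"incompatible"`.
#' @param applicable List of character vectors: the already-computed
#'   applicable categories per biopsy (or a single character vector for one
#'   biopsy).
#' @return Logical vector.
#' @export
c4d_without_rejection <- function(c4d, abo, applicable) {
  if (!is.list(applicable)) applicable <- list(applicable)
  blocked <- vapply(applicable, function(a) {
    a <- a[!is.na(a)]
    any(rejection_level(a) == "rejection") || "IFTA" %in% a
  }, logical(1))
  score0(c4d) >= 2 & abo == "compatible" & !blocked
}

# Vectorized assessment of a cohort: every intermediate the rule set uses,
# one row per biopsy. Internal; the exported surface wraps it.
engine_assess <- function(cohort) {
  n <- nrow(cohort)
  sc <- cohort[, BANFF_SCORE_FIELDS, drop = FALSE]
  abo <- as.character(cohort$abo)
  dsa <- as.character(cohort$hla_dsa)

  mvi <- mvi_score(sc$g, sc$ptc)
  c4d_ev <- c4d_evidence(sc$c4d, abo)
  tcmr <- classify_tcmr(sc)
  flags <- concurrent_tcmr_flags(sc)
  crit1 <- amr_criterion1(sc, abo, dsa, flags)
  crit2 <- amr_criterion2(sc, abo)
  amr <- classify_amr(sc, abo, dsa)
  ifta <- ifta_grade(sc$ci, sc$ct)

  applicable <- vector("list", n)
  for (k in seq_len(n)) {
    a <- character()
    if (!is.na(amr[k])) a <- c(a, amr[k])
    if (!is.na(tcmr$acute_grade[k])) a <- c(a, "A-TCMR")
    if (tcmr$chronic_active[k]) a <- c(a, "CA-TCMR")
    if (is.na(tcmr$acute_grade[k]) && !tcmr$chronic_active[k] &&
        tcmr$borderline[k]) a <- c(a, "BC")
    if (!is.na(ifta[k])) a <- c(a, "IFTA")
    applicable[[k]] <- a
  }
  c4d_nr <- c4d_without_rejection(sc$c4d, abo, applicable)
  for (k in which(c4d_nr)) {
    applicable[[k]] <- c(applicable[[k]], "C4d-no-rejection")
  }
  primary <- vapply(applicable, select_primary, character(1))

  trace <- character(n)
  for (k in seq_len(n)) {
    tr <- paste0("mvi=", mvi[k])
    if (c4d_ev[k]) tr <- c(tr, "c4d_evidence")
    if (abo[k] == "incompatible" && score0(sc$c4d[k]) >= 2) {
      tr <- c(tr, "c4d_discounted_abo_incompatible")
    }
    if (flags$full_tcmr[k]) tr <- c(tr, "concurrent_full_tcmr")
    if (crit1[k]) tr <- c(tr, "amr_criterion1")
    if (crit2[k]) tr <- c(tr, "amr_criterion2")
    if (!is.na(amr[k])) {
      if (amr[k] == "CA-AMR") tr <- c(tr, "amr_chronicity")
      tr <- c(tr, paste0("amr=", amr[k]))
    }
    if (!is.na(tcmr$acute_grade[k])) {
      tr <- c(tr, paste0("tcmr_acute=", tcmr$acute_grade[k]))
    }
    if (tcmr$chronic_active[k]) tr <- c(tr, "tcmr_chronic_active")
    if ("BC" %in% applicable[[k]]) tr <- c(tr, "borderline")
    if (!is.na(ifta[k])) tr <- c(tr, paste0("ifta=", ifta[k]))
    if (c4d_nr[k]) tr <- c(tr, "c4d_without_rejection")
    trace[k] <- paste(c(tr, paste0("primary=", primary[k])), collapse = ";")
  }

  list(mvi = mvi, c4d_evidence = c4d_ev, criterion1 = crit1,
       criterion2 = crit2, amr = amr, tcmr = tcmr, ifta = ifta,
       applicable = applicable, primary = primary, trace = trace)
}

#' Applicable diagnosis categories
#'
#' The union of the non-null AMR classification, the TCMR classification
#' (both acute and chronic active when both hold; borderline only when
#' neither does), graded IFTA, and C4d staining without rejection. The set
#' may be empty (a biopsy with no findings).
#'
#' @param cohort Data frame in the cohort schema.
#' @return List of character vectors, one per row.
#' @export
applicable_categories <- function(cohort) {
  engine_assess(cohort)$applicable
}

#' Select the primary category from an applicable set
#'
#' Returns the highest-priority member per [category_priority()];
#' `"no-rejection"` for an empty set.
#'
#' @param applicable Character vector of applicable categories.
#' @return Single category string.
#' @export
#' @examples
#' select_primary(c("IFTA", "CA-TCMR", "A-AMR"))
select_primary <- function(applicable) {
  applicable <- applicable[!is.na(applicable)]
  if (length(applicable) == 0) return("no-rejection")
  prio <- category_priority()
  idx <- match(applicable, prio)
  if (anyNA(idx)) {
    stop("category outside the vocabulary: ",
         paste(applicable[is.na(idx)], collapse = ", "))
  }
  prio[min(idx)]
}

#' Classify a cohort of biopsies
#'
#' Runs the full rule engine on every record and appends the results:
#' `engine_dx` (primary category), `engine_tcmr_grade`, `engine_ifta_grade`,
#' `mvi`, `engine_applicable` (`;`-joined applicable set) and
#' `engine_trace` (`;`-joined fired-rule identifiers). Classification is a
#' pure, deterministic function of the lesion scores, ABO compatibility and
#' DSA status; biopsy type, day after transplant and the TMA flag are
#' carried through untouched and never consulted.
#'
#' @param cohort Data frame in the cohort schema (see [banff_record()],
#'   [read_cohort_csv()]).
#' @param validate Logical; check the cohort first and raise an error
#'   listing the findings when it is invalid (default `TRUE`).
#' @return The input data frame with the engine columns appended.
#' @export
#' @examples
#' classify_cohort(banff_record(g = 1, ptc = 1, c4d = 0))$engine_dx
classify_cohort <- function(cohort, validate = TRUE) {
  if (validate) {
    findings <- validate_cohort(cohort)
    if (nrow(findings) > 0) {
      stop("invalid cohort (", nrow(findings), " finding(s)); first: record ",
           findings$record_id[1], ", field ", findings$field[1], ": ",
           findings$rule[1])
    }
  }
  a <- engine_assess(cohort)
  cohort$mvi <- a$mvi
  cohort$engine_applicable <- vapply(a$applicable, paste, character(1),
                                     collapse = ";")
  cohort$engine_dx <- a$primary
  cohort$engine_tcmr_grade <- a$tcmr$acute_grade
  cohort$engine_ifta_grade <- a$ifta
  cohort$engine_trace <- a$trace
  cohort
}

#' Classify a single biopsy
#'
#' Validates the record (raising an error with the findings attached when
#' it is invalid) and returns a diagnosis object with the applicable
#' category set, the selected primary category, grades, and the ordered
#' trace of fired rules.
#'
#' @param record A one-row cohort data frame (see [banff_record()]).
#' @return An object of class `"banff_dx"`: a list with elements
#'   `record_id`, `applicable`, `primary`, `tcmr_grade`, `ifta_grade`,
#'   `mvi`, `trace`.
#' @export
#' @examples
#' classify_biopsy(banff_record(g = 1, ptc = 1, c4d = 2))
classify_biopsy <- function(record) {
  stopifnot(is.data.frame(record), nrow(record) == 1)
  findings <- validate_record(record)
  if (nrow(findings) > 0) {
    cond <- simpleError(paste0(
      "record ", record$record_id, " failed validation: ",
      paste(paste0(findings$field, " (", findings$rule, ")"), collapse = "; ")
    ))
    cond$findings <- findings
    stop(cond)
  }
  a <- engine_assess(record)
  structure(
    list(record_id = record$record_id,
         applicable = a$applicable[[1]],
         primary = a$primary[1],
         tcmr_grade = a$tcmr$acute_grade[1],
         ifta_grade = a$ifta[1],
         mvi = a$mvi[1],
         trace = strsplit(a$trace[1], ";", fixed = TRUE)[[1]]),
    class = "banff_dx"
  )
}

#' @export
print.banff_dx <- function(x, ...) {
  cat("Banff automated diagnosis for record", x$record_id, "\n")
  cat("  primary:   ", x$primary,
      if (!is.na(x$tcmr_grade) && x$primary == "A-TCMR") {
        paste0("(grade ", x$tcmr_grade, ")")
      } else if (!is.na(x$ifta_grade) && x$primary == "IFTA") {
        paste0("(grade ", x$ifta_grade, ")")
      } else "", "\n")
  cat("  applicable:", if (length(x$applicable)) {
    paste(x$applicable, collapse = ", ")
  } else "(none)", "\n")
  cat("  trace:     ", paste(x$trace, collapse = " -> "), "\n")
  invisible(x)
}
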