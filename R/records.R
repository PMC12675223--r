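# Cohort CSV schema: header exact and ordered; score cells 0-3, empty, or a
# dash (both map to missing); abo in {compatible, incompatible}; hla_dsa in
# {+, -, unknown}.
COHORT_COLUMNS <- c(
  "record_id", "patient_id", "bx_year", "bx_type", "day_after_tx",
  "abo", "hla_dsa", BANFF_SCORE_FIELDS, "tma",
  "pathologist_dx", "expected_engine_dx", "known_deviation"
)

#' Build a single biopsy record
#'
#' Convenience constructor for a one-row cohort data frame in the schema
#' used throughout the package. All lesion scores default to 0; pass `NA`
#' for a score that was not evaluated (e.g. t-IFTA in a biopsy without
#' fibrotic cortex). Missing is distinct from 0: an unscored lesion never
#' contributes to any rule.
#'
#' @param record_id,patient_id Identifiers.
#' @param bx_year Biopsy year (metadata).
#' @param bx_type One of `"protocol"`, `"for-cause"`, `"follow-up"`
#'   (metadata only; never consulted by the rule engine).
#' @param day_after_tx Non-negative days after transplant (metadata only).
#' @param abo `"compatible"` or `"incompatible"`.
#' @param hla_dsa Donor-specific antibody status: `"+"`, `"-"` or
#'   `"unknown"`.
#' @param t,t_ifta,i,i_ifta,v,g,ptc,c4d,cg,cv,ci,ct,ptcbm Ordinal Banff
#'   lesion scores in 0--3 or `NA`.
#' @param tma Logical; thrombotic microangiopathy reported. Carried into
#'   reports but fires no classification rule.
#' @param pathologist_dx Optional pathologist diagnosis (free text allowed).
#' @param expected_engine_dx Optional expected engine category (fixtures).
#' @param known_deviation Logical; marks fixture rows where the engine is
#'   known to deviate from the recorded expected output.
#' @return A one-row data frame with the cohort schema columns.
#' @export
#' @examples
#' banff_record(g = 1, ptc = 1, c4d = 2, abo = "incompatible")
banff_record <- function(record_id = "r1", patient_id = record_id,
                         bx_year = NA_integer_, bx_type = "protocol",
                         day_after_tx = 0L, abo = "compatible", hla_dsa = "-",
                         t = 0L, t_ifta = 0L, i = 0L, i_ifta = 0L, v = 0L,
                         g = 0L, ptc = 0L, c4d = 0L, cg = 0L, cv = 0L,
                         ci = 0L, ct = 0L, ptcbm = 0L, tma = FALSE,
                         pathologist_dx = NA_character_,
                         expected_engine_dx = NA_character_,
                         known_deviation = FALSE) {
  df <- data.frame(
    record_id = as.character(record_id),
    patient_id = as.character(patient_id),
    bx_year = as.integer(bx_year),
    bx_type = as.character(bx_type),
    day_after_tx = as.integer(day_after_tx),
    abo = as.character(abo),
    hla_dsa = as.character(hla_dsa),
    t = as.integer(t), t_ifta = as.integer(t_ifta),
    i = as.integer(i), i_ifta = as.integer(i_ifta),
    v = as.integer(v), g = as.integer(g), ptc = as.integer(ptc),
    c4d = as.integer(c4d), cg = as.integer(cg), cv = as.integer(cv),
    ci = as.integer(ci), ct = as.integer(ct), ptcbm = as.integer(ptcbm),
    tma = as.logical(tma),
    pathologist_dx = as.character(pathologist_dx),
    expected_engine_dx = as.character(expected_engine_dx),
    known_deviation = as.logical(known_deviation),
    stringsAsFactors = FALSE
  )
  df[, COHORT_COLUMNS]
}

#' Validate a cohort of biopsy records
#'
#' Checks every record against the type invariants: lesion scores are
#' integers in 0--3 or missing, `abo`/`hla_dsa` take legal values, biopsy
#' metadata is well-formed, record ids are unique, and `known_deviation`
#' is only set alongside an `expected_engine_dx`. Findings are returned,
#' never thrown; an empty result means the cohort is valid. The input is
#' not modified.
#'
#' @param cohort Data frame in the cohort schema (see [banff_record()]).
#' @return Data frame of findings with columns `record_id`, `field`,
#'   `value`, `rule`; zero rows when the cohort is valid.
#' @export
#' @examples
#' validate_cohort(banff_record(t = 5))
validate_cohort <- function(cohort) {
  stopifnot(is.data.frame(cohort))
  findings <- list()
  add <- function(record_id, field, value, rule) {
    findings[[length(findings) + 1L]] <<- data.frame(
      record_id = as.character(record_id), field = field,
      value = as.character(value), rule = rule, stringsAsFactors = FALSE
    )
  }
  missing_cols <- setdiff(c("record_id", "abo", "hla_dsa", BANFF_SCORE_FIELDS),
                          names(cohort))
  if (length(missing_cols) > 0) {
    add("<cohort>", paste(missing_cols, collapse = ","), "<absent>",
        "required column missing")
    return(do.call(rbind, findings))
  }
  ids <- as.character(cohort$record_id)
  for (dup in unique(ids[duplicated(ids)])) {
    add(dup, "record_id", dup, "record_id must be unique within a cohort")
  }
  for (f in BANFF_SCORE_FIELDS) {
    x <- cohort[[f]]
    bad <- !is.na(x) & (x %% 1 != 0 | x < 0 | x > 3)
    for (k in which(bad)) {
      add(ids[k], f, x[k], "lesion score must be an integer in 0-3 or missing")
    }
  }
  bad <- is.na(cohort$abo) | !(cohort$abo %in% ABO_LEVELS)
  for (k in which(bad)) {
    add(ids[k], "abo", cohort$abo[k], "abo must be 'compatible' or 'incompatible'")
  }
  bad <- is.na(cohort$hla_dsa) | !(cohort$hla_dsa %in% DSA_LEVELS)
  for (k in which(bad)) {
    add(ids[k], "hla_dsa", cohort$hla_dsa[k], "hla_dsa must be '+', '-' or 'unknown'")
  }
  if ("bx_type" %in% names(cohort)) {
    bad <- !is.na(cohort$bx_type) & !(cohort$bx_type %in% BX_TYPE_LEVELS)
    for (k in which(bad)) {
      add(ids[k], "bx_type", cohort$bx_type[k],
          "bx_type must be 'protocol', 'for-cause' or 'follow-up'")
    }
  }
  if ("day_after_tx" %in% names(cohort)) {
    bad <- !is.na(cohort$day_after_tx) & cohort$day_after_tx < 0
    for (k in which(bad)) {
      add(ids[k], "day_after_tx", cohort$day_after_tx[k],
          "day_after_tx must be a non-negative number of days")
    }
  }
  if (all(c("known_deviation", "expected_engine_dx") %in% names(cohort))) {
    bad <- !is.na(cohort$known_deviation) & cohort$known_deviation &
      is.na(cohort$expected_engine_dx)
    for (k in which(bad)) {
      add(ids[k], "known_deviation", TRUE,
          "known_deviation requires expected_engine_dx to be set")
    }
  }
  if (length(findings) == 0) {
    return(data.frame(record_id = character(), field = character(),
                      value = character(), rule = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, findings)
  rownames(out) <- NULL
  out
}

#' @rdname validate_cohort
#' @param record A one-row cohort data frame.
#' @export
validate_record <- function(record) validate_cohort(record)
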