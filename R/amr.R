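# Antibody-mediated rejection rules. The axis follows the classical triad:
# microvascular inflammation (histologic criterion), evidence of
# antibody-endothelium interaction (C4d or MVI >= 2), and DSA context.

#' Microvascular inflammation score
#'
#' MVI = g + ptc; an unscored component counts 0. Range 0--6.
#'
#' @param g,ptc Glomerulitis and peritubular capillaritis scores (0--3 or
#'   `NA`).
#' @return Integer vector.
#' @export
#' @examples
#' mvi_score(g = 1, ptc = 1)
mvi_score <- function(g, ptc) {
  score0(g) + score0(ptc)
}

#' C4d as evidence of antibody interaction
#'
#' C4d counts as evidence only at score >= 2 (diffuse/focal linear staining
#' by immunofluorescence) and only in ABO-compatible grafts. In
#' ABO-incompatible transplantation, peritubular-capillary C4d positivity is
#' near-universal on protocol biopsy without rejection, so it never counts
#' as evidence of antibody interaction here. Missing C4d counts negative.
#'
#' @param c4d C4d score (0--3 or `NA`).
#' @param abo `"compatible"` or `"incompatible"`.
#' @return Logical vector.
#' @export
#' @examples
#' c4d_evidence(c4d = 2, abo = "incompatible")  # FALSE
c4d_evidence <- function(c4d, abo) {
  score0(c4d) >= 2 & abo == "compatible"
}

#' Concurrent TCMR flags used by the AMR histologic criterion
#'
#' Reports whether a score vector carries full T-cell-mediated rejection
#' (an acute grade or the chronic active criterion) or only borderline
#' changes. Full TCMR re-attributes isolated peritubular capillaritis to
#' the T-cell axis; borderline changes do not.
#'
#' @param scores Data frame with columns `t`, `t_ifta`, `i`, `i_ifta`, `v`,
#'   `ct`.
#' @return Data frame with logical columns `full_tcmr`, `borderline`.
#' @export
concurrent_tcmr_flags <- function(scores) {
  grade <- acute_tcmr_grade(scores$t, scores$i, scores$v)
  ca <- ca_tcmr_present(scores$t, scores$t_ifta, scores$i_ifta, scores$ct)
  full <- !is.na(grade) | ca
  data.frame(full_tcmr = full,
             borderline = is_borderline(scores$t, scores$i, scores$v) & !full)
}

#' AMR criterion 1: histologic evidence of microvascular inflammation
#'
#' Glomerulitis of any degree satisfies the criterion. Peritubular
#' capillaritis alone (ptc >= 1 with g = 0) also satisfies it, except in two
#' situations where isolated ptc is attributed elsewhere: (a) concurrent
#' full TCMR, unless both C4d evidence and MVI >= 2 still point to antibody
#' interaction; (b) an ABO-incompatible graft without positive DSA, where
#' isolated capillaritis is insufficient. Borderline changes alone never
#' block the criterion.
#'
#' @param scores Data frame of lesion scores (see [concurrent_tcmr_flags()];
#'   also needs `g`, `ptc`, `c4d`).
#' @param abo,hla_dsa Clinical context vectors.
#' @param flags Optional data frame from [concurrent_tcmr_flags()];
#'   recomputed when omitted.
#' @return Logical vector.
#' @export
amr_criterion1 <- function(scores, abo, hla_dsa, flags = NULL) {
  if (is.null(flags)) flags <- concurrent_tcmr_flags(scores)
  g <- score0(scores$g)
  ptc <- score0(scores$ptc)
  mvi <- mvi_score(scores$g, scores$ptc)
  c4d_ev <- c4d_evidence(scores$c4d, abo)
  block_tcmr <- flags$full_tcmr & !(c4d_ev & mvi >= 2)
  block_abo <- abo == "incompatible" & hla_dsa != "+"
  g >= 1 | (ptc >= 1 & g == 0 & !block_tcmr & !block_abo)
}

#' AMR criterion 2: evidence of antibody-endothelium interaction
#'
#' Satisfied by C4d evidence (see [c4d_evidence()]) or by moderate
#' microvascular inflammation (MVI = g + ptc >= 2).
#'
#' @inheritParams amr_criterion1
#' @return Logical vector.
#' @export
amr_criterion2 <- function(scores, abo) {
  c4d_evidence(scores$c4d, abo) | mvi_score(scores$g, scores$ptc) >= 2
}

#' AMR chronicity
#'
#' Chronic active (rather than active) AMR requires transplant
#' glomerulopathy, cg >= 1. Peritubular capillary basement-membrane
#' multilayering alone is insufficient.
#'
#' @param cg Transplant glomerulopathy score (0--3 or `NA`).
#' @return Logical vector.
#' @export
amr_chronicity <- function(cg) {
  score0(cg) >= 1
}

#' Classify the AMR axis of one or more biopsies
#'
#' Both criteria must hold for any AMR category. Chronicity (cg >= 1) gives
#' chronic active AMR. Otherwise, when DSA status is unknown and C4d
#' provides no evidence, the case is only equivocal for AMR; in all other
#' cases the category is active AMR. Negative DSA does not veto AMR when
#' both criteria hold (C4d-negative, DSA-negative AMR by microvascular
#' inflammation alone was a recognised phenotype under these rules).
#'
#' @param scores Data frame of lesion scores.
#' @param abo,hla_dsa Clinical context vectors.
#' @return Character vector: `"A-AMR"`, `"CA-AMR"`, `"equivocal-AMR"`, or
#'   `NA` when the criteria are not met.
#' @export
#' @examples
#' classify_amr(data.frame(t = 0, t_ifta = 0, i = 0, i_ifta = 0, v = 0,
#'                         g = 1, ptc = 1, c4d = 2, cg = 0, ct = 0),
#'              abo = "incompatible", hla_dsa = "-")
classify_amr <- function(scores, abo, hla_dsa) {
  crit1 <- amr_criterion1(scores, abo, hla_dsa)
  crit2 <- amr_criterion2(scores, abo)
  c4d_ev <- c4d_evidence(scores$c4d, abo)
  chronic <- amr_chronicity(scores$cg)
  ifelse(!(crit1 & crit2), NA_character_,
  ifelse(chronic, "CA-AMR",
  ifelse(hla_dsa == "unknown" & !c4d_ev, "equivocal-AMR", "A-AMR")))
}
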