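# T-cell-mediated rejection rules. All score arguments are ordinal 0-3;
# missing scores count as 0 (an unscored lesion contributes no evidence).

score0 <- function(x) {
  x <- as.integer(x)
  ifelse(is.na(x), 0L, x)
}

#' Acute TCMR grade
#'
#' Vascular lesions dominate: intimal arteritis v = 1/2/3 gives grade
#' IIA/IIB/III regardless of tubulo-interstitial scores. Without arteritis,
#' significant interstitial inflammation (i >= 2) with tubulitis t = 2 gives
#' IA and t = 3 gives IB. Anything less carries no acute grade.
#'
#' @param t,i,v Banff tubulitis, interstitial inflammation and intimal
#'   arteritis scores (0--3 or `NA`).
#' @return Character vector of grades `"IA"`, `"IB"`, `"IIA"`, `"IIB"`,
#'   `"III"`, or `NA` when no acute grade applies.
#' @export
#' @examples
#' acute_tcmr_grade(t = 2, i = 2, v = 0)
acute_tcmr_grade <- function(t, i, v) {
  t <- score0(t); i <- score0(i); v <- score0(v)
  out <- rep(NA_character_, length(t))
  out[i >= 2 & t == 2] <- "IA"
  out[i >= 2 & t == 3] <- "IB"
  out[v == 1] <- "IIA"
  out[v == 2] <- "IIB"
  out[v == 3] <- "III"
  out
}

#' Borderline changes suspicious for TCMR
#'
#' Foci of tubulitis below the acute-TCMR threshold: no arteritis, no acute
#' grade, and either any tubulitis with minor interstitial inflammation
#' (t >= 1, i <= 1) or significant inflammation with mild tubulitis
#' (i >= 2, t = 1).
#'
#' @inheritParams acute_tcmr_grade
#' @return Logical vector.
#' @export
is_borderline <- function(t, i, v) {
  t <- score0(t); i <- score0(i); v <- score0(v)
  v == 0 & is.na(acute_tcmr_grade(t, i, v)) &
    ((t >= 1 & i <= 1) | (i >= 2 & t == 1))
}

#' Chronic active TCMR criterion
#'
#' Requires inflammation in fibrotic cortex (i-IFTA >= 2) together with
#' tubulitis: either tubulitis in preserved cortex (t >= 2) or tubulitis
#' within atrophic tubules (t-IFTA >= 2) in the presence of established
#' tubular atrophy (ct >= 2).
#'
#' @param t,t_ifta,i_ifta,ct Banff scores (0--3 or `NA`); missing counts 0.
#' @return Logical vector.
#' @export
#' @examples
#' ca_tcmr_present(t = 0, t_ifta = 3, i_ifta = 2, ct = 2)
ca_tcmr_present <- function(t, t_ifta, i_ifta, ct) {
  t <- score0(t); t_ifta <- score0(t_ifta)
  i_ifta <- score0(i_ifta); ct <- score0(ct)
  i_ifta >= 2 & (t >= 2 | (t_ifta >= 2 & ct >= 2))
}

#' Classify the TCMR axis of one or more biopsies
#'
#' Applies the acute grade, chronic active criterion and borderline
#' definition in that order of precedence. When both an acute grade and the
#' chronic active criterion hold, both belong to the applicable set and the
#' diagnosis pipeline resolves priority; this function reports the acute
#' grade.
#'
#' @param scores Data frame with columns `t`, `t_ifta`, `i`, `i_ifta`, `v`,
#'   `ct` (extra columns ignored).
#' @return Data frame with columns `category` (`"A-TCMR"`, `"CA-TCMR"`,
#'   `"BC"` or `NA`), `acute_grade`, `chronic_active`, `borderline`.
#' @export
classify_tcmr <- function(scores) {
  grade <- acute_tcmr_grade(scores$t, scores$i, scores$v)
  ca <- ca_tcmr_present(scores$t, scores$t_ifta, scores$i_ifta, scores$ct)
  bc <- is_borderline(scores$t, scores$i, scores$v)
  category <- ifelse(!is.na(grade), "A-TCMR",
              ifelse(ca, "CA-TCMR",
              ifelse(bc, "BC", NA_character_)))
  data.frame(category = category, acute_grade = grade,
             chronic_active = ca, borderline = bc,
             stringsAsFactors = FALSE)
}
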