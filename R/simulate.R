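# Seeded synthetic cohorts. Scores are drawn from category-shaped ordinal
# proposals and accepted by rejection sampling against the real rule
# engine, so generated records are guaranteed to classify to their target
# category under whatever rules the engine currently implements.

default_prevalences <- function() {
  # Cohort shape: ~12% rejection overall, IFTA the dominant engine-side
  # non-rejection finding, borderline and isolated C4d staining uncommon.
  c("no-rejection" = 0.621, "IFTA" = 0.220, "BC" = 0.031,
    "C4d-no-rejection" = 0.008, "A-AMR" = 0.050, "CA-AMR" = 0.020,
    "A-TCMR" = 0.030, "CA-TCMR" = 0.020)
}

#' Specification of a synthetic cohort
#'
#' @param n_biopsies Number of biopsies to generate.
#' @param abo_incompatible_fraction Probability a biopsy comes from an
#'   ABO-incompatible graft (default 0.277, the fraction observed in a
#'   large Japanese living-donor cohort).
#' @param dsa_positive_rate Probability of positive donor-specific antibody
#'   (default 0.1; DSA is drawn from `{+, -}`).
#' @param category_prevalences Named probability vector over target primary
#'   categories, summing to 1. The default places about 12% of mass on the
#'   rejection categories, mirroring a low-prevalence surveillance-biopsy
#'   cohort.
#' @param seed Integer seed; the cohort is a deterministic function of the
#'   spec including the seed.
#' @return An object of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_biopsies, abo_incompatible_fraction = 0.277,
                        dsa_positive_rate = 0.1,
                        category_prevalences = default_prevalences(),
                        seed = 1L) {
  stopifnot(n_biopsies >= 0, n_biopsies %% 1 == 0,
            abo_incompatible_fraction >= 0, abo_incompatible_fraction <= 1,
            dsa_positive_rate >= 0, dsa_positive_rate <= 1)
  if (is.null(names(category_prevalences)) ||
      any(!nzchar(names(category_prevalences)))) {
    stop("category_prevalences must be a named vector")
  }
  bad <- setdiff(names(category_prevalences), diagnosis_categories())
  if (length(bad) > 0) stop("unknown category in prevalences: ",
                            paste(bad, collapse = ", "))
  if (any(category_prevalences < 0) ||
      abs(sum(category_prevalences) - 1) > 1e-9) {
    stop("category_prevalences must be non-negative and sum to 1")
  }
  structure(list(n_biopsies = as.integer(n_biopsies),
                 abo_incompatible_fraction = abo_incompatible_fraction,
                 dsa_positive_rate = dsa_positive_rate,
                 category_prevalences = category_prevalences,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# Ordinal draw helper: n values over 0..3 with the given weights.
rscore <- function(n, w) {
  sample(0:3, n, replace = TRUE, prob = w / sum(w))
}

# Category-shaped proposal for the 13 lesion scores. Proposals only need
# to land in the acceptance region often; rejection sampling does the rest.
propose_scores <- function(category, n, abo, dsa) {
  z <- integer(n)
  s <- data.frame(t = z, t_ifta = z, i = z, i_ifta = z, v = z, g = z,
                  ptc = z, c4d = z, cg = z, cv = z, ci = z, ct = z,
                  ptcbm = z)
  low <- c(8, 2, 0, 0)       # mostly 0, occasionally 1
  mild <- c(5, 4, 1, 0)
  if (category == "no-rejection") {
    s$i <- rscore(n, low); s$ptc <- rscore(n, low); s$g <- rscore(n, low)
    s$i_ifta <- rscore(n, low); s$cv <- rscore(n, low)
    s$ptcbm <- rscore(n, c(9, 1, 0, 0))
    # C4d is irrelevant in incompatible grafts; keep it low when compatible
    # so isolated staining does not convert the record.
    s$c4d <- ifelse(abo == "incompatible", rscore(n, c(1, 1, 4, 4)),
                    rscore(n, c(8, 2, 0, 0)))
  } else if (category == "BC") {
    s$t <- rscore(n, c(0, 5, 3, 2)); s$i <- rscore(n, c(5, 4, 1, 0))
    s$ptc <- rscore(n, low); s$c4d <- rscore(n, low)
    s$i_ifta <- rscore(n, low); s$ci <- rscore(n, low); s$ct <- s$ci
  } else if (category == "IFTA") {
    s$ci <- rscore(n, c(0, 5, 3, 2)); s$ct <- rscore(n, c(0, 5, 3, 2))
    s$i <- rscore(n, low); s$i_ifta <- rscore(n, low)
    s$ptc <- rscore(n, low); s$c4d <- rscore(n, low)
  } else if (category == "C4d-no-rejection") {
    s$c4d <- rscore(n, c(0, 0, 6, 4))
  } else if (category %in% c("A-AMR", "CA-AMR", "equivocal-AMR")) {
    # ABO-incompatible DSA-negative grafts need glomerulitis (isolated ptc
    # is blocked there), so keep g generous.
    s$g <- rscore(n, c(2, 5, 2, 1)); s$ptc <- rscore(n, c(2, 4, 3, 1))
    s$c4d <- rscore(n, c(3, 2, 3, 2)); s$t <- rscore(n, mild)
    s$i <- rscore(n, low); s$i_ifta <- rscore(n, low)
    s$ci <- rscore(n, low); s$ct <- s$ci
    s$ptcbm <- rscore(n, c(7, 3, 0, 0))
    if (category == "CA-AMR") s$cg <- rscore(n, c(0, 6, 3, 1))
    if (category == "equivocal-AMR") s$c4d <- rscore(n, c(6, 4, 0, 0))
  } else if (category == "A-TCMR") {
    vascular <- stats::runif(n) < 0.45
    s$v <- ifelse(vascular, rscore(n, c(0, 5, 3, 2)), 0L)
    s$t <- ifelse(vascular, rscore(n, mild), rscore(n, c(0, 0, 6, 4)))
    s$i <- ifelse(vascular, rscore(n, mild), rscore(n, c(0, 0, 6, 4)))
    s$ptc <- rscore(n, low); s$c4d <- rscore(n, low)
    s$i_ifta <- rscore(n, low); s$ci <- rscore(n, low); s$ct <- s$ci
  } else if (category == "CA-TCMR") {
    s$i_ifta <- rscore(n, c(0, 0, 6, 4))
    preserved <- stats::runif(n) < 0.5
    s$t <- ifelse(preserved, rscore(n, c(0, 0, 6, 4)), rscore(n, low))
    s$t_ifta <- ifelse(preserved, rscore(n, low), rscore(n, c(0, 0, 6, 4)))
    s$ct <- ifelse(preserved, rscore(n, c(4, 4, 2, 0)),
                   rscore(n, c(0, 0, 6, 4)))
    s$ci <- rscore(n, c(2, 4, 3, 1))
    s$i <- rscore(n, low); s$ptc <- rscore(n, low); s$c4d <- rscore(n, low)
  } else {
    stop("category '", category, "' is not reachable by the generator",
         call. = FALSE)
  }
  s
}

#' Draw one biopsy record that classifies to a target category
#'
#' Rejection sampling: ordinal score vectors are proposed from a
#' category-shaped distribution and accepted once [classify_cohort()]
#' assigns the target primary category under the given clinical context.
#' The returned record is therefore guaranteed, by construction, to lie in
#' the target category's acceptance region. Draws from the current RNG
#' stream; seed upstream (see [sample_cohort()]).
#'
#' @param category Target primary category.
#' @param abo,hla_dsa Clinical context for the record.
#' @param max_tries Proposal budget before declaring the pair unreachable.
#' @return A one-row cohort data frame.
#' @export
#' @examples
#' withr::with_seed(1, sample_biopsy_for_category("CA-TCMR"))
sample_biopsy_for_category <- function(category, abo = "compatible",
                                       hla_dsa = "-", max_tries = 2000L) {
  batch <- sample_category_batch(category, 1L, abo, hla_dsa,
                                 max_rounds = max_tries)
  batch
}

# Vectorized rejection sampling: k records for one category, each with its
# own context. Internal workhorse for both exported samplers.
sample_category_batch <- function(category, k, abo, dsa, max_rounds = 50L) {
  if (!category %in% diagnosis_categories()) {
    stop("unknown category: ", category)
  }
  abo <- rep_len(abo, k)
  dsa <- rep_len(dsa, k)
  if (category == "C4d-no-rejection" && any(abo == "incompatible")) {
    stop("category 'C4d-no-rejection' is unreachable in ABO-incompatible ",
         "grafts (C4d staining there reports as no-rejection)")
  }
  if (category == "equivocal-AMR" && any(dsa != "unknown")) {
    stop("category 'equivocal-AMR' is only reachable with hla_dsa 'unknown'")
  }
  out <- NULL
  pending <- seq_len(k)
  for (round in seq_len(max_rounds)) {
    m <- length(pending)
    sc <- propose_scores(category, m, abo[pending], dsa[pending])
    cand <- cbind(
      data.frame(record_id = paste0("cand", seq_len(m)),
                 patient_id = "p", bx_year = NA_integer_,
                 bx_type = "protocol", day_after_tx = 0L,
                 abo = abo[pending], hla_dsa = dsa[pending],
                 stringsAsFactors = FALSE),
      sc,
      data.frame(tma = FALSE, pathologist_dx = NA_character_,
                 expected_engine_dx = NA_character_,
                 known_deviation = FALSE, stringsAsFactors = FALSE)
    )[, COHORT_COLUMNS]
    dx <- classify_cohort(cand, validate = FALSE)$engine_dx
    ok <- dx == category
    if (any(ok)) {
      out <- rbind(out, cbind(cand[ok, , drop = FALSE],
                              slot = pending[ok]))
    }
    pending <- pending[!ok]
    if (length(pending) == 0) break
  }
  if (length(pending) > 0) {
    stop("could not generate category '", category, "' under context abo=",
         paste(unique(abo[pending]), collapse = "/"), ", dsa=",
         paste(unique(dsa[pending]), collapse = "/"),
         " within the proposal budget; the pair may be unreachable")
  }
  out <- out[order(out$slot), , drop = FALSE]
  out$slot <- NULL
  rownames(out) <- NULL
  out
}

#' Generate a synthetic biopsy cohort
#'
#' Draws true primary categories from the spec prevalences and clinical
#' context (ABO compatibility, DSA status) from the spec rates, then fills
#' in lesion scores by rejection sampling against the rule engine so that
#' every record classifies to its true category. The true label is kept in
#' `true_dx` for recovery tests. The whole cohort is a deterministic
#' function of the spec (one seeded RNG stream; the seed is recorded in the
#' `cohort_seed` attribute).
#'
#' Two context adjustments keep every (category, context) pair reachable:
#' `C4d-no-rejection` records are always ABO-compatible, and `equivocal-AMR`
#' records always carry unknown DSA. Both categories have zero default
#' prevalence.
#'
#' @param spec A [cohort_spec()].
#' @return Cohort data frame with a `true_dx` column and a `cohort_seed`
#'   attribute.
#' @export
#' @examples
#' cohort <- sample_cohort(cohort_spec(50, seed = 7))
#' all(classify_cohort(cohort)$engine_dx == cohort$true_dx)
sample_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_biopsies
  if (n == 0) {
    out <- banff_record()[0, , drop = FALSE]
    out$true_dx <- character(0)
    attr(out, "cohort_seed") <- spec$seed
    return(out)
  }
  prev <- spec$category_prevalences
  withr::with_seed(spec$seed, {
    true_dx <- sample(names(prev), n, replace = TRUE, prob = prev)
    abo <- ifelse(stats::runif(n) < spec$abo_incompatible_fraction,
                  "incompatible", "compatible")
    dsa <- ifelse(stats::runif(n) < spec$dsa_positive_rate, "+", "-")
    abo[true_dx == "C4d-no-rejection"] <- "compatible"
    dsa[true_dx == "equivocal-AMR"] <- "unknown"
    pieces <- lapply(unique(true_dx), function(cat) {
      idx <- which(true_dx == cat)
      piece <- sample_category_batch(cat, length(idx), abo[idx], dsa[idx])
      piece$slot <- idx
      piece
    })
    out <- do.call(rbind, pieces)
    out <- out[order(out$slot), , drop = FALSE]
    out$slot <- NULL
    out$record_id <- sprintf("syn%05d", seq_len(n))
    out$patient_id <- out$record_id
    out$day_after_tx <- sample(7:2000, n, replace = TRUE)
    out$bx_type <- sample(BX_TYPE_LEVELS, n, replace = TRUE,
                          prob = c(0.6, 0.3, 0.1))
    out$true_dx <- true_dx
    rownames(out) <- NULL
    attr(out, "cohort_seed") <- spec$seed
    out
  })
}

#' Apply a pathologist confusion kernel to true labels
#'
#' Emulates pathologist-versus-engine discordance: each record's
#' `pathologist_dx` is drawn from the confusion kernel row of its true
#' category. The identity kernel yields perfect downstream concordance.
#'
#' @param cohort Cohort with a `true_dx` column (see [sample_cohort()]).
#' @param confusion Named list: for each true category, a named probability
#'   vector over emitted labels (categories or `"other"`) summing to 1.
#'   Categories absent from the list keep their true label.
#' @param seed Optional integer seed for this step.
#' @return The cohort with `pathologist_dx` filled in.
#' @export
#' @examples
#' cohort <- sample_cohort(cohort_spec(20, seed = 3))
#' perturb_pathologist_labels(cohort,
#'   list("A-AMR" = c("A-AMR" = 0.9, "no-rejection" = 0.1)), seed = 4)
perturb_pathologist_labels <- function(cohort, confusion = list(),
                                       seed = NULL) {
  stopifnot(is.data.frame(cohort), "true_dx" %in% names(cohort))
  if (!is.list(confusion)) stop("confusion must be a named list of rows")
  for (cat in names(confusion)) {
    row <- confusion[[cat]]
    if (is.null(names(row)) || any(row < 0) || abs(sum(row) - 1) > 1e-9) {
      stop("confusion row for '", cat,
           "' must be a named non-negative probability vector summing to 1")
    }
  }
  draw <- function() {
    labels <- cohort$true_dx
    for (cat in names(confusion)) {
      idx <- which(cohort$true_dx == cat)
      if (length(idx) > 0) {
        row <- confusion[[cat]]
        labels[idx] <- sample(names(row), length(idx), replace = TRUE,
                              prob = row)
      }
    }
    labels
  }
  cohort$pathologist_dx <- if (is.null(seed)) draw() else {
    withr::with_seed(seed, draw())
  }
  cohort
}
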