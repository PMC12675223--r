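# Independent scalar re-derivation of the rule set, used as a brute-force
# oracle against the vectorized engine. Deliberately written as plain
# one-record if/else logic.

oracle_applicable <- function(t = 0, t_ifta = 0, i = 0, i_ifta = 0, v = 0,
                              g = 0, ptc = 0, c4d = 0, cg = 0, ci = 0,
                              ct = 0, abo = "compatible", dsa = "-") {
  z <- function(x) if (is.na(x)) 0 else x
  t <- z(t); t_ifta <- z(t_ifta); i <- z(i); i_ifta <- z(i_ifta); v <- z(v)
  g <- z(g); ptc <- z(ptc); c4d <- z(c4d); cg <- z(cg); ci <- z(ci); ct <- z(ct)

  acute <- NULL
  if (v == 3) acute <- "III"
  else if (v == 2) acute <- "IIB"
  else if (v == 1) acute <- "IIA"
  else if (i >= 2 && t == 3) acute <- "IB"
  else if (i >= 2 && t == 2) acute <- "IA"
  chronic_tcmr <- i_ifta >= 2 && (t >= 2 || (t_ifta >= 2 && ct >= 2))
  borderline <- v == 0 && is.null(acute) &&
    ((t >= 1 && i <= 1) || (i >= 2 && t == 1))

  mvi <- g + ptc
  c4d_ev <- c4d >= 2 && abo == "compatible"
  full_tcmr <- !is.null(acute) || chronic_tcmr
  block_tcmr <- full_tcmr && !(c4d_ev && mvi >= 2)
  block_abo <- abo == "incompatible" && dsa != "+"
  crit1 <- g >= 1 || (ptc >= 1 && g == 0 && !block_tcmr && !block_abo)
  crit2 <- c4d_ev || mvi >= 2

  app <- character()
  if (crit1 && crit2) {
    app <- c(app, if (cg >= 1) "CA-AMR"
             else if (dsa == "unknown" && !c4d_ev) "equivocal-AMR"
             else "A-AMR")
  }
  if (!is.null(acute)) app <- c(app, "A-TCMR")
  if (chronic_tcmr) app <- c(app, "CA-TCMR")
  if (is.null(acute) && !chronic_tcmr && borderline) app <- c(app, "BC")
  if (max(ci, ct) >= 1) app <- c(app, "IFTA")
  rejection_or_ifta <- c("A-AMR", "CA-AMR", "equivocal-AMR",
                         "A-TCMR", "CA-TCMR", "IFTA")
  if (c4d >= 2 && abo == "compatible" && !any(app %in% rejection_or_ifta)) {
    app <- c(app, "C4d-no-rejection")
  }
  app
}

oracle_primary <- function(app) {
  for (p in c("A-AMR", "equivocal-AMR", "CA-AMR", "A-TCMR", "CA-TCMR",
              "C-AMR-inactive", "BC", "IFTA", "C4d-no-rejection")) {
    if (p %in% app) return(p)
  }
  "no-rejection"
}

# Brute-force kappa on a square matrix: observed diagonal proportion and
# expected diagonal proportion from the marginals, summed cell by cell.
oracle_kappa <- function(m) {
  n <- sum(m)
  p_o <- sum(diag(m)) / n
  p_e <- 0
  for (k in seq_len(nrow(m))) {
    p_e <- p_e + sum(m[k, ]) * sum(m[, k]) / n^2
  }
  (p_o - p_e) / (1 - p_e)
}

# The exhaustive acute-lesion grid used by the property tests: all
# combinations of t, i, v, g, ptc, c4d in 0-3 under every ABO x DSA
# context, chronic scores fixed at 0.
make_engine_grid <- function() {
  grid <- expand.grid(t = 0:3, i = 0:3, v = 0:3, g = 0:3, ptc = 0:3,
                      c4d = 0:3, abo = c("compatible", "incompatible"),
                      dsa = c("+", "-", "unknown"),
                      stringsAsFactors = FALSE)
  cohort <- banff_record()[rep(1, nrow(grid)), ]
  cohort$record_id <- sprintf("g%05d", seq_len(nrow(grid)))
  for (col in c("t", "i", "v", "g", "ptc", "c4d")) {
    cohort[[col]] <- grid[[col]]
  }
  cohort$abo <- grid$abo
  cohort$hla_dsa <- grid$dsa
  rownames(cohort) <- NULL
  cohort
}
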