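scores_df <- function(...) {
  rec <- banff_record(...)
  rec[, c("t", "t_ifta", "i", "i_ifta", "v", "g", "ptc", "c4d", "cg",
          "cv", "ci", "ct", "ptcbm")]
}

test_that("MVI is g + ptc with missing components counting zero", {
  expect_identical(mvi_score(1, 1), 2L)
  expect_identical(mvi_score(0, 0), 0L)
  expect_identical(mvi_score(2, 2), 4L)
  expect_identical(mvi_score(NA, 3), 3L)
  expect_identical(mvi_score(c(0, 2), c(1, NA)), c(1L, 2L))
})

test_that("C4d counts as evidence only at >= 2 in ABO-compatible grafts", {
  expect_true(c4d_evidence(2, "compatible"))
  expect_false(c4d_evidence(2, "incompatible"))
  expect_false(c4d_evidence(1, "compatible"))
  expect_false(c4d_evidence(NA, "compatible"))
  expect_true(c4d_evidence(3, "compatible"))
})

test_that("concurrent TCMR flags separate full TCMR from borderline-only", {
  f <- concurrent_tcmr_flags(scores_df(v = 1))
  expect_true(f$full_tcmr)
  f <- concurrent_tcmr_flags(scores_df(t = 3, i = 0))
  expect_false(f$full_tcmr)
  expect_true(f$borderline)
  f <- concurrent_tcmr_flags(scores_df())
  expect_false(f$full_tcmr)
  expect_false(f$borderline)
  # chronic active TCMR also counts as full
  f <- concurrent_tcmr_flags(scores_df(t = 2, i_ifta = 2))
  expect_true(f$full_tcmr)
})

test_that("histologic criterion handles glomerulitis and the ptc-only blocks", {
  # any glomerulitis suffices
  expect_true(amr_criterion1(scores_df(g = 1), "compatible", "-"))
  # isolated ptc with full TCMR is re-attributed to the T-cell axis
  expect_false(amr_criterion1(scores_df(g = 0, ptc = 2, t = 2, i = 2, c4d = 1),
                              "compatible", "-"))
  # ... unless C4d evidence plus MVI >= 2 still point to antibody interaction
  expect_true(amr_criterion1(scores_df(g = 0, ptc = 2, t = 1, i_ifta = 2,
                                       t_ifta = 3, ct = 3, c4d = 2),
                             "compatible", "-"))
  # borderline alone does not block isolated ptc
  expect_true(amr_criterion1(scores_df(g = 0, ptc = 2, t = 2, i = 0),
                             "compatible", "-"))
  # ABO-incompatible without positive DSA blocks isolated ptc
  expect_false(amr_criterion1(scores_df(g = 0, ptc = 2), "incompatible", "-"))
  expect_true(amr_criterion1(scores_df(g = 0, ptc = 2), "incompatible", "+"))
})

test_that("interaction criterion is C4d evidence or MVI >= 2", {
  expect_true(amr_criterion2(scores_df(g = 1, ptc = 1, c4d = 0), "compatible"))
  expect_false(amr_criterion2(scores_df(g = 1, c4d = 2), "incompatible"))
  expect_false(amr_criterion2(scores_df(), "compatible"))
})

test_that("chronicity requires transplant glomerulopathy, not ptcbm alone", {
  expect_true(amr_chronicity(1))
  expect_false(amr_chronicity(0))
  rec <- scores_df(t = 1, ptc = 2, c4d = 2, ptcbm = 1)
  expect_identical(classify_amr(rec, "compatible", "-"), "A-AMR")
})

test_that("classify_amr reproduces calibrated discrepancy cases", {
  # ABO-incompatible, DSA-, g1 ptc1 C4d2: MVI carries the diagnosis
  expect_identical(
    classify_amr(scores_df(g = 1, ptc = 1, c4d = 2), "incompatible", "-"),
    "A-AMR")
  # ABO-incompatible, DSA+, g2 C4d2 cg1: chronic active
  expect_identical(
    classify_amr(scores_df(g = 2, c4d = 2, cg = 1), "incompatible", "+"),
    "CA-AMR")
  # ABO-incompatible g1 C4d2 alone: C4d discounted, MVI 1 below threshold
  expect_identical(
    classify_amr(scores_df(g = 1, c4d = 2), "incompatible", "-"),
    NA_character_)
  # compatible g1 C4d1 DSA+: no interaction evidence
  expect_identical(
    classify_amr(scores_df(g = 1, c4d = 1), "compatible", "+"),
    NA_character_)
  # unknown DSA without C4d evidence is only equivocal
  expect_identical(
    classify_amr(scores_df(g = 1, ptc = 1), "compatible", "unknown"),
    "equivocal-AMR")
  expect_identical(
    classify_amr(scores_df(g = 1, ptc = 1, c4d = 2), "compatible", "unknown"),
    "A-AMR")
  expect_identical(classify_amr(scores_df(), "compatible", "-"),
                   NA_character_)
})

test_that("AMR classification is monotone in g", {
  set.seed(41)
  n <- 400
  base <- data.frame(
    t = sample(0:3, n, TRUE), t_ifta = sample(0:3, n, TRUE),
    i = sample(0:3, n, TRUE), i_ifta = sample(0:3, n, TRUE),
    v = sample(0:3, n, TRUE), g = sample(0:2, n, TRUE),
    ptc = sample(0:3, n, TRUE), c4d = sample(0:3, n, TRUE),
    cg = sample(0:3, n, TRUE), cv = 0, ci = 0, ct = 0, ptcbm = 0)
  abo <- sample(c("compatible", "incompatible"), n, TRUE)
  dsa <- sample(c("+", "-", "unknown"), n, TRUE)
  lo <- classify_amr(base, abo, dsa)
  bumped <- base
  bumped$g <- base$g + 1L
  hi <- classify_amr(bumped, abo, dsa)
  expect_true(all(is.na(lo) | !is.na(hi)))
})

test_that("in ABO-incompatible grafts the AMR call ignores C4d entirely", {
  set.seed(42)
  n <- 300
  base <- data.frame(
    t = sample(0:3, n, TRUE), t_ifta = sample(0:3, n, TRUE),
    i = sample(0:3, n, TRUE), i_ifta = sample(0:3, n, TRUE),
    v = sample(0:3, n, TRUE), g = sample(0:3, n, TRUE),
    ptc = sample(0:3, n, TRUE), c4d = 0L,
    cg = sample(0:1, n, TRUE), cv = 0, ci = 0, ct = 0, ptcbm = 0)
  dsa <- sample(c("+", "-", "unknown"), n, TRUE)
  ref <- classify_amr(base, "incompatible", dsa)
  for (value in 1:3) {
    alt <- base
    alt$c4d <- value
    expect_identical(classify_amr(alt, "incompatible", dsa), ref)
  }
})

test_that("fixture regression: engine AMR exactly on the engine-only panel", {
  t1 <- classify_cohort(load_fixture("table1"))
  engine_only <- category_family(parse_diagnosis_label(t1$pathologist_dx)) != "AMR"
  amr_out <- !is.na(classify_amr(t1, t1$abo, t1$hla_dsa))
  # all 13 engine-only-panel rows trigger AMR
  expect_true(all(amr_out[engine_only]))
  # on the pathologist-only panel, only the flagged known deviation does
  expect_identical(t1$record_id[!engine_only & amr_out],
                   t1$record_id[!engine_only & t1$known_deviation])
})
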