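fixture_flow <- function() {
  build_flow_table(classify_cohort(load_fixture("table1")))
}

test_that("flow tables aggregate record pairs with consistent marginals", {
  flow <- fixture_flow()
  expect_s3_class(flow, "banff_flow")
  expect_identical(flow$n_total, 27L)
  expect_identical(sum(flow$counts), 27L)
  # eleven pathologist "A-AMR" rows in the fixture
  expect_identical(unname(rowSums(flow$counts)["A-AMR"]), 11)
  # aggregation: identical label pairs share a cell
  two <- rbind(banff_record("a", pathologist_dx = "BC"),
               banff_record("b", pathologist_dx = "BC"))
  two$engine_dx <- "no-rejection"
  expect_identical(max(build_flow_table(two)$counts), 2L)
  empty <- banff_record()[0, ]
  empty$engine_dx <- character(0)
  expect_identical(build_flow_table(empty)$n_total, 0L)
})

test_that("a missing label is reported by record id", {
  rec <- banff_record("bx77")
  rec$engine_dx <- "no-rejection"
  expect_error(build_flow_table(rec), "bx77")
})

test_that("agreement rates reproduce the published stratified arithmetic", {
  counts <- matrix(0, 2, 3,
                   dimnames = list(c("no-rejection", "A-AMR"),
                                   c("no-rejection", "A-AMR", "A-TCMR")))
  counts["no-rejection", "no-rejection"] <- 863
  counts["no-rejection", "A-AMR"] <- 23
  counts["A-AMR", "A-AMR"] <- 87
  counts["A-AMR", "A-TCMR"] <- 26
  counts["A-AMR", "no-rejection"] <- 18
  flow <- flow_from_counts(counts)
  nr <- agreement_rate(flow, "non_rejection")
  expect_identical(c(nr$numerator, nr$denominator), c(863, 886))
  expect_equal(round(100 * nr$rate, 1), 97.4)
  rj <- agreement_rate(flow, "rejection")
  expect_identical(c(rj$numerator, rj$denominator), c(113, 131))
  expect_equal(round(100 * rj$rate, 1), 86.3)
  ex <- agreement_rate(flow, "exact_type")
  expect_identical(c(ex$numerator, ex$denominator), c(87, 131))
  expect_equal(round(100 * ex$rate, 1), 66.4)
  # conservation: stratum denominators partition the total
  expect_identical(nr$denominator + rj$denominator, sum(counts))
})

test_that("identity and zero-diagonal tables bound the overall rate", {
  ident <- diag(c(5, 5, 5))
  dimnames(ident) <- list(c("A-AMR", "BC", "no-rejection"),
                          c("A-AMR", "BC", "no-rejection"))
  expect_equal(agreement_rate(flow_from_counts(ident), "overall")$rate, 1)
  off <- matrix(c(0, 3, 4, 0), 2, 2,
                dimnames = list(c("A-AMR", "BC"), c("A-AMR", "BC")))
  expect_equal(agreement_rate(flow_from_counts(off), "overall")$rate, 0)
  norej <- matrix(c(2, 1, 1, 2), 2, 2,
                  dimnames = list(c("BC", "no-rejection"),
                                  c("BC", "no-rejection")))
  expect_error(agreement_rate(flow_from_counts(norej), "rejection"), "empty")
})

test_that("kappa matches hand-computed and brute-force values", {
  ident <- diag(c(5, 5))
  dimnames(ident) <- list(c("a", "b"), c("a", "b"))
  expect_equal(cohen_kappa(flow_from_counts(ident)), 1)
  indep <- matrix(25, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(cohen_kappa(flow_from_counts(indep)), 0)
  hand <- matrix(c(40, 10, 10, 40), 2, 2,
                 dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(cohen_kappa(flow_from_counts(hand)), 0.6)
  degenerate <- matrix(7, 1, 1, dimnames = list("a", "a"))
  expect_error(cohen_kappa(flow_from_counts(degenerate)), "undefined")
})

test_that("kappa agrees with the brute-force oracle on random tables", {
  set.seed(11)
  for (rep in 1:100) {
    k <- sample(2:5, 1)
    m <- matrix(rpois(k * k, 3) + 1, k, k)
    dimnames(m) <- list(letters[1:k], letters[1:k])
    expect_equal(cohen_kappa(flow_from_counts(m)), oracle_kappa(m))
  }
})

test_that("kappa agrees with an independent library implementation", {
  skip_if_not_installed("e1071")
  set.seed(12)
  m <- matrix(rpois(16, 5) + 1, 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  expect_equal(cohen_kappa(flow_from_counts(m)),
               e1071::classAgreement(m)$kappa)
})

test_that("discrepancy extraction mirrors the two-panel table layout", {
  t1 <- classify_cohort(load_fixture("table1"))
  d1 <- discrepancy_records(t1)
  amr <- d1[d1$dx_family %in% "AMR", ]
  expect_identical(sum(amr$panel == "pathologist-only"), 13L)
  expect_identical(sum(amr$panel == "engine-only"), 13L)
  t2 <- classify_cohort(load_fixture("table2"))
  d2 <- discrepancy_records(t2)
  tcmr <- d2[d2$dx_family %in% "TCMR", ]
  expect_identical(sum(tcmr$panel == "pathologist-only"), 8L)
  expect_identical(sum(tcmr$panel == "engine-only"), 14L)
  # perfect agreement yields no discrepancies
  agree <- banff_record("x", pathologist_dx = "No rejection")
  agree$engine_dx <- "no-rejection"
  expect_identical(nrow(discrepancy_records(agree)), 0L)
})

test_that("flow exports round-trip through CSV and Sankey JSON", {
  flow <- fixture_flow()
  csv <- withr::local_tempfile(fileext = ".csv")
  write_flow_csv(flow, csv)
  long <- read.csv(csv, stringsAsFactors = FALSE)
  expect_identical(sum(long$count), 27L)
  expect_named(long, c("pathologist", "engine", "count"))
  sk <- flow_sankey_json(flow)
  expect_identical(sum(sk$links$value), 27L)
  expect_true(all(sk$links$source < nrow(sk$nodes)))
  expect_true(all(sk$links$target < nrow(sk$nodes)))
  js <- jsonlite::toJSON(sk, dataframe = "rows")
  expect_true(jsonlite::validate(js))
})

test_that("the agreement report holds full precision and labels kappa", {
  t1 <- classify_cohort(load_fixture("table1"))
  rep <- agreement_report(build_flow_table(t1))
  expect_s3_class(rep, "banff_agreement")
  expect_true(rep$overall$rate >= 0 && rep$overall$rate <= 1)
  expect_output(print(rep), "chance-corrected extension")
})
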