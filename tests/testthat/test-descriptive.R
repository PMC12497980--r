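test_that("case tables count per drug with an explicit missing row", {
  cs <- select_cases(small_faers())
  tb <- case_table(cs, "sex")
  expect_equal(tb$counts["Male", "nivolumab"], 1L)    # report 1
  expect_equal(tb$counts["Female", "nivolumab"], 1L)  # report 7
  expect_equal(tb$counts["Female", "pembrolizumab"], 1L)
  expect_equal(sum(tb$counts[, "Total"]), 4L)         # 4 event cases
  # percentages recompute from counts where the denominator is positive
  pos <- tb$denominators > 0
  expect_equal(tb$pct[, pos],
               round(100 * sweep(tb$counts[, pos], 2,
                                 tb$denominators[pos], "/"), 1))
  expect_true(all(is.na(tb$pct[, !pos])))
})

test_that("an empty case set yields an all-zero table", {
  cs <- select_cases(small_faers(),
                     event = event_definition("none", "Toe fracture"))
  tb <- case_table(cs, "sex")
  expect_true(all(tb$counts == 0))
})

test_that("emitted percentages always recompute from their counts", {
  cfg <- synthetic_config(n_reports = 3000, seed = 5,
                          quarters = quarter_labels("2023Q1", "2023Q4"))
  cs <- select_cases(generate_faers(cfg))
  for (v in c("sex", "age", "weight", "reporter", "country")) {
    tb <- case_table(cs, v)
    redo <- round(100 * sweep(tb$counts, 2, pmax(tb$denominators, 1),
                              "/"), 1)
    expect_true(all(abs(tb$pct - redo) <= 0.05, na.rm = TRUE))
    expect_equal(colSums(tb$counts), tb$denominators)
  }
})

test_that("table totals are invariant to input row order", {
  cs <- select_cases(small_faers())
  tb1 <- case_table(cs, "age")
  shuffled <- cs
  set.seed(2)
  shuffled$cases <- shuffled$cases[sample(nrow(shuffled$cases)), ]
  tb2 <- case_table(shuffled, "age")
  expect_identical(tb1$counts, tb2$counts)
})

test_that("chi-square matches the hand Pearson computation", {
  m <- matrix(c(10, 30, 20, 240), 2, 2)
  res <- chi_square_test(m, drop_missing = FALSE)
  expect_equal(res$statistic, 11.538, tolerance = 1e-4)
  expect_equal(res$statistic, oracle_chi2_rc(m))
  expect_equal(res$df, 1L)
  # identical column distributions give statistic 0
  same <- matrix(c(5, 10, 5, 10, 5, 10), 2, 3)
  expect_equal(chi_square_test(same)$statistic, 0)
})

test_that("chi-square equals brute force on random tables up to 6x8", {
  set.seed(77)
  for (i in 1:40) {
    nr <- sample(2:6, 1)
    nc <- sample(2:8, 1)
    m <- matrix(rpois(nr * nc, 8) + 1, nr, nc)
    res <- chi_square_test(m, drop_missing = FALSE)
    expect_equal(res$statistic, oracle_chi2_rc(m), tolerance = 1e-12)
    expect_equal(res$df, (nr - 1) * (nc - 1))
    expect_equal(res$p_value,
                 pchisq(oracle_chi2_rc(m), (nr - 1) * (nc - 1),
                        lower.tail = FALSE))
  }
})

test_that("degenerate rows/columns are dropped, not fatal", {
  m <- matrix(c(10, 0, 5, 12, 0, 6), 3, 2,
              dimnames = list(c("x", "zero", "y"), c("d1", "d2")))
  res <- chi_square_test(m, drop_missing = FALSE)
  expect_equal(res$cells_used, 4L)
  expect_match(paste(res$dropped, collapse = " "), "zero")
  expect_error(chi_square_test(matrix(c(3, 4), 1, 2),
                               drop_missing = FALSE), "2x2")
})

test_that("yearly counts split events and carry period percentages", {
  cs <- select_cases(small_faers())
  yc <- yearly_counts(cs)
  expect_equal(yc$year, 2023)
  expect_equal(yc$event, 3L)      # reports 1, 2, 7
  expect_equal(yc$non_event, 1L)  # report 6
  expect_equal(yc$total_pct, 100)
  # single year at 100% of the period
  expect_equal(sum(yc$event_pct), 100)
})

test_that("death proportions use the outcome-recorded denominator", {
  cs <- select_cases(small_faers())
  ds <- death_summary(cs)
  niv <- ds[ds$drug == "nivolumab", ]
  # nivolumab event cases: reports 1 (death) and 7 (outcome OT)
  expect_equal(niv$event_cases, 2L)
  expect_equal(niv$deaths, 1L)
  expect_equal(niv$death_pct, 50)
  # zero-denominator drug reports NA, not 0
  ate <- ds[ds$drug == "atezolizumab", ]
  expect_true(is.na(ate$death_pct))
  # all-fatal group reports 100
  expect_equal(prop_pct(11, 11), 100)
})

test_that("summary counts expand into marginal-exact case rows", {
  counts <- data.frame(
    drug = rep("drugx", 4),
    variable = c("sex", "sex", "outcome", "outcome"),
    category = c("male", "female", "death", "other_outcome"),
    count = c(7, 3, 2, 8))
  cs <- cases_from_counts(counts)
  expect_equal(nrow(cs), 10)
  expect_equal(sum(cs$sex == "male"), 7)
  expect_equal(sum(cs$outcome == "death"), 2)
  bad <- counts
  bad$count[2] <- 99
  expect_error(cases_from_counts(bad), "sum")
})
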