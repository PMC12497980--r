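test_that("the worked 2x2 example gives the textbook statistics", {
  t <- pv_2x2(10, 20, 30, 240)
  expect_equal(ror(t)$ror, 4)
  expect_equal(prr(t)$prr, 3.25)
  expect_equal(prr(t)$chi2, oracle_chi2(10, 20, 30, 240))
  expect_equal(prr(t)$chi2, 11.538, tolerance = 1e-4)
  expect_equal(bcpnn(t)$ic, log2(2.5))
  expect_equal(mgps(t)$ebgm, 2.5)
  ci <- oracle_ror_ci(10, 20, 30, 240)
  expect_equal(unlist(ror(t)[c("ror_lo95", "ror_hi95")]), ci,
               ignore_attr = TRUE)
})

test_that("independence tables score 1 on every statistic", {
  t <- pv_2x2(25, 25, 25, 25)
  s <- signal_scores(t)
  expect_equal(s$ror, 1)
  expect_equal(s$prr, 1)
  expect_equal(s$chi2, 0)
  expect_equal(s$ic, 0)
  expect_equal(s$ebgm, 1)
  expect_true(s$ror_lo95 < 1 && s$ror_hi95 > 1)
  # a/b = c/d generally
  s2 <- signal_scores(pv_2x2(6, 18, 14, 42))
  expect_equal(s2$prr, 1)
  expect_equal(s2$chi2, 0, tolerance = 1e-12)
  expect_equal(s2$ebgm, 1)
})

test_that("zero cells fall back to the flagged Haldane correction", {
  r0 <- ror(pv_2x2(0, 20, 30, 240))
  expect_true(r0$corrected)
  expect_equal(r0$ror, (0.5 * 240.5) / (20.5 * 30.5))
  # chi-square stays on raw counts
  expect_equal(prr(pv_2x2(0, 20, 30, 240))$chi2,
               oracle_chi2(0, 20, 30, 240))
  expect_false(ror(pv_2x2(10, 20, 30, 240))$corrected)
  r_none <- ror(pv_2x2(0, 20, 30, 240), zero_policy = "none")
  expect_equal(r_none$ror, 0)
  # a = 0 is a flagged non-signal for IC and EBGM
  s <- signal_scores(pv_2x2(0, 20, 30, 240))
  expect_true(is.na(s$ic) && is.na(s$ebgm))
  expect_false(s$bcpnn_positive || s$mgps_positive || s$signal)
})

test_that("EBGM is exactly 2^IC and both grow with a at fixed margins", {
  set.seed(31)
  for (i in 1:200) {
    a <- sample(1:80, 1); b <- sample(1:400, 1)
    c_ <- sample(1:400, 1); d <- sample(1:5000, 1)
    s <- signal_scores(a = a, b = b, c = c_, d = d)
    expect_equal(s$ebgm, 2^s$ic, tolerance = 1e-12)
    expect_equal(s$ebgm, ic_to_ebgm(s$ic), tolerance = 1e-12)
  }
  # monotonicity: move one report from d into a, margins free
  grid <- lapply(c(5, 10, 20, 40), function(a)
    signal_scores(a = a, b = 100, c = 200, d = 10000))
  for (stat in c("ror", "prr", "ic", "ebgm")) {
    vals <- vapply(grid, `[[`, 0, stat)
    expect_true(all(diff(vals) > 0))
  }
})

test_that("all five statistics match brute force on 1000 random tables", {
  set.seed(123)
  n_tab <- 1000
  a <- sample(1:50, n_tab, TRUE)
  b <- sample(1:300, n_tab, TRUE)
  c_ <- sample(1:300, n_tab, TRUE)
  d <- sample(1:20000, n_tab, TRUE)
  s <- signal_scores(a = a, b = b, c = c_, d = d)
  rel <- function(x, y) abs(x - y) / pmax(abs(y), 1e-300)
  expect_true(all(rel(s$ror, oracle_ror(a, b, c_, d)) < 1e-10))
  expect_true(all(rel(s$prr, oracle_prr(a, b, c_, d)) < 1e-10))
  chi_o <- mapply(oracle_chi2, a, b, c_, d)
  expect_true(all(rel(s$chi2, chi_o) < 1e-10))
  expect_true(all(rel(s$ic, oracle_ic(a, b, c_, d)) < 1e-10))
  expect_true(all(rel(s$ebgm, oracle_ebgm(a, b, c_, d)) < 1e-10))
  # ROR tracks PRR in the rare-event regime (a << c, b << d)
  rare <- a < c_ / 50 & b < d / 50
  if (any(rare))
    expect_true(all(abs(s$ror[rare] / s$prr[rare] - 1) < 0.05))
})

test_that("positivity criteria classify the boundary cases correctly", {
  flags <- function(...) signal_flags(data.frame(...))
  base <- list(a = 10, ror_lo95 = 2, prr = 3, chi2 = 10, ic025 = 0.5,
               ebgm05 = 3)
  # ROR: lower bound > 1 AND a >= 3 (a = 3 inclusive)
  expect_true(do.call(flags, modifyList(base, list(a = 3,
    ror_lo95 = 1.01)))$ror_positive)
  expect_false(do.call(flags, modifyList(base, list(a = 2,
    ror_lo95 = 5)))$ror_positive)
  expect_false(do.call(flags, modifyList(base,
    list(ror_lo95 = 1)))$ror_positive)      # exactly 1 is not a signal
  # PRR: thresholds inclusive
  expect_true(do.call(flags, modifyList(base, list(a = 3, prr = 2,
    chi2 = 4)))$prr_positive)
  expect_false(do.call(flags, modifyList(base,
    list(prr = 1.999)))$prr_positive)
  expect_false(do.call(flags, modifyList(base,
    list(chi2 = 3.999)))$prr_positive)
  expect_false(do.call(flags, modifyList(base,
    list(a = 2)))$prr_positive)
  # BCPNN: IC025 strictly positive
  expect_false(do.call(flags, modifyList(base,
    list(ic025 = 0)))$bcpnn_positive)
  expect_true(do.call(flags, modifyList(base,
    list(ic025 = 1e-9)))$bcpnn_positive)
  # MGPS: EBGM05 strictly above 2, a > 0
  expect_false(do.call(flags, modifyList(base,
    list(ebgm05 = 2)))$mgps_positive)
  expect_true(do.call(flags, modifyList(base,
    list(ebgm05 = 2.0001)))$mgps_positive)
  expect_false(do.call(flags, modifyList(base, list(a = 0,
    ebgm05 = 5)))$mgps_positive)
  # composite requires all four
  all_pos <- do.call(flags, base)
  expect_true(all_pos$signal)
  expect_false(do.call(flags, modifyList(base,
    list(ic025 = -0.1)))$signal)
})

test_that("contingency tables partition the (stratified) background", {
  demo <- rbind(demo_row("1", sex = "M"), demo_row("2", sex = "M"),
                demo_row("3", sex = "F"), demo_row("4", sex = "F"))
  drug <- rbind(drug_row("1", "OPDIVO"), drug_row("2", "OPDIVO"),
                drug_row("3", "ASPIRIN"), drug_row("4", "ASPIRIN"))
  reac <- rbind(reac_row("1", "Pancreatitis"), reac_row("2", "Nausea"),
                reac_row("3", "Pancreatitis"), reac_row("4", "Nausea"))
  cs <- select_cases(make_faers(demo, drug, reac))
  t_all <- contingency_table(cs, "nivolumab")
  expect_equal(unlist(t_all[c("a", "b", "c", "d")]),
               c(a = 1, b = 1, c = 1, d = 1))
  expect_equal(t_all$n, 4)
  t_m <- contingency_table(cs, "nivolumab", sex = "male")
  expect_equal(t_m$n, 2)   # only male reports in the stratum
  expect_equal(unlist(t_m[c("a", "b", "c", "d")]),
               c(a = 1, b = 0, c = 1, d = 0))
  expect_error(contingency_table(cs, "nivolumab", age65 = ">=65"),
               "no background")
})

test_that("drug-set margins count multi-drug reports once", {
  cs <- select_cases(small_faers())
  t_total <- contingency_table(cs, cs$dict$drugs)
  a_by_drug <- vapply(cs$dict$drugs, function(d)
    contingency_table(cs, d)$a, 0)
  # report 7 carries two drugs, so the union is one less than the sum
  expect_equal(t_total$a, sum(a_by_drug) - 1)
  expect_equal(t_total$n, nrow(cs$reports))
})

test_that("panel tables equal the generator's planted joint counts", {
  cfg <- synthetic_config(n_reports = 4000, seed = 17, duplicate_rate = 0,
                          quarters = quarter_labels("2023Q1", "2023Q2"))
  x <- generate_faers(cfg)
  truth <- attr(x, "truth")
  cs <- select_cases(x)
  for (d in c("nivolumab", "pembrolizumab")) {
    tab <- contingency_table(cs, d)
    expect_equal(tab$a, sum(truth$drug == d & truth$event, na.rm = TRUE))
    expect_equal(tab$c, sum(truth$drug == d & !truth$event,
                            na.rm = TRUE))
    expect_equal(tab$a + tab$b, sum(truth$event))
    expect_equal(tab$n, nrow(truth))
  }
})

test_that("the panel emits one row per group/event/stratum and prints", {
  cs <- select_cases(small_faers())
  panel <- pv_signal(cs, strata = "sex", pt_level = TRUE)
  expect_s3_class(panel, "pv_signal")
  n_groups <- 2 + length(cs$dict$drugs)  # Total, classes>1, drugs
  n_groups <- length(unique(panel$group))
  expect_equal(sum(panel$stratum == "overall" &
                     panel$event == "pancreatitis"), n_groups)
  expect_true(all(table(panel$group, panel$stratum, panel$event) <= 1))
  expect_output(print(panel), "ROR")
  expect_true(is.data.frame(as.data.frame(panel)))
})
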