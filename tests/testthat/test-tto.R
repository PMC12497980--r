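test_that("onset intervals use calendar day counts including leap years", {
  demo <- demo_row("1", event_dt = "20200315")
  drug <- drug_row("1", "OPDIVO")
  reac <- reac_row("1", "Pancreatitis")
  ther <- ther_row("1", "20200101")
  recs <- tto_records(select_cases(make_faers(demo, drug, reac, ther)),
                      ther)
  expect_equal(recs$records$tto_days, 74)   # across 2020-02-29
  expect_true(recs$records$complete_dates)
})

test_that("a missing start day imputes to the 1st of the month", {
  demo <- demo_row("1", event_dt = "20200320")
  ther <- ther_row("1", "202003")
  recs <- tto_records(select_cases(make_faers(
    demo, drug_row("1", "OPDIVO"), reac_row("1", "Pancreatitis"),
    ther)), ther)
  expect_equal(recs$records$tto_days, 19)
  expect_false(recs$records$complete_dates)
})

test_that("exclusion reasons partition every event case exactly once", {
  demo <- rbind(
    demo_row("1", event_dt = "20230301"),  # ok
    demo_row("2", event_dt = ""),          # no event date
    demo_row("3", event_dt = "2023"),      # month missing
    demo_row("4", event_dt = "20230101"),  # event precedes start
    demo_row("5", event_dt = "20230301"),  # no therapy row
    demo_row("6", event_dt = "20230301")   # start year only
  )
  drug <- do.call(rbind, lapply(1:6, function(i)
    drug_row(as.character(i), "OPDIVO")))
  reac <- do.call(rbind, lapply(1:6, function(i)
    reac_row(as.character(i), "Pancreatitis")))
  ther <- rbind(ther_row("1", "20230201"), ther_row("2", "20230201"),
                ther_row("3", "20230201"), ther_row("4", "20230601"),
                ther_row("6", "2023"))
  recs <- tto_records(select_cases(make_faers(demo, drug, reac, ther)),
                      ther)
  expect_equal(nrow(recs$records) + nrow(recs$exclusions), 6)
  expect_equal(recs$records$primaryid, "1")
  got <- setNames(recs$exclusions$reason, recs$exclusions$primaryid)
  expect_equal(got[["2"]], "no_event_date")
  expect_equal(got[["3"]], "partial_event_date")
  expect_equal(got[["4"]], "negative_tto")
  expect_equal(got[["5"]], "no_therapy_start")
  expect_equal(got[["6"]], "partial_start_date")
})

test_that("the earliest therapy start of the matched drug is used", {
  demo <- demo_row("1", event_dt = "20230601")
  drug <- rbind(drug_row("1", "OPDIVO"),
                drug_row("1", "OPDIVO", drug_seq = "2"))
  ther <- rbind(ther_row("1", "20230501"),
                ther_row("1", "20230201", dsg_drug_seq = "2"))
  recs <- tto_records(select_cases(make_faers(
    demo, drug, reac_row("1", "Pancreatitis"), ther)), ther)
  expect_equal(recs$records$tto_days,
               as.integer(as.Date("2023-06-01") - as.Date("2023-02-01")))
})

test_that("summaries use interpolated quartiles", {
  r <- data.frame(drug = "x", tto_days = c(1, 2, 3), sex = NA,
                  age65 = NA)
  expect_equal(tto_summary(r, by = "drug")$median, 2)
  r2 <- data.frame(drug = "x", tto_days = c(10, 20, 30, 40))
  s <- tto_summary(r2, by = "drug")
  expect_equal(s$median, 25)
  expect_equal(s$q1, 17.5)
  expect_equal(s$q3, 32.5)
  expect_true(s$small_group)  # n = 4 < 5
})

test_that("a planted Weibull recovers its closed-form median", {
  set.seed(99)
  v <- rweibull(5000, 1.5, 80)
  r <- data.frame(drug = "x", tto_days = v)
  med <- tto_summary(r, by = "drug")$median
  expect_equal(med, 80 * log(2)^(1 / 1.5), tolerance = 0.05)
})

test_that("Kaplan-Meier equals the empirical survival without censoring", {
  r <- data.frame(drug = "x", tto_days = c(1, 2, 3))
  km <- km_curve(r)
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))
  expect_equal(km$n_risk, c(3, 2, 1))
  # ties drop simultaneously
  r2 <- data.frame(drug = "x", tto_days = c(5, 5, 9))
  km2 <- km_curve(r2)
  expect_equal(km2$time, c(5, 9))
  expect_equal(km2$surv, c(1 / 3, 0))
  # single record: one step from 1 to 0
  km3 <- km_curve(data.frame(drug = "x", tto_days = 7))
  expect_equal(km3$surv, 0)
  expect_equal(km3$time, 7)
})

test_that("Kaplan-Meier matches enumeration on random samples", {
  set.seed(7)
  for (i in 1:10) {
    v <- sample(1:30, 40, replace = TRUE)
    km <- km_curve(data.frame(tto_days = v))
    o <- oracle_km(v)
    expect_equal(km$time, o$time)
    expect_equal(km$surv, o$surv, tolerance = 1e-12)
    # equals 1 - ECDF at the event times
    expect_equal(km$surv, 1 - ecdf(v)(o$time), tolerance = 1e-12)
  }
})

test_that("log-rank is zero for identical groups and scale-invariant", {
  r <- data.frame(drug = rep(c("a", "b"), each = 4),
                  tto_days = rep(c(3, 9, 17, 30), 2))
  lr <- tto_logrank(r, by = "drug")
  expect_equal(lr$statistic, 0, tolerance = 1e-12)
  expect_equal(lr$p_value, 1)
  expect_equal(lr$df, 1)
  set.seed(12)
  r2 <- data.frame(drug = rep(c("a", "b"), each = 30),
                   tto_days = c(rweibull(30, 1, 50),
                                rweibull(30, 1, 120)))
  lr_days <- tto_logrank(r2, by = "drug")
  r2$tto_days <- r2$tto_days * 7    # rescale the unit
  lr_weeks <- tto_logrank(r2, by = "drug")
  expect_equal(lr_days$statistic, lr_weeks$statistic, tolerance = 1e-12)
  expect_error(tto_logrank(data.frame(drug = "a", tto_days = 1),
                           by = "drug"), "two groups")
})

test_that("log-rank separates well-separated Weibull groups", {
  set.seed(2024)
  t1 <- rweibull(200, 1.2, 40)
  t2 <- rweibull(200, 1.2, 160)
  r <- data.frame(drug = rep(c("a", "b"), each = 200),
                  tto_days = c(t1, t2))
  lr <- tto_logrank(r, by = "drug")
  expect_lt(lr$p_value, 0.001)
  # agree with an independent permutation reference
  p_perm <- oracle_logrank_perm_p(t1, t2, n_perm = 2000)
  expect_lt(p_perm, 0.001)
})

test_that("the full onset analysis assembles summaries and tests", {
  cfg <- synthetic_config(n_reports = 30000, seed = 55,
                          missing_event_dt_rate = 0.1,
                          partial_date_rate = 0.05)
  x <- generate_faers(cfg)
  cs <- select_cases(x)
  res <- tto_analysis(cs, x$ther)
  expect_s3_class(res, "pv_tto")
  expect_gt(nrow(res$records$records), 10)
  expect_true(all(res$records$records$tto_days >= 0))
  expect_true(!is.null(res$summaries$drug))
  expect_s3_class(res$kruskal, "htest")
  # exclusions all carry a single reason
  expect_true(all(res$records$exclusions$reason %in%
                    c("no_event_date", "partial_event_date",
                      "no_therapy_start", "partial_start_date",
                      "negative_tto")))
})
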