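test_that("invalid configurations fail naming the offending field", {
  expect_error(synthetic_config(n_reports = 0), "n_reports")
  expect_error(synthetic_config(duplicate_rate = 1), "duplicate_rate")
  expect_error(synthetic_config(background_event_prob = 0),
               "background_event_prob")
  d <- synthetic_ici_drugs()
  expect_error(synthetic_config(drugs = d[0, ]), "drugs")
  d2 <- d; d2$planted_rrr[1] <- -1
  expect_error(synthetic_config(drugs = d2), "planted_rrr")
  d3 <- d; d3$name[2] <- toupper(d3$name[1])
  expect_error(synthetic_config(drugs = d3), "unique")
})

test_that("no duplicate injection means exactly one DEMO row per report", {
  cfg <- synthetic_config(n_reports = 1000, duplicate_rate = 0, seed = 7)
  x <- generate_faers(cfg)
  expect_equal(nrow(x$demo), 1000)
  expect_equal(anyDuplicated(x$demo$caseid), 0)
})

test_that("injected duplicates are strictly earlier and dedup discards them", {
  cfg <- synthetic_config(n_reports = 2000, duplicate_rate = 0.2,
                          seed = 8)
  x <- generate_faers(cfg)
  expect_equal(nrow(x$demo), 2400)
  r <- parse_reports(x$demo)
  dup_case <- r$caseid[duplicated(r$caseid)]
  expect_equal(length(dup_case), 400)
  out <- dedup_reports(r)
  expect_equal(nrow(out), 2000)
  # every survivor is an original record (ids below the duplicate block)
  expect_true(all(as.numeric(out$primaryid) <= 100000000 + 2000))
  for (cid in dup_case[1:20]) {
    pair <- r[r$caseid == cid, ]
    expect_lt(min(as.numeric(pair$fda_dt)), max(as.numeric(pair$fda_dt)))
  }
})

test_that("a fixed seed reproduces the dataset exactly", {
  cfg <- synthetic_config(n_reports = 1500, seed = 123)
  x1 <- generate_faers(cfg)
  x2 <- generate_faers(cfg)
  for (k in c("demo", "drug", "reac", "ther", "outc"))
    expect_identical(x1[[k]], x2[[k]])
  x3 <- generate_faers(synthetic_config(n_reports = 1500, seed = 124))
  expect_false(identical(x1$demo, x3$demo))
})

test_that("generated marginals match the configured distributions", {
  n <- 20000
  cfg <- synthetic_config(n_reports = n, seed = 202)
  x <- generate_faers(cfg)
  r <- parse_reports(x$demo)[seq_len(n), ]   # originals only
  # binomial 99% bounds around each configured probability
  ok <- function(phat, p) abs(phat - p) < 2.576 * sqrt(p * (1 - p) / n)
  expect_true(ok(mean(!is.na(r$sex) & r$sex == "male"),
                 cfg$sex_dist[["male"]]))
  expect_true(ok(mean(is.na(r$sex)), cfg$sex_dist[["missing"]]))
  expect_true(ok(mean(!is.na(r$country) & r$country == "JP"),
                 cfg$country_dist[["JP"]] * (1 - cfg$country_missing)))
  expect_true(ok(mean(is.na(r$age_years)), cfg$age_missing))
  # planted exposure shares
  truth <- attr(x, "truth")
  for (d in c("nivolumab", "pembrolizumab")) {
    p <- cfg$drugs$exposure_prob[cfg$drugs$name == d]
    expect_true(ok(mean(!is.na(truth$drug) & truth$drug == d), p))
  }
  # event rate among unexposed reports
  bg <- truth[is.na(truth$drug), ]
  expect_true(ok(mean(bg$event), cfg$background_event_prob))
})

test_that("quarterly files round-trip exactly through the readers", {
  dir <- withr::local_tempdir()
  cfg <- synthetic_config(n_reports = 400, seed = 31,
                          duplicate_rate = 0,
                          quarters = c("2023Q1", "2023Q3"))
  x <- generate_faers(cfg)
  paths <- write_faers(x, dir)
  # 5 tables x 2 quarters
  expect_equal(length(list.files(dir, pattern = "\\.txt$")), 10)
  expect_true(all(grepl("^(DEMO|DRUG|REAC|THER|OUTC)23Q[13]\\.txt$",
                        list.files(dir))))
  back <- read_faers(dir)
  for (k in c("demo", "drug", "reac", "ther", "outc")) {
    a <- x[[k]][order(x[[k]]$primaryid,
                      apply(x[[k]], 1, paste, collapse = "$")), ]
    b <- back[[k]][order(back[[k]]$primaryid,
                         apply(back[[k]], 1, paste, collapse = "$")), ]
    rownames(a) <- rownames(b) <- NULL
    attr(a, "rejected") <- attr(b, "rejected") <- NULL
    expect_identical(a, b)
  }
})

test_that("an empty table writes as a header-only file", {
  dir <- withr::local_tempdir()
  x <- make_faers(demo_row("1"), drug_row("1", "OPDIVO"),
                  reac_row("1", "Nausea"))
  write_faers(x, dir)
  ther_file <- list.files(dir, pattern = "^THER", full.names = TRUE)
  expect_equal(length(readLines(ther_file)), 1)
  expect_match(readLines(ther_file), "primaryid\\$dsg_drug_seq")
})

test_that("published-count fixtures rebuild exact marginal tables", {
  counts <- utils::read.csv(system.file("extdata", "ici_case_counts.csv",
                                        package = "pvfaers"))
  cs <- select_cases(faers_from_counts(counts))
  expect_equal(sum(cs$cases$is_event), sum(counts$count[
    counts$variable == "sex"]))
  tb <- case_table(cs, "sex")
  expect_equal(tb$counts["Male", "Total"],
               sum(counts$count[counts$variable == "sex" &
                                  counts$category == "male"]))
})
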