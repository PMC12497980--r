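# Synthetic FAERS-dialect data with known ground truth: planted
# drug-event association strengths (relative reporting rates), per-drug
# Weibull time-to-onset distributions, duplicate-record injection and
# configurable missingness. One primary-suspect drug is assigned per
# report (categorical over the configured exposure probabilities, the
# remainder drawn from a background pool), so planted strengths stay
# uncontaminated by co-exposure.

.default_bg_drugs <- c("METFORMIN", "ASPIRIN", "LISINOPRIL",
                       "ATORVASTATIN", "OMEPRAZOLE", "LEVOTHYROXINE",
                       "METHOTREXATE", "CISPLATIN", "CARBOPLATIN",
                       "PACLITAXEL")
.default_bg_pts <- c("Nausea", "Fatigue", "Diarrhoea", "Pyrexia", "Rash",
                     "Headache", "Vomiting", "Dyspnoea",
                     "Decreased appetite", "Anaemia")

#' Default synthetic drug panel
#'
#' The seven checkpoint inhibitors with exposure shares proportional to
#' their FAERS report volumes, planted relative reporting rates near the
#' published signal strengths, Weibull onset-time parameters matched to
#' the published medians (shape 0.85, right-skewed), and per-drug death
#' probabilities near the published mortality proportions.
#'
#' @return data.frame with one row per drug.
#' @export
synthetic_ici_drugs <- function() {
  med <- c(71.5, 71, 117, 146.5, 58.5, 67, 39.5)
  shape <- rep(0.85, 7)
  data.frame(
    name = c("atezolizumab", "durvalumab", "avelumab", "tislelizumab",
             "pembrolizumab", "nivolumab", "ipilimumab"),
    class = c("PD-L1 inhibitor", "PD-L1 inhibitor", "PD-L1 inhibitor",
              "PD-1 inhibitor", "PD-1 inhibitor", "PD-1 inhibitor",
              "CTLA-4 inhibitor"),
    synonyms = c("Tecentriq", "Imfinzi", "Bavencio", "Tevimbra;Baizean",
                 "Keytruda", "Opdivo", "Yervoy"),
    exposure_prob = c(0.007, 0.0035, 0.0007, 0.0004, 0.014, 0.018,
                      0.006),
    planted_rrr = c(2.82, 3.35, 3.23, 3.27, 2.18, 2.19, 2.78),
    tto_shape = shape,
    tto_scale = med / log(2)^(1 / shape),
    death_prob = c(0.16, 0.122, 0.273, 0, 0.136, 0.155, 0.095),
    stringsAsFactors = FALSE
  )
}

#' Quarter labels between two quarters
#'
#' @param from,to quarter labels like `"2011Q1"`.
#' @return character vector of consecutive quarter labels.
#' @export
quarter_labels <- function(from, to) {
  yr <- function(q) as.integer(substr(q, 1, 4))
  qq <- function(q) as.integer(substr(q, 6, 6))
  idx <- (yr(from) * 4 + qq(from) - 1):(yr(to) * 4 + qq(to) - 1)
  paste0(idx %/% 4, "Q", idx %% 4 + 1)
}

#' Configure the synthetic FAERS generator
#'
#' Defaults emulate a checkpoint-inhibitor pancreatitis screen: seven
#' drugs with planted association strengths and onset distributions
#' ([synthetic_ici_drugs()]), a 0.5% background event rate, demographic
#' mixes near the published case tables, 10% duplicate injection and 15%
#' partial dates over the 2011Q1-2024Q3 quarter range.
#'
#' @param n_reports number of (pre-duplication) reports.
#' @param drugs data.frame like [synthetic_ici_drugs()] (columns `name`,
#'   `class`, `synonyms`, `exposure_prob`, `planted_rrr`, `tto_shape`,
#'   `tto_scale`, `death_prob`).
#' @param background_event_prob event probability for unexposed reports;
#'   an exposed report has probability `min(1, background_event_prob *
#'   planted_rrr)`.
#' @param event_pts named numeric vector: event preferred terms with
#'   sampling weights.
#' @param background_pts,background_drugs pools for non-event reactions
#'   and non-target drugs.
#' @param sex_dist named probabilities over `male`, `female`, `missing`.
#' @param age_mean,age_sd,age_missing age model (years) and missing rate.
#' @param weight_meanlog,weight_sdlog,weight_missing lognormal weight
#'   model (kg) and missing rate.
#' @param country_dist,occupation_dist named category probabilities
#'   (occupation uses FAERS codes MD/HP/CN/PH/OT/LW).
#' @param country_missing,occupation_missing missing rates.
#' @param duplicate_rate fraction of cases receiving one extra,
#'   strictly earlier DEMO record (with a new primaryid) that
#'   deduplication must discard.
#' @param partial_date_rate probability that a date string is truncated
#'   to YYYYMM (3/4 of truncations) or YYYY (1/4).
#' @param missing_event_dt_rate probability the event date is absent.
#' @param missing_start_dt_rate probability a therapy start date is
#'   absent.
#' @param outcome_record_prob probability a report carries an outcome
#'   row (death rows are always recorded).
#' @param bg_death_prob death probability for reports not exposed to a
#'   configured drug (and for exposed non-event reports).
#' @param ici_other_role_rate probability that an unexposed report also
#'   lists a configured drug with a non-suspect role code (exercises
#'   role filtering).
#' @param quarters quarter labels reports are spread over.
#' @param seed integer seed; a fixed seed gives byte-identical output.
#' @return validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(
    n_reports = 200000,
    drugs = synthetic_ici_drugs(),
    background_event_prob = 0.005,
    event_pts = c("Pancreatitis" = 0.5, "Pancreatitis acute" = 0.2,
                  "Immune-mediated pancreatitis" = 0.12,
                  "Autoimmune pancreatitis" = 0.08,
                  "Pancreatitis chronic" = 0.05,
                  "Obstructive pancreatitis" = 0.05),
    background_pts = .default_bg_pts,
    background_drugs = .default_bg_drugs,
    sex_dist = c(male = 0.54, female = 0.36, missing = 0.10),
    age_mean = 63, age_sd = 12, age_missing = 0.26,
    weight_meanlog = log(72), weight_sdlog = 0.2, weight_missing = 0.6,
    country_dist = c(US = 0.32, JP = 0.29, DE = 0.08, FR = 0.08,
                     CN = 0.03, GB = 0.05, IT = 0.04, CA = 0.04,
                     AU = 0.03, ES = 0.04),
    country_missing = 0.01,
    occupation_dist = c(MD = 0.53, HP = 0.17, CN = 0.14, PH = 0.05,
                        OT = 0.10, LW = 0.01),
    occupation_missing = 0.01,
    duplicate_rate = 0.1,
    partial_date_rate = 0.15,
    missing_event_dt_rate = 0.3,
    missing_start_dt_rate = 0.1,
    outcome_record_prob = 0.9,
    bg_death_prob = 0.05,
    ici_other_role_rate = 0.01,
    quarters = quarter_labels("2011Q1", "2024Q3"),
    seed = 1) {
  cfg <- list(n_reports = n_reports, drugs = drugs,
              background_event_prob = background_event_prob,
              event_pts = event_pts, background_pts = background_pts,
              background_drugs = background_drugs, sex_dist = sex_dist,
              age_mean = age_mean, age_sd = age_sd,
              age_missing = age_missing,
              weight_meanlog = weight_meanlog,
              weight_sdlog = weight_sdlog,
              weight_missing = weight_missing,
              country_dist = country_dist,
              country_missing = country_missing,
              occupation_dist = occupation_dist,
              occupation_missing = occupation_missing,
              duplicate_rate = duplicate_rate,
              partial_date_rate = partial_date_rate,
              missing_event_dt_rate = missing_event_dt_rate,
              missing_start_dt_rate = missing_start_dt_rate,
              outcome_record_prob = outcome_record_prob,
              bg_death_prob = bg_death_prob,
              ici_other_role_rate = ici_other_role_rate,
              quarters = quarters, seed = seed)
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  bad <- function(field, why)
    stop("invalid synthetic config field '", field, "': ", why,
         call. = FALSE)
  if (!is.numeric(cfg$n_reports) || cfg$n_reports < 1)
    bad("n_reports", "must be a positive integer")
  d <- cfg$drugs
  if (!is.data.frame(d) || !nrow(d)) bad("drugs", "empty drug list")
  need <- c("name", "exposure_prob", "planted_rrr", "tto_shape",
            "tto_scale", "death_prob")
  miss <- setdiff(need, names(d))
  if (length(miss)) bad("drugs", paste("missing column(s):",
                                       paste(miss, collapse = ", ")))
  if (anyDuplicated(tolower(d$name)))
    bad("drugs", "drug names must be unique after case folding")
  if (any(d$exposure_prob <= 0 | d$exposure_prob >= 1))
    bad("drugs$exposure_prob", "must lie in (0,1)")
  if (sum(d$exposure_prob) >= 1)
    bad("drugs$exposure_prob", "must sum to less than 1")
  if (any(d$planted_rrr <= 0)) bad("drugs$planted_rrr", "must be > 0")
  if (any(d$tto_shape <= 0) || any(d$tto_scale <= 0))
    bad("drugs$tto_shape/tto_scale", "must be > 0")
  if (any(d$death_prob < 0 | d$death_prob > 1))
    bad("drugs$death_prob", "must lie in [0,1]")
  for (f in c("background_event_prob", "age_missing", "weight_missing",
              "country_missing", "occupation_missing",
              "missing_event_dt_rate", "missing_start_dt_rate",
              "outcome_record_prob", "bg_death_prob",
              "ici_other_role_rate"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1) bad(f, "must lie in [0,1]")
  if (cfg$background_event_prob <= 0 || cfg$background_event_prob >= 1)
    bad("background_event_prob", "must lie in (0,1)")
  for (f in c("duplicate_rate", "partial_date_rate"))
    if (cfg[[f]] < 0 || cfg[[f]] >= 1) bad(f, "must lie in [0,1)")
  for (f in c("sex_dist", "country_dist", "occupation_dist",
              "event_pts"))
    if (any(cfg[[f]] < 0)) bad(f, "weights must be non-negative")
  if (!length(cfg$quarters)) bad("quarters", "must be non-empty")
  if (is.null(cfg$seed) || !is.finite(cfg$seed))
    bad("seed", "an integer seed is required")
  invisible(cfg)
}

#' Read a synthetic-generator config from YAML
#'
#' Top-level keys are the argument names of [synthetic_config()]; the
#' `drugs` key is a list of per-drug maps.
#'
#' @param path YAML file path.
#' @return a `synthetic_config`.
#' @export
read_synthetic_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$drugs)) {
    cfg$drugs <- do.call(rbind, lapply(cfg$drugs, function(d) {
      data.frame(name = d$name, class = d$class %||% "unclassified",
                 synonyms = paste(unlist(d$synonyms), collapse = ";"),
                 exposure_prob = d$exposure_prob,
                 planted_rrr = d$planted_rrr,
                 tto_shape = d$tto_shape, tto_scale = d$tto_scale,
                 death_prob = d$death_prob %||% 0,
                 stringsAsFactors = FALSE)
    }))
  }
  for (f in c("event_pts", "sex_dist", "country_dist",
              "occupation_dist"))
    if (!is.null(cfg[[f]])) cfg[[f]] <- unlist(cfg[[f]])
  do.call(synthetic_config, cfg)
}

# truncate YYYYMMDD strings to YYYYMM / YYYY with the configured rate
.truncate_dates <- function(x, rate) {
  n <- length(x)
  u <- runif(n)
  v <- runif(n)
  out <- x
  part <- u < rate & nzchar(x)
  out[part & v < 0.75] <- substr(x[part & v < 0.75], 1, 6)
  out[part & v >= 0.75] <- substr(x[part & v >= 0.75], 1, 4)
  out
}

.sample_cat <- function(n, dist, missing_rate = 0, missing_code = "") {
  p <- dist / sum(dist)
  v <- names(dist)[sample.int(length(dist), n, replace = TRUE, prob = p)]
  if (missing_rate > 0) v[runif(n) < missing_rate] <- missing_code
  v
}

#' Generate a synthetic FAERS-dialect dataset
#'
#' Draws reports per the configured generative model and assembles the
#' five quarterly tables. The ground-truth assignment (exposed drug,
#' event flag, true onset days, death flag) is attached as the
#' `"truth"` attribute for validation against pipeline output. A fixed
#' seed yields byte-identical tables.
#'
#' @param config a `synthetic_config`.
#' @return a `faers_data` object with attributes `"truth"` (data.frame)
#'   and `"config"`.
#' @export
generate_faers <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  validate_synthetic_config(config)
  set.seed(config$seed)
  n <- as.integer(config$n_reports)
  d <- config$drugs
  k <- nrow(d)

  # exposure: one primary-suspect drug per report (0 = background pool)
  drug_idx <- sample.int(k + 1, n, replace = TRUE,
                         prob = c(1 - sum(d$exposure_prob),
                                  d$exposure_prob)) - 1L
  exposed <- drug_idx > 0L
  p_event <- ifelse(exposed,
                    pmin(1, config$background_event_prob *
                           d$planted_rrr[pmax(drug_idx, 1L)]),
                    config$background_event_prob)
  event <- runif(n) < p_event

  # calendar placement: receipt date inside an assigned quarter
  q_idx <- sample.int(length(config$quarters), n, replace = TRUE)
  qlab <- config$quarters[q_idx]
  qyear <- as.integer(substr(qlab, 1, 4))
  qq <- as.integer(substr(qlab, 6, 6))
  qstart <- as.Date(sprintf("%d-%02d-01", qyear, (qq - 1L) * 3L + 1L))
  qend <- as.Date(sprintf("%d-%02d-01", qyear + (qq == 4L),
                          ifelse(qq == 4L, 1L, qq * 3L + 1L)))
  qlen <- as.integer(qend - qstart)
  fda_date <- qstart + floor(runif(n) * qlen)

  # onset interval: planted Weibull for exposed event reports, a generic
  # right-skewed onset for everything else
  tto_all <- round(rweibull(n, 1.2, 80))
  tto_drug <- numeric(n)
  for (j in seq_len(k)) {
    sel <- exposed & drug_idx == j & event
    tto_drug[sel] <- round(rweibull(sum(sel), d$tto_shape[j],
                                    d$tto_scale[j]))
  }
  tto <- ifelse(exposed & event, tto_drug, tto_all)
  report_lag <- floor(runif(n, 7, 120))
  event_date <- fda_date - report_lag
  start_date <- event_date - tto

  # demographics
  sex <- .sample_cat(n, config$sex_dist)
  sex <- c(male = "M", female = "F", missing = "")[sex]
  age_years <- pmin(pmax(rnorm(n, config$age_mean, config$age_sd), 19),
                    90)
  age_unit_u <- runif(n)
  age_cod <- ifelse(age_unit_u < 0.9, "YR",
                    ifelse(age_unit_u < 0.95, "DEC", "MON"))
  age_val <- ifelse(age_cod == "YR", round(age_years),
                    ifelse(age_cod == "DEC", round(age_years / 10, 1),
                           round(age_years * 12)))
  age_na <- runif(n) < config$age_missing
  wt_kg <- round(exp(rnorm(n, config$weight_meanlog,
                           config$weight_sdlog)), 1)
  wt_lbs <- runif(n) < 0.15
  wt_cod <- ifelse(wt_lbs, "LBS", "KG")
  wt_val <- ifelse(wt_lbs, round(wt_kg / 0.45359237, 1), wt_kg)
  wt_na <- runif(n) < config$weight_missing
  occp <- .sample_cat(n, config$occupation_dist,
                      config$occupation_missing)
  country <- .sample_cat(n, config$country_dist, config$country_missing)

  primaryid <- as.character(100000000 + seq_len(n))
  caseid <- as.character(50000000 + seq_len(n))

  ymd <- function(x) ifelse(is.na(x), "", format(x, "%Y%m%d"))
  event_dt <- ymd(event_date)
  event_dt[runif(n) < config$missing_event_dt_rate] <- ""
  event_dt <- .truncate_dates(event_dt, config$partial_date_rate)

  demo <- data.frame(
    primaryid = primaryid, caseid = caseid,
    fda_dt = ymd(fda_date), event_dt = event_dt, sex = unname(sex),
    age = ifelse(age_na, "", as.character(age_val)),
    age_cod = ifelse(age_na, "", age_cod),
    wt = ifelse(wt_na, "", as.character(wt_val)),
    wt_cod = ifelse(wt_na, "", wt_cod),
    occp_cod = occp, reporter_country = country,
    stringsAsFactors = FALSE
  )

  # DRUG: one primary-suspect row per report plus concomitant noise
  syn_pick <- runif(n)
  brand <- vapply(strsplit(d$synonyms %||% rep("", k), ";"),
                  function(s) if (length(s) && nzchar(s[1])) s[1] else "",
                  "")
  ps_name <- character(n)
  ps_name[!exposed] <- sample(config$background_drugs, sum(!exposed),
                              replace = TRUE)
  for (j in seq_len(k)) {
    sel <- drug_idx == j
    nm <- toupper(d$name[j])
    bn <- toupper(brand[j])
    nms <- ifelse(syn_pick[sel] < 0.5 | !nzchar(bn), nm, bn)
    dose <- runif(sum(sel)) < 0.1
    nms[dose] <- paste0(nms[dose], " 100MG")
    ps_name[sel] <- nms
  }
  ps_ai <- ifelse(exposed, toupper(d$name[pmax(drug_idx, 1L)]), "")
  drug_rows <- data.frame(
    primaryid = primaryid, drug_seq = "1", role_cod = "PS",
    drugname = ps_name, prod_ai = ps_ai, stringsAsFactors = FALSE
  )
  n_con <- rpois(n, 0.8)
  con_pid <- rep(primaryid, n_con)
  con_seq <- as.character(unlist(lapply(n_con[n_con > 0], seq_len)) + 1L)
  con_role <- sample(c("C", "SS", "I"), sum(n_con), replace = TRUE,
                     prob = c(0.7, 0.2, 0.1))
  con_name <- sample(config$background_drugs, sum(n_con), replace = TRUE)
  con <- data.frame(primaryid = con_pid, drug_seq = con_seq,
                    role_cod = con_role, drugname = con_name,
                    prod_ai = "", stringsAsFactors = FALSE)
  # configured drugs as non-suspect rows on unexposed reports
  extra_sel <- !exposed & runif(n) < config$ici_other_role_rate
  if (any(extra_sel) && k > 0) {
    ex_drug <- sample.int(k, sum(extra_sel), replace = TRUE)
    con <- rbind(con, data.frame(
      primaryid = primaryid[extra_sel], drug_seq = "90", role_cod = "C",
      drugname = toupper(d$name[ex_drug]),
      prod_ai = toupper(d$name[ex_drug]), stringsAsFactors = FALSE))
  }
  drug_rows <- rbind(drug_rows, con)

  # THER: start date for the primary-suspect drug
  start_dt <- ymd(start_date)
  start_dt[runif(n) < config$missing_start_dt_rate] <- ""
  start_dt <- .truncate_dates(start_dt, config$partial_date_rate)
  end_dt <- ymd(start_date + floor(runif(n, 10, 200)))
  end_dt[runif(n) < 0.5] <- ""
  ther <- data.frame(primaryid = primaryid, dsg_drug_seq = "1",
                     start_dt = start_dt, end_dt = end_dt,
                     stringsAsFactors = FALSE)

  # REAC: the event PT for event reports, background PTs for all
  ev_pt <- .sample_cat(n, config$event_pts)
  n_bg_pt <- rpois(n, 0.7) + as.integer(!event)
  bg_pid <- rep(primaryid, n_bg_pt)
  bg_pt <- sample(config$background_pts, sum(n_bg_pt), replace = TRUE)
  reac <- rbind(
    data.frame(primaryid = primaryid[event], pt = ev_pt[event],
               stringsAsFactors = FALSE),
    data.frame(primaryid = bg_pid, pt = bg_pt, stringsAsFactors = FALSE)
  )
  reac <- unique(reac)
  reac <- reac[order(num(reac$primaryid), reac$pt), , drop = FALSE]
  rownames(reac) <- NULL

  # OUTC: deaths always recorded; otherwise recorded at the configured
  # rate with a non-death code
  death <- rep(FALSE, n)
  death[exposed & event] <- runif(sum(exposed & event)) <
    d$death_prob[drug_idx[exposed & event]]
  death[!(exposed & event)] <- runif(sum(!(exposed & event))) <
    config$bg_death_prob
  has_outc <- death | runif(n) < config$outcome_record_prob
  outc_cod <- ifelse(death, "DE",
                     sample(c("HO", "OT", "LT", "DS", "CA", "RI"), n,
                            replace = TRUE,
                            prob = c(0.4, 0.3, 0.1, 0.1, 0.05, 0.05)))
  outc <- data.frame(primaryid = primaryid[has_outc],
                     outc_cod = outc_cod[has_outc],
                     stringsAsFactors = FALSE)

  # duplicate injection: extra DEMO record per sampled case with a new
  # primaryid and strictly earlier receipt date (dedup must discard it)
  n_dup <- floor(config$duplicate_rate * n)
  if (n_dup > 0) {
    dup_i <- sort(sample.int(n, n_dup))
    dup_pid <- as.character(100000000 + n + seq_len(n_dup))
    dup_demo <- demo[dup_i, , drop = FALSE]
    dup_demo$primaryid <- dup_pid
    dup_demo$fda_dt <- ymd(fda_date[dup_i] - floor(runif(n_dup, 30, 200)))
    demo <- rbind(demo, dup_demo)
    remap <- function(tab) {
      sub <- tab[tab$primaryid %in% primaryid[dup_i], , drop = FALSE]
      sub$primaryid <- dup_pid[match(sub$primaryid, primaryid[dup_i])]
      rbind(tab, sub)
    }
    drug_rows <- remap(drug_rows)
    reac <- remap(reac)
    ther <- remap(ther)
    outc <- remap(outc)
  }
  rownames(demo) <- rownames(drug_rows) <- rownames(ther) <-
    rownames(outc) <- NULL

  truth <- data.frame(
    primaryid = primaryid, caseid = caseid,
    drug = ifelse(exposed, d$name[pmax(drug_idx, 1L)], NA_character_),
    event = event, death = death,
    tto_days = ifelse(exposed & event, tto, NA_real_),
    quarter = qlab, sex = unname(sex), age_years = age_years,
    age_missing = age_na, stringsAsFactors = FALSE
  )
  out <- faers_data(list(demo = demo, drug = drug_rows, reac = reac,
                         ther = ther, outc = outc))
  attr(out, "truth") <- truth
  attr(out, "config") <- config
  out
}

#' Build FAERS-dialect tables from published summary counts
#'
#' Expands a long table of per-drug category counts (see
#' [cases_from_counts()]) into minimal DEMO/DRUG/REAC/OUTC rows so that
#' published case-table arithmetic can be reproduced through the actual
#' pipeline. Every generated report is an event report (one "Pancreatitis"
#' reaction, unless an `event_pt` column overrides it); supported
#' variables are `sex` (male/female/missing), `age`, `weight`,
#' `occupation` (physician/health_professional/consumer/pharmacist/
#' lawyer/other/missing), `country` (two-letter codes or missing) and
#' `outcome` (death/other_outcome/none).
#'
#' @param counts data.frame with columns `drug`, `variable`, `category`,
#'   `count`.
#' @return a `faers_data` object.
#' @export
faers_from_counts <- function(counts) {
  cs <- cases_from_counts(counts)
  n <- nrow(cs)
  pick <- function(var, map, default = "") {
    if (!var %in% names(cs)) return(rep(default, n))
    v <- map[cs[[var]]]
    v[is.na(v)] <- default
    unname(v)
  }
  sex <- pick("sex", c(male = "M", female = "F"))
  age_map <- c("<18 years" = "10", "18~64.9 years" = "45",
               "65~85 years" = "75", ">85 years" = "90")
  age <- pick("age", age_map)
  wt_map <- c("<50 kg" = "45", "50~100 kg" = "70", ">100 kg" = "110")
  wt <- pick("weight", wt_map)
  occ <- pick("occupation",
              c(physician = "MD", health_professional = "HP",
                consumer = "CN", pharmacist = "PH", lawyer = "LW",
                other = "OT"))
  country <- if ("country" %in% names(cs))
    ifelse(cs$country == "missing", "", cs$country) else rep("", n)
  pid <- as.character(900000000 + seq_len(n))
  demo <- data.frame(
    primaryid = pid, caseid = as.character(800000000 + seq_len(n)),
    fda_dt = "20240101", event_dt = "", sex = sex, age = age,
    age_cod = ifelse(nzchar(age), "YR", ""), wt = wt,
    wt_cod = ifelse(nzchar(wt), "KG", ""), occp_cod = occ,
    reporter_country = country, stringsAsFactors = FALSE)
  drug <- data.frame(primaryid = pid, drug_seq = "1", role_cod = "PS",
                     drugname = toupper(cs$drug), prod_ai = "",
                     stringsAsFactors = FALSE)
  pt <- if ("event_pt" %in% names(cs)) cs$event_pt else
    rep("Pancreatitis", n)
  reac <- data.frame(primaryid = pid, pt = pt, stringsAsFactors = FALSE)
  outcome <- if ("outcome" %in% names(cs)) cs$outcome else
    rep("other_outcome", n)
  has <- outcome != "none"
  outc <- data.frame(primaryid = pid[has],
                     outc_cod = ifelse(outcome[has] == "death", "DE",
                                       "OT"),
                     stringsAsFactors = FALSE)
  ther <- data.frame(primaryid = character(0),
                     dsg_drug_seq = character(0),
                     start_dt = character(0), end_dt = character(0),
                     stringsAsFactors = FALSE)
  faers_data(list(demo = demo, drug = drug, reac = reac, ther = ther,
                  outc = outc))
}

#' Planted-signal recovery experiment
#'
#' Generates a dataset with `n_drugs` drugs planted at one common
#' relative reporting rate, runs the full pipeline (generate, select,
#' deduplicate, contingency tables, signal scores) and compares the
#' pooled drug-set EBGM against the model-implied truth: the EBGM of the
#' expected 2x2 table computed from the generative probabilities. With a
#' non-negligible exposed fraction the expected EBGM sits slightly below
#' the planted rate because the planted signal itself inflates the
#' database-wide event rate that the statistic conditions on; the
#' expected-table truth accounts for that exactly.
#'
#' @param rrr planted relative reporting rate (1 = null).
#' @param n_drugs number of drugs planted at `rrr` (pooling their
#'   reports tightens the estimate; all at `exposure_prob` each).
#' @param seed generator seed.
#' @param n_reports,exposure_prob,background_event_prob study-size
#'   parameters of the experiment.
#' @return list with `ebgm` (pooled estimate), `expected_ebgm`
#'   (generative truth), `planted_rrr`, `per_drug` (signal-score rows
#'   per drug), `composite_positive_rate` (fraction of drugs flagged by
#'   all four criteria), `a_pooled`.
#' @export
planted_recovery <- function(rrr, n_drugs, seed, n_reports = 200000,
                             exposure_prob = 0.01,
                             background_event_prob = 0.005) {
  drugs <- data.frame(
    name = sprintf("plantdrug%02d", seq_len(n_drugs)),
    class = "planted", synonyms = "",
    exposure_prob = exposure_prob, planted_rrr = rrr,
    tto_shape = 1.5, tto_scale = 80, death_prob = 0.1,
    stringsAsFactors = FALSE)
  cfg <- synthetic_config(
    n_reports = n_reports, drugs = drugs,
    background_event_prob = background_event_prob, seed = seed,
    quarters = quarter_labels("2020Q1", "2024Q4"))
  x <- generate_faers(cfg)
  dict <- drug_dictionary(data.frame(drug = drugs$name,
                                     class = drugs$class,
                                     synonyms = drugs$synonyms,
                                     stringsAsFactors = FALSE))
  cs <- select_cases(x, dict = dict, event = pancreatitis_event())
  pooled <- signal_scores(contingency_table(cs, drugs$name))
  per <- do.call(rbind, lapply(drugs$name, function(d)
    signal_scores(contingency_table(cs, d))))
  per <- cbind(data.frame(drug = drugs$name), per)
  # expected 2x2 table under the generative model
  mp <- n_drugs * exposure_prob
  pe <- min(1, background_event_prob * rrr)
  ea <- n_reports * mp * pe
  eb <- n_reports * (1 - mp) * background_event_prob
  ec <- n_reports * mp * (1 - pe)
  ed <- n_reports * (1 - mp) * (1 - background_event_prob)
  expected_ebgm <- ea * (ea + eb + ec + ed) / ((ea + ec) * (ea + eb))
  list(ebgm = pooled$ebgm, expected_ebgm = expected_ebgm,
       planted_rrr = rrr, per_drug = per,
       composite_positive_rate = mean(per$signal),
       a_pooled = pooled$a)
}
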