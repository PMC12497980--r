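# Clinical-characteristics tables, yearly trends, death summaries and
# chi-square homogeneity tests across drugs.

#' Tabulate a case characteristic per drug
#'
#' Counts event cases per (category, drug) with an explicit "Missing"
#' row, and percentages relative to each drug's event-case total (one
#' decimal), the layout of published FAERS clinical-characteristics
#' tables. Bins: age <18 / 18~64.9 / 65~85 / >85 years; weight <50 /
#' 50~100 / >100 kg.
#'
#' @param x a `pv_cases` object, or a data.frame of cases with the
#'   columns that [select_cases()] produces.
#' @param variable one of `"sex"`, `"age"`, `"weight"`, `"reporter"`,
#'   `"country"`, `"year"`, `"outcome"`.
#' @param countries countries shown individually for
#'   `variable = "country"`; the rest are pooled as "Other countries".
#' @return object of class `pv_freq`: list with integer matrix `counts`
#'   (categories x drugs, plus a Total column), matrix `pct`, vector
#'   `denominators`, and `variable`.
#' @export
case_table <- function(x, variable,
                       countries = c("US", "JP", "DE", "FR", "CN")) {
  cases <- if (inherits(x, "pv_cases"))
    x$cases[x$cases$is_event, , drop = FALSE] else x
  variable <- match.arg(variable, c("sex", "age", "weight", "reporter",
                                    "country", "year", "outcome"))
  drugs <- if (inherits(x, "pv_cases")) x$dict$drugs else
    sort(unique(cases$drug))
  cat_of <- switch(variable,
    sex = factor(c(female = "Female", male = "Male")[cases$sex],
                 levels = c("Female", "Male")),
    age = cases$age_group,
    weight = cases$weight_group,
    reporter = factor(c(consumer = "Consumer",
                        health_professional = "Health professional",
                        physician = "Physician", pharmacist = "Pharmacist",
                        lawyer = "Lawyer", other = "Others")[cases$occupation],
                      levels = c("Consumer", "Health professional",
                                 "Physician", "Pharmacist", "Lawyer",
                                 "Others")),
    country = {
      v <- ifelse(is.na(cases$country), NA_character_,
                  ifelse(cases$country %in% countries, cases$country,
                         "Other countries"))
      factor(v, levels = c(countries, "Other countries"))
    },
    year = factor(cases$year, levels = sort(unique(cases$year))),
    outcome = factor(ifelse(cases$death, "Death", "Non-death"),
                     levels = c("Death", "Non-death"))
  )
  f <- addNA(cat_of, ifany = FALSE)
  levels(f)[is.na(levels(f))] <- "Missing"
  drug_f <- factor(cases$drug, levels = drugs)
  counts <- table(f, drug_f)
  counts <- cbind(counts, Total = rowSums(counts))
  counts <- matrix(as.integer(counts), nrow = nrow(counts),
                   dimnames = dimnames(counts))
  denominators <- colSums(counts)
  pct <- sweep(counts, 2, pmax(denominators, 1), "/") * 100
  pct <- round(pct, 1)
  pct[, denominators == 0] <- NA_real_
  structure(list(counts = counts, pct = pct,
                 denominators = denominators, variable = variable),
            class = "pv_freq")
}

#' @export
print.pv_freq <- function(x, ...) {
  cat("event cases by", x$variable, "(count, % of per-drug total)\n")
  fmt <- matrix(sprintf("%d (%s%%)", x$counts,
                        ifelse(is.na(x$pct), "-", format(x$pct))),
                nrow = nrow(x$counts), dimnames = dimnames(x$counts))
  print(as.data.frame(fmt), ...)
  invisible(x)
}

#' @export
as.data.frame.pv_freq <- function(x, ...) {
  df <- data.frame(category = rownames(x$counts),
                   as.data.frame.matrix(x$counts),
                   check.names = FALSE)
  pcts <- as.data.frame.matrix(x$pct)
  names(pcts) <- paste0(names(pcts), "_pct")
  cbind(df, pcts)
}

#' Chi-square homogeneity test on a frequency table
#'
#' Pearson chi-square (no continuity correction) of the category x drug
#' table, testing whether the categorical distribution differs across
#' drugs. The "Missing" row is excluded by default so that reporting
#' practice does not masquerade as demography; set `drop_missing = FALSE`
#' to keep it. All-zero rows/columns (after dropping) are removed and
#' reported. The fraction of cells with expected count < 5 is returned as
#' a quality flag.
#'
#' @param tab a `pv_freq` object or a count matrix.
#' @param drop_missing drop the "Missing" category before testing.
#' @return object of class `pv_chisq`: list with `statistic`, `df`,
#'   `p_value`, `cells_used`, `expected_lt5` (fraction), `dropped`
#'   (labels of removed rows/columns).
#' @export
chi_square_test <- function(tab, drop_missing = TRUE) {
  m <- if (inherits(tab, "pv_freq")) tab$counts else as.matrix(tab)
  if (is.null(rownames(m)))
    rownames(m) <- paste0("r", seq_len(nrow(m)))
  if (is.null(colnames(m)))
    colnames(m) <- paste0("c", seq_len(ncol(m)))
  m <- m[, colnames(m) != "Total", drop = FALSE]
  dropped <- character(0)
  if (drop_missing && "Missing" %in% rownames(m)) {
    dropped <- c(dropped, "row: Missing")
    m <- m[rownames(m) != "Missing", , drop = FALSE]
  }
  zr <- rowSums(m) == 0
  zc <- colSums(m) == 0
  if (any(zr)) dropped <- c(dropped, paste("row:", rownames(m)[zr]))
  if (any(zc)) dropped <- c(dropped, paste("col:", colnames(m)[zc]))
  m <- m[!zr, !zc, drop = FALSE]
  if (nrow(m) < 2 || ncol(m) < 2)
    stop("need at least a 2x2 table after dropping degenerate categories")
  ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  structure(list(statistic = unname(ct$statistic),
                 df = unname(ct$parameter),
                 p_value = unname(ct$p.value),
                 cells_used = length(m),
                 expected_lt5 = mean(ct$expected < 5),
                 dropped = dropped),
            class = "pv_chisq")
}

#' @export
print.pv_chisq <- function(x, ...) {
  cat(sprintf("Pearson chi-square: X2 = %.3f, df = %d, p = %.3g\n",
              x$statistic, x$df, x$p_value))
  if (x$expected_lt5 > 0)
    cat(sprintf("  note: %.0f%% of cells have expected count < 5\n",
                100 * x$expected_lt5))
  if (length(x$dropped))
    cat("  dropped:", paste(x$dropped, collapse = "; "), "\n")
  invisible(x)
}

#' Yearly report counts, event vs non-event
#'
#' One row per calendar year of the receipt date among reports exposed to
#' a dictionary drug, split into event and non-event reports, with
#' column-wise percentages over the full period (two decimals, the
#' convention of yearly trend tables).
#'
#' @param x a `pv_cases` object.
#' @return data.frame with columns `year`, `non_event`, `non_event_pct`,
#'   `event`, `event_pct`, `total`, `total_pct`.
#' @export
yearly_counts <- function(x) {
  stopifnot(inherits(x, "pv_cases"))
  r <- x$reports[x$reports$has_target_drug & !is.na(x$reports$year), ,
                 drop = FALSE]
  years <- sort(unique(r$year))
  ev <- table(factor(r$year[r$is_event], levels = years))
  nev <- table(factor(r$year[!r$is_event], levels = years))
  tot <- ev + nev
  data.frame(year = years,
             non_event = as.integer(nev),
             non_event_pct = pct1(as.integer(nev), sum(nev), 2),
             event = as.integer(ev),
             event_pct = pct1(as.integer(ev), sum(ev), 2),
             total = as.integer(tot),
             total_pct = pct1(as.integer(tot), sum(tot), 2))
}

#' Death counts and proportions among event cases
#'
#' Deaths (any outcome code DE) per drug among event cases, with the
#' denominator restricted to cases that have any outcome recorded.
#' Zero-denominator drugs report `NA`, never 0. An overall row is
#' appended.
#'
#' @param x a `pv_cases` object.
#' @return data.frame with `drug`, `event_cases`, `with_outcome`,
#'   `deaths`, `death_pct`.
#' @export
death_summary <- function(x) {
  stopifnot(inherits(x, "pv_cases"))
  ev <- x$cases[x$cases$is_event, , drop = FALSE]
  drugs <- x$dict$drugs
  f <- factor(ev$drug, levels = drugs)
  n_cases <- as.integer(table(f))
  n_outc <- as.integer(table(f[ev$outcome_recorded]))
  n_death <- as.integer(table(f[ev$death]))
  out <- data.frame(drug = c(drugs, "overall"),
                    event_cases = c(n_cases, nrow(ev)),
                    with_outcome = c(n_outc, sum(ev$outcome_recorded)),
                    deaths = c(n_death, sum(ev$death)))
  out$death_pct <- pct1(out$deaths, out$with_outcome)
  out
}

#' Expand a published summary-count table into case rows
#'
#' Reconstructs a case-level data.frame whose marginal distributions
#' match a table of per-drug category counts (long format: `drug`,
#' `variable`, `category`, `count`). Within a drug, categories of
#' different variables are combined arbitrarily, so only the marginals —
#' which is what frequency tables and their percentages use — are
#' meaningful, not the joint distribution.
#'
#' @param counts data.frame with columns `drug`, `variable`, `category`,
#'   `count`.
#' @return data.frame with one row per case and one column per variable.
#' @export
cases_from_counts <- function(counts) {
  stopifnot(all(c("drug", "variable", "category", "count") %in%
                  names(counts)))
  counts$count <- as.integer(counts$count)
  out <- list()
  for (d in unique(counts$drug)) {
    sub <- counts[counts$drug == d, , drop = FALSE]
    vars <- unique(sub$variable)
    n <- sum(sub$count[sub$variable == vars[1]])
    cols <- list(drug = rep(d, n))
    for (v in vars) {
      sv <- sub[sub$variable == v, , drop = FALSE]
      if (sum(sv$count) != n)
        stop("counts for variable '", v, "' of drug '", d,
             "' do not sum to the drug total (", n, ")")
      cols[[v]] <- rep(sv$category, sv$count)
    }
    out[[d]] <- as.data.frame(cols, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
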