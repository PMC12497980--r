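#' Parse FAERS-style numeric dates
#'
#' FAERS date fields are numerals in `YYYYMMDD`, `YYYYMM` or `YYYY` form;
#' any of the finer components may be absent ("partial dates"). The parser
#' never fails on malformed input: implausible components (month > 12,
#' day > 31, year outside 1900-2100) are set to `NA`.
#'
#' @param x character (or numeric) vector of raw date strings.
#' @return data.frame with integer columns `year`, `month`, `day` (`NA`
#'   where the component is absent or implausible).
#' @export
#' @examples
#' parse_faers_date(c("20200315", "202003", "2020", ""))
parse_faers_date <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  x <- gsub("[^0-9]", "", x)
  n <- nchar(x)
  comp <- function(from, to, need) {
    v <- rep(NA_integer_, length(x))
    ok <- n >= need
    v[ok] <- suppressWarnings(as.integer(substr(x[ok], from, to)))
    v
  }
  year <- comp(1, 4, 4L)
  month <- comp(5, 6, 6L)
  day <- comp(7, 8, 8L)
  year[!is.na(year) & (year < 1900 | year > 2100)] <- NA_integer_
  month[!is.na(month) & (month < 1 | month > 12)] <- NA_integer_
  day[!is.na(day) & (day < 1 | day > 31)] <- NA_integer_
  data.frame(year = year, month = month, day = day)
}

#' Convert parsed partial dates to Date
#'
#' A missing day is imputed to the 1st of the month when `impute_day` is
#' set; a missing month (or year) yields `NA`. Calendar-invalid dates
#' (e.g. February 30) also yield `NA`.
#'
#' @param parsed data.frame from [parse_faers_date()].
#' @param impute_day impute day-of-month 1 when the day is absent.
#' @return `Date` vector.
#' @export
faers_date <- function(parsed, impute_day = TRUE) {
  day <- parsed$day
  if (impute_day) day[is.na(day) & !is.na(parsed$month)] <- 1L
  out <- rep(as.Date(NA), nrow(parsed))
  ok <- !is.na(parsed$year) & !is.na(parsed$month) & !is.na(day)
  out[ok] <- as.Date(sprintf("%04d-%02d-%02d",
                             parsed$year[ok], parsed$month[ok], day[ok]),
                     format = "%Y-%m-%d")
  out
}

# percentage at 1 decimal, the convention of FAERS case tables
pct1 <- function(count, denom, digits = 1) {
  ifelse(denom > 0, round(100 * count / denom, digits), NA_real_)
}

#' Percentage of a count over a denominator
#'
#' Formats counts as the percentages used throughout spontaneous-report
#' case tables (one decimal by default). Zero denominators give `NA`,
#' never 0.
#'
#' @param count,denom numeric vectors.
#' @param digits decimals to round to.
#' @return numeric vector of percentages.
#' @export
#' @examples
#' prop_pct(162, 1151)  # 14.1
prop_pct <- function(count, denom, digits = 1) {
  pct1(count, denom, digits)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stable numeric coercion that never warns
num <- function(x) suppressWarnings(as.numeric(x))
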