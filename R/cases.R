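# Case selection: deduplicate, map drugs, flag event reports, assemble
# the analysis-ready case table.

# age bins of the standard clinical-characteristics table
.age_breaks <- c(-Inf, 18, 65, 85 + 1e-9, Inf)  # 85 belongs to 65~85
.age_labels <- c("<18 years", "18~64.9 years", "65~85 years", ">85 years")
.weight_breaks <- c(-Inf, 50, 100 + 1e-9, Inf)  # 100 belongs to 50~100
.weight_labels <- c("<50 kg", "50~100 kg", ">100 kg")

#' Select drug-event cases from FAERS tables
#'
#' Runs the standard spontaneous-report extraction: parse and deduplicate
#' the DEMO table (keep the latest record per case), flag reports whose
#' reactions intersect the event PT list, map drug rows with the requested
#' role codes through the dictionary, and emit one case per
#' (report, matched drug) pair. Reports exposed to two dictionary drugs
#' with a qualifying role yield two cases, flagged `multi_ici`. Attrition
#' counts at every step are recorded.
#'
#' @param x a `faers_data` object (see [read_faers()], [generate_faers()]).
#' @param dict a `drug_dictionary`; default [ici_dictionary()].
#' @param event an `event_definition`; default [pancreatitis_event()].
#' @param role_filter drug role codes to keep; default `"PS"` (primary
#'   suspect). Use `c("PS","SS","C","I")` for any-role selection.
#' @return object of class `pv_cases`: list with `reports` (all
#'   deduplicated reports with event/outcome flags — the disproportionality
#'   background), `cases` (one row per report x matched drug),
#'   `case_seqs` (drug-sequence links for therapy-date lookup),
#'   `report_event_pts` (event PT rows per report), `attrition`, plus the
#'   dictionary and event used.
#' @export
select_cases <- function(x, dict = ici_dictionary(),
                         event = pancreatitis_event(),
                         role_filter = "PS") {
  stopifnot(inherits(x, "faers_data"))
  if (!inherits(dict, "drug_dictionary") || !length(dict$drugs))
    stop("a non-empty drug dictionary is required")
  stopifnot(inherits(event, "event_definition"))
  role_filter <- toupper(role_filter)
  if (!all(role_filter %in% c("PS", "SS", "C", "I")))
    stop("role_filter must be a subset of PS, SS, C, I")

  reports <- parse_reports(x$demo)
  n_raw <- nrow(reports)
  reports <- dedup_reports(reports)
  n_removed <- attr(reports, "removed")
  ids <- reports$primaryid

  # event flag: any reaction PT in the event list (case-insensitive)
  reac <- x$reac[x$reac$primaryid %in% ids, , drop = FALSE]
  pts_lc <- tolower(event$pts)
  hit <- tolower(trimws(reac$pt)) %in% pts_lc
  report_event_pts <- reac[hit, c("primaryid", "pt"), drop = FALSE]
  reports$is_event <- reports$primaryid %in% report_event_pts$primaryid

  # outcomes: death = any DE row; denominator flag = any outcome row
  outc <- x$outc[x$outc$primaryid %in% ids, , drop = FALSE]
  reports$outcome_recorded <- reports$primaryid %in% outc$primaryid
  reports$death <- reports$primaryid %in%
    outc$primaryid[toupper(trimws(outc$outc_cod)) == "DE"]

  reports$age_group <- cut(reports$age_years, .age_breaks, .age_labels,
                           right = FALSE)
  reports$age65 <- ifelse(is.na(reports$age_years), NA_character_,
                          ifelse(reports$age_years < 65, "<65", ">=65"))
  reports$weight_group <- cut(reports$weight_kg, .weight_breaks,
                              .weight_labels, right = FALSE)

  # drug mapping on rows with a qualifying role code
  drows <- x$drug[x$drug$primaryid %in% ids, , drop = FALSE]
  drows <- drows[toupper(trimws(drows$role_cod)) %in% role_filter, ,
                 drop = FALSE]
  drows$matched <- match_drug(drows$drugname, drows$prod_ai, dict)
  drows <- drows[!is.na(drows$matched), , drop = FALSE]
  case_seqs <- data.frame(primaryid = drows$primaryid,
                          drug = drows$matched,
                          drug_seq = drows$drug_seq,
                          stringsAsFactors = FALSE)
  pairs <- unique(case_seqs[c("primaryid", "drug")])

  reports$has_target_drug <- reports$primaryid %in% pairs$primaryid

  idx <- match(pairs$primaryid, reports$primaryid)
  pts_by_report <- split(report_event_pts$pt, report_event_pts$primaryid)
  cases <- data.frame(
    primaryid = pairs$primaryid,
    caseid = reports$caseid[idx],
    drug = pairs$drug,
    drug_class = unname(dict$classes[pairs$drug]),
    is_event = reports$is_event[idx],
    death = reports$death[idx],
    outcome_recorded = reports$outcome_recorded[idx],
    year = reports$year[idx],
    sex = reports$sex[idx],
    age_years = reports$age_years[idx],
    age_group = reports$age_group[idx],
    age65 = reports$age65[idx],
    weight_kg = reports$weight_kg[idx],
    weight_group = reports$weight_group[idx],
    occupation = reports$occupation[idx],
    country = reports$country[idx],
    stringsAsFactors = FALSE
  )
  cases$matched_pts <- ""
  m <- match(cases$primaryid, names(pts_by_report))
  has_pts <- !is.na(m)
  cases$matched_pts[has_pts] <- vapply(pts_by_report[m[has_pts]],
    function(v) paste(sort(unique(v)), collapse = "; "), "")
  multi <- table(pairs$primaryid)
  cases$multi_ici <- unname(multi[cases$primaryid] > 1)

  attrition <- data.frame(
    step = c("raw demo rows", "deduplicated reports",
             paste0("reports with dictionary drug as ",
                    paste(role_filter, collapse = "/")),
             "event reports (target drug)", "cases (report x drug)",
             "event cases (report x drug)"),
    n = c(n_raw, nrow(reports), sum(reports$has_target_drug),
          sum(reports$has_target_drug & reports$is_event),
          nrow(cases), sum(cases$is_event)),
    stringsAsFactors = FALSE
  )

  structure(list(reports = reports, cases = cases, case_seqs = case_seqs,
                 report_event_pts = report_event_pts, event = event,
                 dict = dict, role_filter = role_filter,
                 attrition = attrition, n_duplicates_removed = n_removed),
            class = "pv_cases")
}

#' @export
print.pv_cases <- function(x, ...) {
  cat("spontaneous-report case selection ('", x$event$name, "')\n",
      sep = "")
  cat("  roles kept:", paste(x$role_filter, collapse = ", "),
      "| duplicates removed:", x$n_duplicates_removed, "\n")
  print(x$attrition, row.names = FALSE)
  invisible(x)
}

#' @export
summary.pv_cases <- function(object, ...) {
  ev <- object$cases[object$cases$is_event, , drop = FALSE]
  by_drug <- table(factor(ev$drug, levels = object$dict$drugs))
  list(attrition = object$attrition,
       event_cases_by_drug = by_drug,
       event_reports = sum(object$reports$is_event &
                             object$reports$has_target_drug))
}
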