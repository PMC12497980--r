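# Time to onset: days from first therapy start of the matched drug to
# the event date, with Kaplan-Meier curves and log-rank comparisons.

#' Compute time-to-onset records for event cases
#'
#' For every event case, the onset interval is the event date minus the
#' earliest therapy start date among therapy rows linked (via drug
#' sequence) to the matched drug. Partial-date policy: a missing day is
#' imputed to the 1st of the month; a missing month excludes the record;
#' negative intervals are excluded. Every event case ends up either as a
#' record or under exactly one exclusion reason
#' (`no_event_date`, `partial_event_date`, `no_therapy_start`,
#' `partial_start_date`, `negative_tto`).
#'
#' @param x a `pv_cases` object.
#' @param ther THER table (data.frame with `primaryid`, `dsg_drug_seq`,
#'   `start_dt`), e.g. the `ther` element of a `faers_data`.
#' @return list of class `pv_tto_records` with `records` (data.frame:
#'   `primaryid`, `drug`, `tto_days`, `sex`, `age65`, `age_group`,
#'   `complete_dates`) and `exclusions` (`primaryid`, `drug`, `reason`).
#' @export
tto_records <- function(x, ther) {
  stopifnot(inherits(x, "pv_cases"))
  ev <- x$cases[x$cases$is_event, , drop = FALSE]
  if (!nrow(ev)) {
    empty <- data.frame(primaryid = character(0), drug = character(0),
                        tto_days = integer(0), sex = character(0),
                        age65 = character(0), age_group = character(0),
                        complete_dates = logical(0))
    return(structure(list(records = empty,
                          exclusions = data.frame(primaryid = character(0),
                                                  drug = character(0),
                                                  reason = character(0))),
                     class = "pv_tto_records"))
  }
  ev_event_dt <- x$reports$event_dt[match(ev$primaryid,
                                          x$reports$primaryid)]
  epd <- parse_faers_date(ev_event_dt)
  event_date <- faers_date(epd, impute_day = TRUE)
  event_day_known <- !is.na(epd$day)

  # earliest parseable therapy start per (report, drug)
  seqs <- x$case_seqs
  key_case <- paste(seqs$primaryid, seqs$drug_seq)
  key_ther <- paste(ther$primaryid, ther$dsg_drug_seq)
  th_idx <- key_ther %in% key_case
  th <- ther[th_idx, , drop = FALSE]
  spd <- parse_faers_date(th$start_dt)
  th$start_date <- faers_date(spd, impute_day = TRUE)
  th$start_day_known <- !is.na(spd$day)
  th$start_has_year <- !is.na(spd$year)
  # map therapy rows back to (primaryid, drug)
  mm <- match(paste(th$primaryid, th$dsg_drug_seq), key_case)
  th$drug <- seqs$drug[mm]

  agg_key <- paste(th$primaryid, th$drug)
  case_key <- paste(ev$primaryid, ev$drug)
  reason <- rep(NA_character_, nrow(ev))
  tto <- rep(NA_integer_, nrow(ev))
  complete <- rep(NA, nrow(ev))

  has_event_year <- !is.na(epd$year)
  has_event_date <- !is.na(event_date)
  reason[!has_event_year] <- "no_event_date"
  reason[has_event_year & !has_event_date] <- "partial_event_date"

  sp <- split(seq_len(nrow(th)), agg_key)
  for (i in which(is.na(reason))) {
    rows <- sp[[case_key[i]]]
    if (is.null(rows) || !any(!is.na(th$start_date[rows]) |
                                th$start_has_year[rows])) {
      reason[i] <- "no_therapy_start"
      next
    }
    ok <- rows[!is.na(th$start_date[rows])]
    if (!length(ok)) {
      reason[i] <- "partial_start_date"
      next
    }
    j <- ok[which.min(th$start_date[ok])]
    dt <- as.integer(event_date[i] - th$start_date[j])
    if (dt < 0) {
      reason[i] <- "negative_tto"
      next
    }
    tto[i] <- dt
    complete[i] <- event_day_known[i] && th$start_day_known[j]
  }

  keep <- is.na(reason)
  records <- data.frame(primaryid = ev$primaryid[keep],
                        drug = ev$drug[keep],
                        tto_days = tto[keep],
                        sex = ev$sex[keep],
                        age65 = ev$age65[keep],
                        age_group = as.character(ev$age_group[keep]),
                        complete_dates = complete[keep],
                        stringsAsFactors = FALSE)
  exclusions <- data.frame(primaryid = ev$primaryid[!keep],
                           drug = ev$drug[!keep],
                           reason = reason[!keep],
                           stringsAsFactors = FALSE)
  structure(list(records = records, exclusions = exclusions),
            class = "pv_tto_records")
}

#' @export
print.pv_tto_records <- function(x, ...) {
  cat("time-to-onset records:", nrow(x$records), "usable,",
      nrow(x$exclusions), "excluded\n")
  if (nrow(x$exclusions))
    print(table(x$exclusions$reason))
  invisible(x)
}

.tto_recs <- function(records) {
  if (inherits(records, "pv_tto_records")) records$records else records
}

#' Median and IQR of time to onset per group
#'
#' Quartiles use linear interpolation (R's default type-7 quantiles, the
#' midpoint convention). Groups below `min_n` records are flagged.
#'
#' @param records a `pv_tto_records` object or its `records` data.frame.
#' @param by grouping column, `"drug"` (default), `"sex"`, `"age65"`, or
#'   `NULL` for one overall group.
#' @param min_n flag groups with fewer records.
#' @return data.frame with `group`, `n`, `median`, `q1`, `q3`,
#'   `small_group`.
#' @export
tto_summary <- function(records, by = "drug", min_n = 5) {
  r <- .tto_recs(records)
  g <- if (is.null(by)) rep("all", nrow(r)) else r[[by]]
  keep <- !is.na(g)
  r <- r[keep, , drop = FALSE]; g <- g[keep]
  if (!nrow(r))
    return(data.frame(group = character(0), n = integer(0),
                      median = numeric(0), q1 = numeric(0),
                      q3 = numeric(0), small_group = logical(0)))
  out <- do.call(rbind, lapply(split(r$tto_days, g), function(v) {
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(n = length(v), median = q[2], q1 = q[1], q3 = q[3])
  }))
  out <- data.frame(group = rownames(out), out, row.names = NULL,
                    stringsAsFactors = FALSE)
  out$small_group <- out$n < min_n
  out
}

#' Kaplan-Meier curve of remaining event-free fraction
#'
#' Product-limit estimate of the "cumulative incidence of no event"
#' curve per group. With no censoring (the design here: every record is
#' an observed onset) this equals one minus the empirical CDF of onset
#' times; censoring is supported structurally through `status`.
#'
#' @param records a `pv_tto_records` object or its `records` data.frame.
#' @param by grouping column or `NULL` for a single curve.
#' @param status optional 0/1 event indicator (default all 1).
#' @return data.frame with `group`, `time`, `n_risk`, `surv`.
#' @export
km_curve <- function(records, by = NULL, status = NULL) {
  r <- .tto_recs(records)
  g <- if (is.null(by)) rep("all", nrow(r)) else r[[by]]
  keep <- !is.na(g) & !is.na(r$tto_days)
  r <- r[keep, , drop = FALSE]; g <- factor(g[keep])
  if (!nrow(r))
    return(data.frame(group = character(0), time = numeric(0),
                      n_risk = numeric(0), surv = numeric(0)))
  st <- if (is.null(status)) rep(1, nrow(r)) else status[keep]
  fit <- survival::survfit(survival::Surv(r$tto_days, st) ~ g)
  grp <- if (length(levels(g)) == 1) rep(levels(g), length(fit$time)) else
    rep(sub("^g=", "", names(fit$strata)), fit$strata)
  data.frame(group = grp, time = fit$time, n_risk = fit$n.risk,
             surv = fit$surv, stringsAsFactors = FALSE)
}

#' K-group log-rank test on onset times
#'
#' Observed-versus-expected events summed over distinct event times,
#' referred to a chi-square with (groups - 1) degrees of freedom.
#'
#' @inheritParams km_curve
#' @param by grouping column (at least two non-empty groups required).
#' @return list of class `pv_logrank` with `statistic`, `df`, `p_value`,
#'   `n` per group.
#' @export
tto_logrank <- function(records, by = "drug") {
  r <- .tto_recs(records)
  g <- factor(r[[by]])
  keep <- !is.na(g)
  r <- r[keep, , drop = FALSE]; g <- droplevels(g[keep])
  if (nlevels(g) < 2) stop("log-rank needs at least two groups")
  sd <- survival::survdiff(
    survival::Surv(r$tto_days, rep(1, nrow(r))) ~ g)
  df <- nlevels(g) - 1
  structure(list(statistic = unname(sd$chisq), df = df,
                 p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE),
                 n = table(g)),
            class = "pv_logrank")
}

#' @export
print.pv_logrank <- function(x, ...) {
  cat(sprintf("log-rank: chi2 = %.3f, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Kruskal-Wallis comparison of raw onset times
#'
#' Offered as a secondary, rank-based comparison alongside the log-rank
#' test.
#'
#' @inheritParams tto_logrank
#' @return `htest` object from [stats::kruskal.test()].
#' @export
tto_kruskal <- function(records, by = "drug") {
  r <- .tto_recs(records)
  stats::kruskal.test(r$tto_days, factor(r[[by]]))
}

#' Full time-to-onset analysis
#'
#' Computes records, per-drug and per-stratum summaries, Kaplan-Meier
#' curves, the log-rank comparison across drugs and the secondary
#' Kruskal-Wallis test.
#'
#' @param x a `pv_cases` object.
#' @param ther THER table.
#' @param strata additional grouping columns to summarize/compare by
#'   (subset of `c("sex", "age65")`).
#' @return object of class `pv_tto`.
#' @export
tto_analysis <- function(x, ther, strata = c("sex", "age65")) {
  recs <- tto_records(x, ther)
  groups <- c("drug", intersect(strata, c("sex", "age65")))
  summaries <- lapply(setNames(groups, groups),
                      function(b) tto_summary(recs, by = b))
  logranks <- lapply(setNames(groups, groups), function(b) {
    gl <- unique(recs$records[[b]])
    gl <- gl[!is.na(gl)]
    if (length(gl) < 2 ||
        min(table(recs$records[[b]])) < 1) return(NULL)
    tto_logrank(recs, by = b)
  })
  km <- km_curve(recs, by = "drug")
  kw <- if (length(unique(recs$records$drug[
    !is.na(recs$records$drug)])) >= 2)
    tto_kruskal(recs, by = "drug") else NULL
  structure(list(records = recs, overall = tto_summary(recs, by = NULL),
                 summaries = summaries, logrank = logranks, km = km,
                 kruskal = kw),
            class = "pv_tto")
}

#' @export
print.pv_tto <- function(x, ...) {
  print(x$records)
  if (nrow(x$overall))
    cat("\noverall median (IQR):",
        sprintf("%.1f (%.1f-%.1f) days, n = %d\n", x$overall$median,
                x$overall$q1, x$overall$q3, x$overall$n))
  cat("\nby drug:\n")
  print(x$summaries$drug, row.names = FALSE)
  if (!is.null(x$logrank$drug)) {
    cat("\n")
    print(x$logrank$drug)
  }
  invisible(x)
}

#' Plot Kaplan-Meier onset curves per drug
#'
#' @param x a `pv_tto` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.pv_tto <- function(x, ...) {
  km <- x$km
  groups <- unique(km$group)
  cols <- seq_along(groups)
  plot(NA, xlim = c(0, max(km$time)), ylim = c(0, 1),
       xlab = "days since drug initiation",
       ylab = "event-free fraction", main = "Time to onset", ...)
  for (i in seq_along(groups)) {
    sub <- km[km$group == groups[i], , drop = FALSE]
    lines(c(0, sub$time), c(1, sub$surv), type = "s", col = cols[i])
  }
  legend("topright", legend = groups, col = cols, lty = 1, cex = 0.8)
  invisible(x)
}
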