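# Disproportionality statistics on 2x2 report contingency tables.
#
# Cell semantics (the standard four-cell partition of the deduplicated
# report set):
#   a  target drug & target event     b  target event, other drugs
#   c  target drug, other events      d  neither
# ROR  = (a/b)/(c/d) = ad/bc
# PRR  = [a/(a+c)] / [b/(b+d)]            chi2 = four-cell Pearson
# IC   = log2[ a N / ((a+c)(a+b)) ]       (BCPNN information component)
# EBGM =       a N / ((a+c)(a+b))         (= 2^IC, relative reporting ratio)

#' Build a 2x2 drug-event contingency table
#'
#' Partitions the deduplicated reports of a (possibly stratified)
#' background into the four cells. For a drug set (a class or "all
#' ICIs"), a report with any member as a qualifying-role drug counts once
#' in the drug margin.
#'
#' @param x a `pv_cases` object.
#' @param drugs character vector of normalized drug names forming the
#'   target drug (set).
#' @param pts optional character vector of preferred terms defining the
#'   target event; default `NULL` uses the event definition of `x`.
#' @param sex optional stratum filter, `"male"` or `"female"`.
#' @param age65 optional stratum filter, `"<65"` or `">=65"`.
#' @return object of class `pv_2x2` (named list `a`, `b`, `c`, `d`, `n`).
#' @export
contingency_table <- function(x, drugs, pts = NULL, sex = NULL,
                              age65 = NULL) {
  stopifnot(inherits(x, "pv_cases"))
  r <- x$reports
  if (!is.null(sex)) r <- r[!is.na(r$sex) & r$sex == sex, , drop = FALSE]
  if (!is.null(age65))
    r <- r[!is.na(r$age65) & r$age65 == age65, , drop = FALSE]
  if (!nrow(r)) stop("no background: stratum selects zero reports")
  drug_ids <- unique(x$cases$primaryid[x$cases$drug %in% drugs])
  on_drug <- r$primaryid %in% drug_ids
  if (is.null(pts)) {
    is_event <- r$is_event
  } else {
    ev_ids <- x$report_event_pts$primaryid[
      tolower(trimws(x$report_event_pts$pt)) %in% tolower(trimws(pts))]
    is_event <- r$primaryid %in% ev_ids
  }
  pv_2x2(a = sum(on_drug & is_event), b = sum(!on_drug & is_event),
         c = sum(on_drug & !is_event), d = sum(!on_drug & !is_event))
}

#' Construct a 2x2 table from counts
#'
#' @param a,b,c,d non-negative cell counts (drug&event, event-only,
#'   drug-only, neither).
#' @return object of class `pv_2x2`.
#' @export
pv_2x2 <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) stop("cell counts must be non-negative")
  # doubles throughout: margin products overflow integer range on
  # database-sized tables
  structure(list(a = as.numeric(a), b = as.numeric(b),
                 c = as.numeric(c), d = as.numeric(d),
                 n = as.numeric(a) + as.numeric(b) + as.numeric(c) +
                   as.numeric(d)),
            class = "pv_2x2")
}

#' @export
print.pv_2x2 <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(c("event", "other events"),
                              c("target drug", "other drugs")))
  print(m)
  invisible(x)
}

# apply the zero-cell policy: Haldane-Anscombe +0.5 on all four cells of
# tables with any zero (ratio estimates only)
.haldane <- function(a, b, c, d, policy) {
  zero <- a == 0 | b == 0 | c == 0 | d == 0
  if (policy == "haldane") {
    add <- 0.5 * zero
    list(a = a + add, b = b + add, c = c + add, d = d + add,
         corrected = zero)
  } else {
    list(a = a, b = b, c = c, d = d, corrected = rep(FALSE, length(a)))
  }
}

.zero_policies <- c("haldane", "none")

# resolve (table | four vectors) into a plain list of cells; defined
# out-of-line so callers never touch a possibly-missing `c` argument
.cells <- function(t, a, b, c, d) {
  if (!is.null(t) && inherits(t, "pv_2x2")) list(a = t$a, b = t$b,
                                                 c = t$c, d = t$d)
  else list(a = as.numeric(a), b = as.numeric(b), c = as.numeric(c),
            d = as.numeric(d))
}

#' Reporting odds ratio with Wald 95% CI
#'
#' ROR = ad/bc with CI exp(log ROR +/- 1.96 sqrt(1/a+1/b+1/c+1/d)).
#' Tables with a zero cell are handled by the zero-cell policy (default
#' Haldane-Anscombe +0.5 on all cells) and flagged `corrected`.
#'
#' @param t a `pv_2x2` table; alternatively pass vectors `a`,`b`,`c`,`d`.
#' @param a,b,c,d cell count vectors (used when `t` is missing).
#' @param zero_policy `"haldane"` or `"none"`.
#' @return data.frame with `ror`, `ror_lo95`, `ror_hi95`, `corrected`.
#' @export
#' @examples
#' ror(pv_2x2(10, 20, 30, 240))  # ROR 4.0
ror <- function(t = NULL, a, b, c, d, zero_policy = .zero_policies) {
  zero_policy <- match.arg(zero_policy)
  cl <- .cells(t, a, b, c, d)
  h <- .haldane(cl$a, cl$b, cl$c, cl$d, zero_policy)
  est <- (h$a * h$d) / (h$b * h$c)
  se <- sqrt(1 / h$a + 1 / h$b + 1 / h$c + 1 / h$d)
  data.frame(ror = est,
             ror_lo95 = exp(log(est) - 1.96 * se),
             ror_hi95 = exp(log(est) + 1.96 * se),
             corrected = h$corrected)
}

#' Proportional reporting ratio and four-cell Pearson chi-square
#'
#' PRR = \[a/(a+c)\] / \[b/(b+d)\] (exposed margin a+c). The chi-square is
#' the full four-cell Pearson statistic on the raw counts (no Yates
#' correction by default), with expected counts from the table margins.
#'
#' @inheritParams ror
#' @param yates apply Yates' continuity correction to the chi-square.
#' @return data.frame with `prr`, `chi2`, `corrected`.
#' @export
#' @examples
#' prr(pv_2x2(10, 20, 30, 240))  # PRR 3.25, chi2 11.538
prr <- function(t = NULL, a, b, c, d, zero_policy = .zero_policies,
                yates = FALSE) {
  zero_policy <- match.arg(zero_policy)
  cl <- .cells(t, a, b, c, d)
  h <- .haldane(cl$a, cl$b, cl$c, cl$d, zero_policy)
  est <- (h$a / (h$a + h$c)) / (h$b / (h$b + h$d))
  with(cl, {
    n <- a + b + c + d
    ea <- (a + b) * (a + c) / n
    eb <- (a + b) * (b + d) / n
    ec <- (c + d) * (a + c) / n
    ed <- (c + d) * (b + d) / n
    adj <- if (yates) 0.5 else 0
    dev <- function(o, e) (pmax(abs(o - e) - adj, 0))^2 / e
    chi2 <- dev(a, ea) + dev(b, eb) + dev(c, ec) + dev(d, ed)
    data.frame(prr = est, chi2 = chi2, corrected = h$corrected)
  })
}

#' BCPNN information component with closed-form lower bound
#'
#' IC = log2\[aN / ((a+c)(a+b))\]; the 95% lower credibility bound uses
#' the Noren closed-form approximation
#' IC025 = IC - 3.3 a^(-1/2) - 2.0 a^(-3/2). Tables with a = 0 return
#' `NA` (flagged non-signal downstream).
#'
#' @inheritParams ror
#' @return data.frame with `ic`, `ic025`.
#' @export
#' @examples
#' bcpnn(pv_2x2(10, 20, 30, 240))  # IC = log2(2.5)
bcpnn <- function(t = NULL, a, b, c, d) {
  cl <- .cells(t, a, b, c, d)
  with(cl, {
    n <- a + b + c + d
    ic <- ifelse(a > 0, log2(a * n / ((a + c) * (a + b))), NA_real_)
    ic025 <- ic - 3.3 * a^(-0.5) - 2.0 * a^(-1.5)
    data.frame(ic = ic, ic025 = ic025)
  })
}

#' Gamma-Poisson shrinker statistics, ratio form
#'
#' EBGM = aN / ((a+c)(a+b)) — the observed-to-expected relative reporting
#' ratio (identically 2^IC). The one-sided 95% lower bound uses a
#' lognormal approximation with observed-count variance 1/a:
#' EBGM05 = exp(log EBGM - 1.645/sqrt(a)). For the full empirical-Bayes
#' shrinkage across a panel of tables see [fit_mgps_eb()].
#'
#' @inheritParams ror
#' @return data.frame with `ebgm`, `ebgm05`.
#' @export
mgps <- function(t = NULL, a, b, c, d) {
  cl <- .cells(t, a, b, c, d)
  with(cl, {
    n <- a + b + c + d
    ebgm <- ifelse(a > 0, a * n / ((a + c) * (a + b)), NA_real_)
    ebgm05 <- exp(log(ebgm) - 1.645 / sqrt(a))
    data.frame(ebgm = ebgm, ebgm05 = ebgm05)
  })
}

#' Convert an information component to the relative reporting ratio
#'
#' The BCPNN information component and the gamma-Poisson ratio statistic
#' are the same quantity on different scales: EBGM = 2^IC.
#'
#' @param ic numeric vector of information components.
#' @return numeric vector of EBGM values.
#' @export
ic_to_ebgm <- function(ic) 2^ic

#' Apply the standard four-algorithm positivity criteria
#'
#' ROR: 95% CI lower bound > 1 and a >= 3. PRR: PRR >= 2, chi2 >= 4 and
#' a >= 3 (boundaries inclusive). BCPNN: IC025 > 0. MGPS: EBGM05 > 2 and
#' a > 0. The composite `signal` flag requires all four.
#'
#' @param scores data.frame holding columns `a`, `ror_lo95`, `prr`,
#'   `chi2`, `ic025`, `ebgm05` (as produced by [signal_scores()]).
#' @return `scores` with logical columns `ror_positive`, `prr_positive`,
#'   `bcpnn_positive`, `mgps_positive`, `signal` appended.
#' @export
signal_flags <- function(scores) {
  isT <- function(x) !is.na(x) & x
  scores$ror_positive <- isT(scores$ror_lo95 > 1 & scores$a >= 3)
  scores$prr_positive <- isT(scores$prr >= 2 & scores$chi2 >= 4 &
                               scores$a >= 3)
  scores$bcpnn_positive <- isT(scores$ic025 > 0)
  scores$mgps_positive <- isT(scores$ebgm05 > 2 & scores$a > 0)
  scores$signal <- scores$ror_positive & scores$prr_positive &
    scores$bcpnn_positive & scores$mgps_positive
  scores
}

#' All four disproportionality statistics for one or more 2x2 tables
#'
#' @inheritParams ror
#' @param yates apply Yates' correction to the PRR chi-square.
#' @return data.frame with the cell counts, all point/interval estimates
#'   and the positivity flags of [signal_flags()].
#' @export
signal_scores <- function(t = NULL, a, b, c, d,
                          zero_policy = .zero_policies,
                          yates = FALSE) {
  zero_policy <- match.arg(zero_policy)
  cl <- .cells(t, a, b, c, d)
  out <- data.frame(a = cl$a, b = cl$b, c = cl$c, d = cl$d,
                    n = cl$a + cl$b + cl$c + cl$d)
  pr <- prr(a = cl$a, b = cl$b, c = cl$c, d = cl$d,
            zero_policy = zero_policy, yates = yates)
  pr$corrected <- NULL
  out <- cbind(out,
               ror(a = cl$a, b = cl$b, c = cl$c, d = cl$d,
                   zero_policy = zero_policy),
               pr,
               bcpnn(a = cl$a, b = cl$b, c = cl$c, d = cl$d),
               mgps(a = cl$a, b = cl$b, c = cl$c, d = cl$d))
  signal_flags(out)
}

#' Run the disproportionality panel
#'
#' Computes [signal_scores()] for every combination of drug group, event
#' (the configured event or each preferred term), and stratum, the layout
#' of published signal tables. Default groups: the whole dictionary
#' ("Total" set), each pharmacological class with more than one member,
#' and each drug.
#'
#' @param x a `pv_cases` object.
#' @param drugs named list of drug sets; default as described above.
#' @param pt_level also compute one row per preferred term of the event
#'   definition (drug-wise, unstratified).
#' @param strata character subset of `c("sex", "age65")`; each adds
#'   within-stratum rows where both the drug margin and the background
#'   are restricted to the stratum.
#' @param zero_policy,yates passed to [signal_scores()].
#' @return object of class `pv_signal` (a data.frame with columns
#'   `group`, `event`, `stratum` and the [signal_scores()] columns).
#' @export
pv_signal <- function(x, drugs = NULL, pt_level = FALSE, strata = NULL,
                      zero_policy = c("haldane", "none"), yates = FALSE) {
  stopifnot(inherits(x, "pv_cases"))
  zero_policy <- match.arg(zero_policy)
  if (is.null(drugs)) {
    drugs <- list()
    if (length(x$dict$drugs) > 1) drugs$Total <- x$dict$drugs
    for (cls in unique(unname(x$dict$classes))) {
      members <- x$dict$drugs[x$dict$classes == cls]
      if (length(members) > 1) drugs[[cls]] <- members
    }
    for (d in x$dict$drugs) drugs[[d]] <- d
  }
  strata_list <- list(overall = list(sex = NULL, age65 = NULL))
  if ("sex" %in% strata) {
    strata_list$male <- list(sex = "male", age65 = NULL)
    strata_list$female <- list(sex = "female", age65 = NULL)
  }
  if ("age65" %in% strata) {
    strata_list[["age<65"]] <- list(sex = NULL, age65 = "<65")
    strata_list[["age>=65"]] <- list(sex = NULL, age65 = ">=65")
  }
  grid <- list()
  for (s in names(strata_list)) {
    for (g in names(drugs)) {
      grid[[length(grid) + 1L]] <- list(group = g, event = x$event$name,
                                        pts = NULL, stratum = s)
    }
  }
  if (pt_level) {
    for (pt in x$event$pts) {
      for (g in names(drugs)) {
        grid[[length(grid) + 1L]] <- list(group = g, event = pt,
                                          pts = pt, stratum = "overall")
      }
    }
  }
  rows <- lapply(grid, function(spec) {
    st <- strata_list[[spec$stratum]]
    tab <- contingency_table(x, drugs[[spec$group]], pts = spec$pts,
                             sex = st$sex, age65 = st$age65)
    cbind(data.frame(group = spec$group, event = spec$event,
                     stratum = spec$stratum, stringsAsFactors = FALSE),
          signal_scores(tab, zero_policy = zero_policy, yates = yates))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("pv_signal", "data.frame"),
            event_name = x$event$name, zero_policy = zero_policy)
}

#' @export
print.pv_signal <- function(x, digits = 2, ...) {
  fmt <- function(v) formatC(v, digits = digits, format = "f")
  df <- data.frame(
    group = x$group, event = x$event, stratum = x$stratum, `N(a)` = x$a,
    `ROR (95% CI)` = sprintf("%s (%s-%s)", fmt(x$ror), fmt(x$ror_lo95),
                             fmt(x$ror_hi95)),
    `PRR (chi2)` = sprintf("%s (%s)", fmt(x$prr), fmt(x$chi2)),
    `EBGM (EBGM05)` = sprintf("%s (%s)", fmt(x$ebgm), fmt(x$ebgm05)),
    `IC (IC025)` = sprintf("%s (%s)", fmt(x$ic), fmt(x$ic025)),
    signal = ifelse(x$signal, "*", ""),
    check.names = FALSE
  )
  cat("disproportionality panel (", nrow(df), " rows)\n", sep = "")
  print(df, row.names = FALSE, right = FALSE)
  invisible(x)
}

#' @export
summary.pv_signal <- function(object, ...) {
  list(n_rows = nrow(object),
       n_signal = sum(object$signal),
       positives = as.data.frame(object)[object$signal,
                                         c("group", "event", "stratum",
                                           "a", "ror", "ebgm")])
}

#' @export
as.data.frame.pv_signal <- function(x, ...) {
  class(x) <- "data.frame"
  x
}

#' Forest plot of the panel's reporting odds ratios
#'
#' @param x a `pv_signal` object.
#' @param stratum which stratum's rows to show.
#' @param ... passed to [graphics::plot()].
#' @export
plot.pv_signal <- function(x, stratum = "overall", ...) {
  df <- as.data.frame(x)
  df <- df[df$stratum == stratum & df$event == attr(x, "event_name"), ,
           drop = FALSE]
  if (!nrow(df)) stop("no rows for stratum '", stratum, "'")
  k <- nrow(df)
  ylim <- c(0.5, k + 0.5)
  xlim <- range(c(df$ror_lo95, df$ror_hi95, 1), finite = TRUE)
  plot(df$ror, k:1, log = "x", xlim = xlim, ylim = ylim, pch = 18,
       yaxt = "n", xlab = "ROR (95% CI, log scale)", ylab = "",
       main = paste("Reporting odds ratios,", stratum), ...)
  segments(df$ror_lo95, k:1, df$ror_hi95, k:1)
  abline(v = 1, lty = 2, col = "grey40")
  axis(2, at = k:1, labels = df$group, las = 1, cex.axis = 0.8)
  invisible(x)
}
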