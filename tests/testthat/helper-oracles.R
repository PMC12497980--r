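# Independent brute-force oracles, deliberately written with naive
# arithmetic (no shared code with the package internals).

oracle_ror <- function(a, b, c, d) (a / b) / (c / d)

oracle_ror_ci <- function(a, b, c, d) {
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  r <- oracle_ror(a, b, c, d)
  c(exp(log(r) - 1.96 * se), exp(log(r) + 1.96 * se))
}

oracle_prr <- function(a, b, c, d) (a / (a + c)) / (b / (b + d))

# four-cell Pearson chi-square by direct summation over the 2x2 grid
oracle_chi2 <- function(a, b, c, d) {
  obs <- matrix(c(a, c, b, d), 2, 2)
  tot <- sum(obs)
  out <- 0
  for (i in 1:2) for (j in 1:2) {
    e <- sum(obs[i, ]) * sum(obs[, j]) / tot
    out <- out + (obs[i, j] - e)^2 / e
  }
  out
}

# Pearson chi-square for an arbitrary r x c count matrix
oracle_chi2_rc <- function(m) {
  tot <- sum(m)
  out <- 0
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    e <- sum(m[i, ]) * sum(m[, j]) / tot
    out <- out + (m[i, j] - e)^2 / e
  }
  out
}

oracle_ic <- function(a, b, c, d) {
  log((a * (a + b + c + d)) / ((a + c) * (a + b))) / log(2)
}

oracle_ebgm <- function(a, b, c, d) {
  a * (a + b + c + d) / ((a + c) * (a + b))
}

# expected 2x2 cell counts implied by the single-suspect generative
# model: one drug at exposure p, event prob bg * rrr when exposed, bg
# otherwise; used as the parameter-recovery truth
oracle_expected_table <- function(n, exposure, bg, rrr) {
  pe_exposed <- min(1, bg * rrr)
  a <- n * exposure * pe_exposed
  c_ <- n * exposure * (1 - pe_exposed)
  b <- n * (1 - exposure) * bg
  d <- n * (1 - exposure) * (1 - bg)
  list(a = a, b = b, c = c_, d = d)
}

# Kaplan-Meier by direct enumeration (all observations are events)
oracle_km <- function(times) {
  n <- length(times)
  ts <- sort(unique(times))
  surv <- numeric(length(ts))
  s <- 1
  at_risk <- n
  for (i in seq_along(ts)) {
    d <- sum(times == ts[i])
    s <- s * (1 - d / at_risk)
    surv[i] <- s
    at_risk <- at_risk - d
  }
  data.frame(time = ts, surv = surv)
}

# two-group log-rank statistic from first principles (no censoring)
oracle_logrank_stat <- function(t1, t2) {
  times <- sort(unique(c(t1, t2)))
  o1 <- 0; e1 <- 0; v <- 0
  for (tm in times) {
    n1 <- sum(t1 >= tm); n2 <- sum(t2 >= tm)
    d1 <- sum(t1 == tm); d2 <- sum(t2 == tm)
    n <- n1 + n2; d <- d1 + d2
    if (n < 2) next
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n
    v <- v + d * (n1 / n) * (n2 / n) * (n - d) / (n - 1)
  }
  (o1 - e1)^2 / v
}

# permutation reference distribution of the two-group log-rank
# statistic; the per-shuffle statistic uses tabulated death counts and
# reverse-cumulative at-risk counts so 10,000 shuffles stay cheap
oracle_logrank_perm_p <- function(t1, t2, n_perm = 10000) {
  pool <- c(t1, t2)
  times <- sort(unique(pool))
  L <- length(times)
  mt <- match(pool, times)
  d_tot <- tabulate(mt, L)
  n1 <- length(t1)
  stat_from_d1 <- function(d1) {
    d2 <- d_tot - d1
    r1 <- rev(cumsum(rev(d1)))
    r2 <- rev(cumsum(rev(d2)))
    r <- r1 + r2
    num <- sum(d1 - d_tot * r1 / r)
    vt <- ifelse(r > 1,
                 d_tot * (r1 / r) * (r2 / r) * (r - d_tot) / (r - 1), 0)
    num^2 / sum(vt)
  }
  obs <- stat_from_d1(tabulate(mt[seq_len(n1)], L))
  hits <- 0
  for (i in seq_len(n_perm)) {
    idx <- sample.int(length(pool), n1)
    if (stat_from_d1(tabulate(mt[idx], L)) >= obs) hits <- hits + 1
  }
  (hits + 1) / (n_perm + 1)
}

# day count between two calendar dates by explicit month-length
# arithmetic (proleptic Gregorian leap rule), independent of Date
oracle_day_count <- function(y1, m1, d1, y2, m2, d2) {
  is_leap <- function(y) (y %% 4 == 0 & y %% 100 != 0) | y %% 400 == 0
  mlen <- function(y, m) {
    base <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)[m]
    if (m == 2 && is_leap(y)) 29 else base
  }
  serial <- function(y, m, d) {
    total <- 0
    for (yy in 2000:(y - 1)) total <- total + if (is_leap(yy)) 366 else 365
    if (m > 1) for (mm in 1:(m - 1)) total <- total + mlen(y, mm)
    total + d
  }
  serial(y2, m2, d2) - serial(y1, m1, d1)
}
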