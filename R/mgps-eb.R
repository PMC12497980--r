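# Full empirical-Bayes gamma-Poisson shrinker across a panel of tables.
#
# Observed counts a_i ~ Poisson(lambda_i * E_i) with E_i the
# independence-expected count (a+b)(a+c)/N; the relative reporting rates
# lambda_i get a 5-parameter two-component gamma mixture prior
#   lambda ~ w Gamma(alpha1, beta1) + (1-w) Gamma(alpha2, beta2)
# fitted by maximizing the marginal likelihood (a mixture of negative
# binomials). The posterior per table is again a gamma mixture; EBGM is
# its geometric mean exp(E[log lambda]) and EB05 its 5th percentile.

# negative log marginal likelihood of the observed counts
.mgps_nll <- function(par, a, E) {
  alpha1 <- exp(par[1]); beta1 <- exp(par[2])
  alpha2 <- exp(par[3]); beta2 <- exp(par[4])
  w <- stats::plogis(par[5])
  p1 <- beta1 / (beta1 + E)
  p2 <- beta2 / (beta2 + E)
  l1 <- stats::dnbinom(a, size = alpha1, prob = p1, log = TRUE)
  l2 <- stats::dnbinom(a, size = alpha2, prob = p2, log = TRUE)
  m <- pmax(l1, l2)
  -sum(m + log(w * exp(l1 - m) + (1 - w) * exp(l2 - m)))
}

#' Fit the empirical-Bayes gamma-Poisson shrinker
#'
#' Fits the two-component gamma mixture prior over a panel of drug-event
#' tables and returns shrunk EBGM and EB05 per table. Counts with little
#' information are pulled toward the prior (shrunk EBGM below the raw
#' observed/expected ratio for small counts); for large counts the
#' shrinkage vanishes and EBGM approaches the raw ratio.
#'
#' @param a integer vector of observed a-cell counts (one per table).
#' @param E numeric vector of expected counts under independence,
#'   (a+b)(a+c)/N per table.
#' @param start starting values `c(alpha1, beta1, alpha2, beta2, w)`;
#'   the default is the customary diffuse-plus-null mixture.
#' @return list with `ebgm`, `eb05` (vectors), `prior` (fitted
#'   parameters), `converged`, `loglik`. On optimizer failure,
#'   `converged` is `FALSE` and `ebgm`/`eb05` fall back to the raw-ratio
#'   statistics of [mgps()] (with `E` in place of the margin product),
#'   with diagnostics in `message`.
#' @export
fit_mgps_eb <- function(a, E, start = c(0.2, 0.1, 2, 4, 1 / 3)) {
  stopifnot(length(a) == length(E), all(E > 0), all(a >= 0))
  if (length(a) < 50)
    warning("fewer than 50 tables; prior fit may be unstable")
  par0 <- c(log(start[1:4]), stats::qlogis(start[5]))
  fit <- tryCatch(
    stats::optim(par0, .mgps_nll, a = a, E = E, method = "BFGS",
                 control = list(maxit = 500)),
    error = function(e) e
  )
  raw <- a / E
  if (inherits(fit, "error") || fit$convergence != 0) {
    msg <- if (inherits(fit, "error")) conditionMessage(fit) else
      paste("optim convergence code", fit$convergence)
    return(list(ebgm = raw,
                eb05 = exp(log(raw) - 1.645 / sqrt(pmax(a, 1))),
                prior = NULL, converged = FALSE, loglik = NA_real_,
                message = msg))
  }
  p <- fit$par
  alpha1 <- exp(p[1]); beta1 <- exp(p[2])
  alpha2 <- exp(p[3]); beta2 <- exp(p[4])
  w <- stats::plogis(p[5])
  # posterior mixture weights
  l1 <- stats::dnbinom(a, size = alpha1, prob = beta1 / (beta1 + E),
                       log = TRUE) + log(w)
  l2 <- stats::dnbinom(a, size = alpha2, prob = beta2 / (beta2 + E),
                       log = TRUE) + log(1 - w)
  m <- pmax(l1, l2)
  q1 <- exp(l1 - m) / (exp(l1 - m) + exp(l2 - m))
  s1 <- alpha1 + a; r1 <- beta1 + E
  s2 <- alpha2 + a; r2 <- beta2 + E
  elog <- q1 * (digamma(s1) - log(r1)) + (1 - q1) * (digamma(s2) - log(r2))
  ebgm <- exp(elog)
  eb05 <- vapply(seq_along(a), function(i) {
    cdf <- function(x) q1[i] * pgamma(x, s1[i], r1[i]) +
      (1 - q1[i]) * pgamma(x, s2[i], r2[i]) - 0.05
    hi <- max(raw[i] + 1, 1)
    while (cdf(hi) < 0) hi <- hi * 2
    stats::uniroot(cdf, c(0, hi), tol = 1e-8)$root
  }, 0)
  list(ebgm = ebgm, eb05 = eb05,
       prior = c(alpha1 = alpha1, beta1 = beta1, alpha2 = alpha2,
                 beta2 = beta2, w = w),
       converged = TRUE, loglik = -fit$value)
}

#' Expected counts for a panel of tables
#'
#' Convenience helper: E = (a+b)(a+c)/N per table, the independence
#' expectation used by the gamma-Poisson shrinker.
#'
#' @param a,b,c,d cell count vectors.
#' @return numeric vector of expected a-cell counts.
#' @export
expected_count <- function(a, b, c, d) {
  n <- a + b + c + d
  (a + b) * (a + c) / n
}
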