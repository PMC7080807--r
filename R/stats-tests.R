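## Statistical primitives for differential splicing: Fisher's exact test
## for the unreplicated two-sample design, a beta-binomial likelihood-ratio
## test for replicated designs (stand-in for Dirichlet-multinomial tools),
## and a Mann-Whitney U with exact enumeration at small n.

#' Two-sided Fisher's exact test on a 2x2 inclusion/exclusion table
#'
#' Raw counts, no pseudocount. A table with a zero margin carries no
#' information and returns p = 1.
#'
#' @param inc_a,exc_a,inc_b,exc_b inclusion/exclusion counts for the two
#'   samples.
#' @return two-sided p-value.
#' @export
fisher_test <- function(inc_a, exc_a, inc_b, exc_b) {
  tab <- matrix(c(inc_a, exc_a, inc_b, exc_b), nrow = 2L)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(1.0)
  stats::fisher.test(tab, alternative = "two.sided")$p.value
}

#' Mann-Whitney U test with midrank ties
#'
#' The U statistic for `a` uses midranks. The two-sided p-value is exact by
#' enumeration of all group assignments when `length(a) + length(b) <=
#' exact_max`, otherwise a normal approximation with tie correction and
#' continuity correction is used.
#'
#' @param a,b numeric samples.
#' @param exact_max exact/approximate crossover (default 12 combined).
#' @return list `U`, `p`.
#' @export
mann_whitney_u <- function(a, b, exact_max = 12L) {
  na <- length(a); nb <- length(b)
  stopifnot(na > 0L, nb > 0L)
  pooled <- c(a, b)
  r <- rank(pooled)
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  n <- na + nb
  if (n <= exact_max) {
    combos <- combn(n, na)
    Us <- apply(combos, 2L, function(ix) sum(r[ix]) - na * (na + 1) / 2)
    eps <- 1e-9
    p_lo <- mean(Us <= U + eps)
    p_hi <- mean(Us >= U - eps)
    p <- min(1, 2 * min(p_lo, p_hi))
  } else {
    mu <- na * nb / 2
    ties <- table(pooled)
    sig2 <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sig2 <= 0) return(list(U = U, p = 1.0))
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sig2)
    p <- min(1, 2 * pnorm(-abs(z)))
  }
  list(U = U, p = p)
}

## Beta-binomial log-likelihood; mu in (0,1), theta > 0 the precision
## (alpha = mu*theta, beta = (1-mu)*theta).
bb_loglik <- function(k, n, mu, theta) {
  a <- mu * theta; b <- (1 - mu) * theta
  sum(lchoose(n, k) + lbeta(k + a, n - k + b) - lbeta(a, b))
}

## Maximize the beta-binomial likelihood over (mu, theta) for one group,
## or over per-condition mu with shared theta; returns fitted values and
## log-likelihood. Optimization on (logit mu, log theta) with BFGS from a
## method-of-moments start; relative tolerance 1e-10.
## Bounds keep the optimizer off the degenerate binomial limit
## (theta -> Inf) where the log-likelihood surface is flat and lbeta
## loses precision.
BB_THETA_MAX <- 1e6
bb_fit_null <- function(k, n) {
  p0 <- min(max(sum(k) / sum(n), 1e-3), 1 - 1e-3)
  fn <- function(par) {
    mu <- stats::plogis(par[1L]); th <- exp(par[2L])
    -bb_loglik(k, n, mu, th)
  }
  lower <- c(stats::qlogis(1e-5), log(1e-2))
  upper <- c(stats::qlogis(1 - 1e-5), log(BB_THETA_MAX))
  best <- NULL
  for (lt0 in c(log(10), log(100), log(1000))) {
    o <- try(optim(c(stats::qlogis(p0), lt0), fn, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(factr = 1e3, maxit = 500L)),
             silent = TRUE)
    if (inherits(o, "try-error") || !is.finite(o$value)) next
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best)) return(NULL)
  list(mu = stats::plogis(best$par[1L]), theta = exp(best$par[2L]),
       loglik = -best$value)
}

bb_fit_alt <- function(k, n, grp, theta) {
  ll <- 0
  mus <- numeric(0)
  for (g in unique(grp)) {
    kk <- k[grp == g]; nn <- n[grp == g]
    o <- try(optimize(function(mu) -bb_loglik(kk, nn, mu, theta),
                      interval = c(1e-6, 1 - 1e-6), tol = 1e-10),
             silent = TRUE)
    if (inherits(o, "try-error")) return(NULL)
    ll <- ll - o$objective
    mus <- c(mus, o$minimum)
  }
  list(mu = mus, loglik = ll)
}

#' Beta-binomial likelihood-ratio test for differential inclusion
#'
#' Null model: one beta-binomial inclusion proportion shared across
#' conditions; alternative: per-condition proportions with the dispersion
#' fixed at its null estimate. The statistic 2*(llA - ll0) is referred to
#' a chi-squared distribution with 1 df. A pseudocount is added to each of
#' the inclusion and exclusion counts.
#'
#' @param inc,exc per-sample inclusion and exclusion counts.
#' @param condition per-sample condition labels (exactly 2 levels, >= 2
#'   samples each).
#' @param pseudocount added to inc and exc (default 1).
#' @return list `p`, `stat`, `mu_null`, `mu_alt`, `theta`; `p` is `NA` on
#'   non-convergence (with a warning).
#' @export
bb_lrt <- function(inc, exc, condition, pseudocount = 1) {
  stopifnot(length(inc) == length(exc), length(inc) == length(condition))
  lev <- unique(condition)
  if (length(lev) != 2L || any(table(condition) < 2L))
    stop("bb_lrt needs two conditions with >= 2 samples each")
  k <- inc + pseudocount
  n <- inc + exc + 2 * pseudocount
  null <- bb_fit_null(k, n)
  if (is.null(null)) { warning("beta-binomial null fit failed");
    return(list(p = NA_real_, stat = NA_real_)) }
  alt <- bb_fit_alt(k, n, condition, null$theta)
  if (is.null(alt)) { warning("beta-binomial alternative fit failed")
    return(list(p = NA_real_, stat = NA_real_)) }
  stat <- max(0, 2 * (alt$loglik - null$loglik))
  list(p = pchisq(stat, df = 1L, lower.tail = FALSE), stat = stat,
       mu_null = null$mu, mu_alt = alt$mu, theta = null$theta)
}

#' Benjamini-Hochberg correction and significance flags for event tests
#'
#' BH is applied within each event type separately. An event is
#' significant when its corrected p is below `alpha`, its |dPSI| exceeds
#' `dpsi_min` percentage points, and it is not exempt from testing.
#'
#' @param tests data.table with `event_id`, `type`, `raw_p`, `dpsi` and
#'   optionally `exempt`.
#' @param alpha corrected-p threshold (default 0.1).
#' @param dpsi_min |dPSI| threshold in percentage points (default 10).
#' @return the table with `corrected_p` and `significant` added.
#' @export
correct_and_flag <- function(tests, alpha = 0.1, dpsi_min = 10) {
  out <- copy(tests)
  if (!"exempt" %in% names(out)) out[, exempt := FALSE]
  out[, corrected_p := NA_real_]
  out[!is.na(raw_p) & !exempt,
      corrected_p := p.adjust(raw_p, method = "BH"), by = type]
  out[, significant := !is.na(corrected_p) & corrected_p < alpha &
        abs(dpsi) > dpsi_min & !exempt]
  out[]
}
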