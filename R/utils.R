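# Shared numerical helpers: truncated-normal moment matching, the
# univariate slice sampler used inside the Gibbs sweep, and log-sum-exp.

#' Moments of a truncated normal distribution
#'
#' Mean and SD of N(mu, sigma^2) truncated to [lower, upper].
#' @param mu,sigma Parent normal parameters.
#' @param lower,upper Truncation bounds.
#' @return Named numeric vector \code{c(mean, sd)}.
#' @keywords internal
truncnorm_moments <- function(mu, sigma, lower, upper) {
  a <- (lower - mu) / sigma
  b <- (upper - mu) / sigma
  Z <- stats::pnorm(b) - stats::pnorm(a)
  da <- stats::dnorm(a); db <- stats::dnorm(b)
  m <- mu + sigma * (da - db) / Z
  v <- sigma^2 * (1 + (a * da - b * db) / Z - ((da - db) / Z)^2)
  c(mean = m, sd = sqrt(pmax(v, 0)))
}

#' Moment-match a truncated normal to target moments
#'
#' Finds parent parameters (mu, sigma) such that N(mu, sigma^2) truncated
#' to [lower, upper] has the requested mean and SD. Solved by
#' Nelder--Mead on the squared moment error; the printed cohort moments
#' are well inside the feasible region so the fit is essentially exact.
#'
#' @param target_mean,target_sd Desired post-truncation moments.
#' @param lower,upper Truncation bounds.
#' @return List with \code{mu}, \code{sigma}, \code{lower}, \code{upper}
#'   and the achieved moments.
#' @export
match_truncnorm <- function(target_mean, target_sd, lower, upper) {
  stopifnot(target_mean > lower, target_mean < upper, target_sd > 0)
  obj <- function(p) {
    m <- truncnorm_moments(p[1], exp(p[2]), lower, upper)
    (m[1] - target_mean)^2 + (m[2] - target_sd)^2
  }
  fit <- stats::optim(c(target_mean, log(target_sd)), obj,
                      method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  mu <- fit$par[1]; sigma <- exp(fit$par[2])
  ach <- truncnorm_moments(mu, sigma, lower, upper)
  list(mu = mu, sigma = sigma, lower = lower, upper = upper,
       achieved_mean = unname(ach[1]), achieved_sd = unname(ach[2]))
}

#' Sample from a moment-matched truncated normal
#' @param n Number of draws.
#' @param tn Result of \code{\link{match_truncnorm}}.
#' @return Numeric vector of length \code{n} inside the bounds.
#' @keywords internal
rtruncnorm_matched <- function(n, tn) {
  pa <- stats::pnorm(tn$lower, tn$mu, tn$sigma)
  pb <- stats::pnorm(tn$upper, tn$mu, tn$sigma)
  u <- stats::runif(n, pa, pb)
  q <- stats::qnorm(u, tn$mu, tn$sigma)
  pmin(pmax(q, tn$lower), tn$upper)
}

# Univariate slice sampler (stepping out + shrinkage, Neal 2003).
# logf must be a vectorisable-in-spirit scalar log density; x0 a point
# with finite logf. Used for the residual and smoothness scales whose
# full conditionals are non-conjugate under half-t / half-normal priors.
slice_sample1 <- function(x0, logf, w = 1, max_steps = 50) {
  y <- logf(x0) - stats::rexp(1)
  L <- x0 - stats::runif(1) * w
  R <- L + w
  j <- floor(stats::runif(1) * max_steps)
  k <- max_steps - 1 - j
  while (j > 0 && logf(L) > y) { L <- L - w; j <- j - 1 }
  while (k > 0 && logf(R) > y) { R <- R + w; k <- k - 1 }
  repeat {
    x1 <- stats::runif(1, L, R)
    if (logf(x1) > y) return(x1)
    if (x1 < x0) L <- x1 else R <- x1
    if (R - L < 1e-12) return(x0)
  }
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Map years of education to an ISCED 0--6 level
#'
#' A documented convention (the cohort data carry both fields): 0--1
#' years of schooling maps to early-childhood (0), then primary (<= 6),
#' lower secondary (<= 9), upper secondary (<= 12), post-secondary
#' (<= 14), short-cycle tertiary (<= 16), bachelor-or-above (> 16).
#' @param edu_years Numeric years of education.
#' @return Integer ISCED levels, 0--6.
#' @export
isced_from_years <- function(edu_years) {
  breaks <- c(-Inf, 1, 6, 9, 12, 14, 16, Inf)
  as.integer(cut(edu_years, breaks = breaks, labels = FALSE)) - 1L
}
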