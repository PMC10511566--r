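# Bayesian fitting of the normative models.
#
# The models are Gaussian regressions (on the log scale for the timed
# trail-making tests) with flat improper priors on the parametric
# coefficients, a wide normal prior on the intercept centered at the
# response median, a half-Student-t(3) prior on the residual SD scaled
# to the response SD, and a half-normal prior on the SD of each
# penalized-spline coefficient block (second-order random-walk
# smoothness prior). Posterior sampling is a blocked Gibbs sweep: the
# full coefficient vector is jointly conjugate-normal given the scales,
# and the residual and smoothness scales are updated by univariate
# slice sampling of their log. Multiple chains are run from dispersed
# starts for split-R-hat convergence checking.

#' MCMC configuration
#'
#' The study profile runs four chains of 2000 iterations with the first
#' 1000 discarded as warm-up, retaining 4000 posterior draws. The desk
#' profile (the package default for tests and examples) halves this to
#' two chains of 1000 with 500 warm-up.
#'
#' @param profile \code{"desk"} or \code{"paper"}; sets the defaults
#'   below, each overridable.
#' @param chains,iterations,warmup Chain count, total iterations per
#'   chain, warm-up iterations discarded per chain.
#' @param seed Integer seed.
#' @return List of class \code{"mcmc_config"}.
#' @export
mcmc_config <- function(profile = c("desk", "paper"),
                        chains = NULL, iterations = NULL, warmup = NULL,
                        seed = 1L) {
  profile <- match.arg(profile)
  def <- if (profile == "paper") c(4L, 2000L, 1000L) else c(2L, 1000L, 500L)
  chains <- if (is.null(chains)) def[1] else as.integer(chains)
  iterations <- if (is.null(iterations)) def[2] else as.integer(iterations)
  warmup <- if (is.null(warmup)) def[3] else as.integer(warmup)
  stopifnot(chains >= 1, warmup >= 0, warmup < iterations)
  structure(list(profile = profile, chains = chains,
                 iterations = iterations, warmup = warmup,
                 seed = as.integer(seed)),
            class = "mcmc_config")
}

#' Fit a Bayesian normative model
#'
#' Rows missing the test's score are dropped (test-wise deletion);
#' trail-making times are log-transformed before fitting and must be
#' strictly positive. Language levels with fewer than
#' \code{min_per_language} observations trigger a warning, mirroring
#' the caution applied to sparsely represented languages.
#'
#' @param spec A \code{\link{model_spec}}.
#' @param cohort Filtered cohort table carrying the score column.
#' @param mcmc A \code{\link{mcmc_config}}.
#' @param min_per_language Warning threshold for language cell size.
#' @return A \code{"normative_fit"}: posterior draw matrix
#'   (\code{$draws}, columns = coefficients, \code{sigma}, smoothness
#'   scales), \code{$chain_id}, pointwise log-likelihood matrix
#'   (\code{$loglik}, draws x observations), the frozen design, and
#'   training summaries.
#' @export
fit_normative_model <- function(spec, cohort, mcmc = mcmc_config(),
                                min_per_language = 50) {
  tspec <- test_spec(spec$test_id)
  col <- tolower(spec$test_id)
  if (!col %in% names(cohort))
    stop("cohort has no score column '", col, "'")
  need <- c("age", "edu_years", "sex", "lang")
  data <- cohort[!is.na(cohort[[col]]),
                 c(intersect(need, names(cohort)), col)]
  if (nrow(data) == 0) stop("no non-missing observations for ",
                            spec$test_id)
  raw <- data[[col]]
  if (tspec$transform == "log" && any(raw <= 0))
    stop("non-positive raw score for log-transformed test ",
         spec$test_id)
  y <- transform_raw(tspec, raw)
  if ("language" %in% spec$predictors) {
    tab <- table(data$lang)
    small <- names(tab)[tab < min_per_language]
    if (length(small))
      warning("language level(s) with fewer than ", min_per_language,
              " observations: ", paste(small, collapse = ", "))
  }
  design <- build_design(spec, data)
  X <- design$X
  n <- nrow(X); p <- ncol(X)
  XtX <- crossprod(X)
  Xty <- drop(crossprod(X, y))

  # priors
  sd_y <- stats::sd(y); if (!is.finite(sd_y) || sd_y == 0) sd_y <- 1
  prior_mean <- numeric(p)
  prior_prec <- numeric(p)
  prior_mean[1] <- stats::median(y)
  prior_prec[1] <- 1 / (10 * sd_y)^2   # wide normal on the intercept
  sigma_scale <- sd_y                  # half-t(3) scale for sigma
  tau_scale <- 2 * sd_y                # half-normal scale for smooths
  pens <- design$penalties

  n_keep <- mcmc$iterations - mcmc$warmup
  par_names <- c(colnames(X), "sigma",
                 if (length(pens)) paste0("tau_", names(pens)))
  draws <- matrix(NA_real_, n_keep * mcmc$chains, length(par_names),
                  dimnames = list(NULL, par_names))
  loglik <- matrix(NA_real_, n_keep * mcmc$chains, n)
  chain_id <- rep(seq_len(mcmc$chains), each = n_keep)

  log_post_sigma <- function(ls, SSR) {
    s <- exp(ls)
    -n * ls - SSR / (2 * s^2) +
      stats::dt(s / sigma_scale, df = 3, log = TRUE) + ls
  }

  rhs_of <- function(sigma) Xty / sigma^2 + prior_prec * prior_mean
  prec_of <- function(sigma, tau) {
    P <- diag(prior_prec, p)
    for (j in names(pens))
      P[pens[[j]]$cols, pens[[j]]$cols] <-
        P[pens[[j]]$cols, pens[[j]]$cols] + pens[[j]]$S / tau[j]^2
    XtX / sigma^2 + P
  }
  # log marginal of (sigma, tau) with all coefficients integrated out,
  # up to terms not involving tau: used for collapsed tau updates so
  # the smoothness scales mix without the centered-funnel stickiness
  log_marg_tau <- function(tau, sigma) {
    A <- prec_of(sigma, tau)
    R <- chol(A)
    quad <- sum(forwardsolve(t(R), rhs_of(sigma))^2)
    -sum(vapply(names(pens),
                function(j) pens[[j]]$rank * log(tau[j]), 0)) -
      sum(log(diag(R))) + quad / 2 +
      sum(stats::dnorm(tau, 0, tau_scale, log = TRUE)) + sum(log(tau))
  }

  set.seed(mcmc$seed)
  row0 <- 0L
  for (ch in seq_len(mcmc$chains)) {
    # dispersed but sane starts
    sigma <- sd_y * exp(stats::rnorm(1, 0, 0.3))
    tau <- stats::setNames(rep(sd_y, length(pens)), names(pens)) *
      exp(stats::rnorm(length(pens), 0, 0.3))
    for (it in seq_len(mcmc$iterations)) {
      # 1. smoothness scales, coefficients collapsed out
      for (j in names(pens)) {
        lt <- slice_sample1(log(tau[j]), function(v) {
          tt <- tau; tt[j] <- exp(v)
          log_marg_tau(tt, sigma)
        }, w = 1)
        tau[j] <- exp(lt)
      }
      # 2. joint coefficient draw
      A <- prec_of(sigma, tau)
      R <- chol(A)
      mu_beta <- backsolve(R, forwardsolve(t(R), rhs_of(sigma)))
      beta <- mu_beta + backsolve(R, stats::rnorm(p))
      resid <- y - drop(X %*% beta)
      SSR <- sum(resid^2)
      # 3. residual scale
      ls <- slice_sample1(log(sigma),
                          function(v) log_post_sigma(v, SSR), w = 0.5)
      sigma <- exp(ls)
      if (it > mcmc$warmup) {
        row0 <- row0 + 1L
        draws[row0, ] <- c(beta, sigma, tau)
        loglik[row0, ] <- stats::dnorm(y, y - resid, sigma, log = TRUE)
      }
    }
  }

  structure(list(
    spec = spec, test = tspec, design = design,
    draws = draws, chain_id = chain_id, loglik = loglik,
    y = y, n = n, p = p, mcmc = mcmc,
    coef_cols = seq_len(p),
    data_summary = list(n = n, sd_y = sd_y,
                        median_y = stats::median(y),
                        lang_counts = if ("lang" %in% names(data))
                          table(data$lang) else NULL)
  ), class = "normative_fit")
}

#' @export
print.normative_fit <- function(x, ...) {
  cat(sprintf("Bayesian %s normative model for %s\n", x$spec$form,
              x$spec$test_id))
  cat(sprintf("  predictors: %s\n",
              paste(x$spec$predictors, collapse = ", ")))
  cat(sprintf("  n = %d, %d retained draws (%d chains)\n", x$n,
              nrow(x$draws), max(x$chain_id)))
  invisible(x)
}

#' Posterior draws of the linear predictor at new data
#' @keywords internal
linpred_draws <- function(fit, newdata) {
  Xn <- design_matrix(fit$design, newdata)
  Xn %*% t(fit$draws[, fit$coef_cols, drop = FALSE])
}

#' Posterior predictive summary at new covariate values
#'
#' The predictive mean is the posterior mean of the linear predictor;
#' the predictive SD combines posterior coefficient uncertainty with
#' the residual noise, \eqn{\sqrt{Var(\mu) + E(\sigma^2)}}. The 95
#' percent predictive interval uses the normal approximation around
#' these two moments. Values are on the model scale (log seconds for
#' trail making). Rows outside the training age/education range are
#' flagged as extrapolation.
#'
#' @param fit A \code{"normative_fit"}.
#' @param newdata Data.frame of demographics.
#' @param chunk Evaluation block size (memory control for large grids).
#' @return Data.frame with \code{mu_hat}, \code{sd_pred}, \code{lwr},
#'   \code{upr}, \code{extrapolation}.
#' @export
posterior_predict <- function(fit, newdata, chunk = 2000L) {
  n <- nrow(newdata)
  mu_hat <- sd_pred <- numeric(n)
  mean_sig2 <- mean(fit$draws[, "sigma"]^2)
  idx <- split(seq_len(n), ceiling(seq_len(n) / chunk))
  for (ii in idx) {
    M <- linpred_draws(fit, newdata[ii, , drop = FALSE])
    m1 <- rowMeans(M)
    v <- rowMeans(M^2) - m1^2
    mu_hat[ii] <- m1
    sd_pred[ii] <- sqrt(pmax(v, 0) + mean_sig2)
  }
  q <- stats::qnorm(0.975)
  data.frame(mu_hat = mu_hat, sd_pred = sd_pred,
             lwr = mu_hat - q * sd_pred, upr = mu_hat + q * sd_pred,
             extrapolation = is_extrapolation(fit$design, newdata))
}

#' Posterior predictive check
#'
#' Draws replicated datasets from the posterior predictive (one
#' posterior draw per replicate, fresh Gaussian noise) and reports the
#' Kolmogorov--Smirnov distance between each replicate's empirical
#' distribution and the observed one.
#'
#' @param fit A \code{"normative_fit"}.
#' @param n_rep Number of replicated datasets.
#' @param seed Integer seed.
#' @return List with \code{ks} (one distance per replicate) and
#'   \code{mean_ks}.
#' @export
posterior_predictive_check <- function(fit, n_rep = 20, seed = 1L) {
  set.seed(seed)
  S <- nrow(fit$draws)
  X <- fit$design$X
  ks <- numeric(n_rep)
  y_sorted <- sort(fit$y)
  n <- fit$n
  for (r in seq_len(n_rep)) {
    s <- sample.int(S, 1)
    beta <- fit$draws[s, fit$coef_cols]
    sigma <- fit$draws[s, "sigma"]
    y_rep <- drop(X %*% beta) + stats::rnorm(n, 0, sigma)
    # two-sample KS statistic, computed directly
    all_v <- sort(c(y_sorted, y_rep))
    F1 <- stats::approxfun(y_sorted, seq_len(n) / n, method = "constant",
                           yleft = 0, yright = 1, f = 0)
    F2 <- stats::approxfun(sort(y_rep), seq_len(n) / n,
                           method = "constant", yleft = 0, yright = 1,
                           f = 0)
    ks[r] <- max(abs(F1(all_v) - F2(all_v)))
  }
  list(ks = ks, mean_ks = mean(ks))
}

#' Split-R-hat convergence diagnostics
#'
#' Each chain is split in half and the classical potential scale
#' reduction factor is computed over the resulting 2x chains for every
#' stored parameter. The fit passes when the largest R-hat is below
#' 1.01 (the Gibbs sweep has no divergence mechanism, so the divergence
#' count is structurally zero).
#'
#' @param fit A \code{"normative_fit"} (at least two chains).
#' @return List of class \code{"convergence_diag"} with \code{rhat}
#'   (named vector), \code{max_rhat}, \code{divergences}, \code{pass}.
#' @export
check_convergence <- function(fit) {
  if (max(fit$chain_id) < 2)
    stop("split-R-hat needs at least two chains")
  rhat <- apply(fit$draws, 2, function(x)
    split_rhat(matrix(x, ncol = max(fit$chain_id))))
  mx <- max(rhat)
  structure(list(rhat = rhat, max_rhat = mx, divergences = 0L,
                 pass = is.finite(mx) && mx < 1.01),
            class = "convergence_diag")
}

#' Split-R-hat for a draws matrix (iterations x chains)
#'
#' @param x Numeric matrix, one column per chain.
#' @return The split potential scale reduction factor.
#' @export
split_rhat <- function(x) {
  n <- nrow(x)
  half <- floor(n / 2)
  # split each chain into halves
  xs <- cbind(x[seq_len(half), , drop = FALSE],
              x[seq.int(n - half + 1, n), , drop = FALSE])
  m <- ncol(xs); nn <- nrow(xs)
  means <- colMeans(xs)
  vars <- apply(xs, 2, stats::var)
  W <- mean(vars)
  B <- nn * stats::var(means)
  if (W == 0) return(if (B == 0) 1 else Inf)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}
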