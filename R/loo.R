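# Pareto-smoothed importance-sampling leave-one-out cross-validation
# (PSIS-LOO) and the CI-based model-comparison rule used to select the
# normative model per test.
#
# For observation i, the importance ratios are 1/p(y_i | theta_s). The
# largest ratios are replaced by expected order statistics of a
# generalized Pareto distribution fitted to the tail (Zhang-Stephens
# profile-likelihood estimator with the weakly informative shape
# adjustment), the per-observation reliability diagnostic k-hat is the
# fitted shape, and the smoothed weights give elpd_loo pointwise.
# LOO-IC = -2 * elpd_loo.

# Zhang & Stephens (2009) generalized Pareto fit to exceedances x > 0.
# Returns shape k (heavy tail for k > 0) and scale sigma.
gpd_fit <- function(x, wip = TRUE) {
  x <- sort(x)
  N <- length(x)
  if (N < 5 || x[N] <= 0) return(list(k = Inf, sigma = NA_real_))
  prior_b <- 3
  M <- 30 + floor(sqrt(N))
  jj <- seq_len(M)
  xstar <- x[max(1, floor(N / 4 + 0.5))]
  theta <- 1 / x[N] + (1 - sqrt(M / (jj - 0.5))) / prior_b / xstar
  k_of <- function(t) mean(log1p(-t * x))
  l_theta <- vapply(theta, function(t) {
    k <- k_of(t)
    N * (log(-t / k) - k - 1)
  }, 0)
  w <- exp(l_theta - logsumexp(l_theta))
  theta_hat <- sum(theta * w)
  k <- k_of(theta_hat)
  sigma <- -k / theta_hat
  if (wip) k <- (k * N + 0.5 * 10) / (N + 10)
  list(k = k, sigma = sigma)
}

# GPD quantile function (location 0)
gpd_quantile <- function(p, k, sigma) {
  if (abs(k) < 1e-12) -sigma * log1p(-p)
  else sigma / k * ((1 - p)^(-k) - 1)
}

# Smooth one vector of log importance ratios; returns the smoothed,
# self-normalized-ready log weights (capped at 0 after max-shift) and
# the Pareto k-hat.
psis_smooth <- function(lr) {
  S <- length(lr)
  lw <- lr - max(lr)
  tail_len <- ceiling(min(0.2 * S, 3 * sqrt(S)))
  if (tail_len < 5) return(list(lw = lw, k = -Inf))
  ord <- order(lw)
  tail_idx <- ord[seq.int(S - tail_len + 1, S)]
  cutoff <- lw[ord[S - tail_len]]
  exceed <- exp(lw[tail_idx]) - exp(cutoff)
  if (length(unique(exceed)) < 5 || max(exceed) <= 0)
    return(list(lw = lw, k = -Inf))
  fit <- gpd_fit(exceed)
  if (!is.finite(fit$k)) return(list(lw = lw, k = Inf))
  ranks <- rank(lw[tail_idx], ties.method = "first")
  qq <- gpd_quantile((ranks - 0.5) / tail_len, fit$k, fit$sigma)
  lw[tail_idx] <- log(qq + exp(cutoff))
  lw <- pmin(lw, 0)
  list(lw = lw, k = fit$k)
}

#' PSIS-LOO expected log predictive density
#'
#' @param fit A \code{"normative_fit"} carrying the pointwise
#'   log-likelihood matrix, or such a matrix directly (draws x
#'   observations).
#' @param k_threshold Observations with Pareto k-hat at or above this
#'   are counted as influential (reported, not refit).
#' @return A \code{"loo_result"}: \code{elpd}, \code{se},
#'   \code{loo_ic = -2 elpd}, \code{se_loo_ic}, \code{pointwise}
#'   (data.frame with \code{elpd_i}, \code{pareto_k}), \code{n},
#'   \code{n_high_k}.
#' @export
compute_loo <- function(fit, k_threshold = 0.5) {
  ll <- if (inherits(fit, "normative_fit")) fit$loglik else fit
  if (!all(is.finite(ll))) stop("non-finite log-likelihood entries")
  n <- ncol(ll)
  elpd_i <- numeric(n)
  k_i <- numeric(n)
  for (i in seq_len(n)) {
    sm <- psis_smooth(-ll[, i])
    lw <- sm$lw - logsumexp(sm$lw)
    elpd_i[i] <- logsumexp(lw + ll[, i])
    k_i[i] <- sm$k
  }
  elpd <- sum(elpd_i)
  se <- sqrt(n * stats::var(elpd_i))
  structure(list(elpd = elpd, se = se,
                 loo_ic = -2 * elpd, se_loo_ic = 2 * se,
                 pointwise = data.frame(elpd_i = elpd_i,
                                        pareto_k = k_i),
                 n = n,
                 n_high_k = sum(is.finite(k_i) & k_i >= k_threshold)),
            class = "loo_result")
}

#' @export
print.loo_result <- function(x, ...) {
  cat(sprintf("PSIS-LOO: elpd = %.2f (SE %.2f), LOO-IC = %.2f (SE %.2f), n = %d\n",
              x$elpd, x$se, x$loo_ic, x$se_loo_ic, x$n))
  cat(sprintf("  Pareto k-hat >= 0.5: %d observation(s)\n", x$n_high_k))
  invisible(x)
}

#' Compare two models by their paired LOO-IC difference
#'
#' The difference of pointwise elpd contributions is paired by
#' observation; its mean and standard error give the LOO-IC difference
#' (a - b) with a normal 95 percent CI (mean +/- 1.96 SE). A difference
#' is significant when the CI excludes zero.
#'
#' @param a,b \code{"loo_result"}s over the same observations.
#' @return A \code{"loo_comparison"} with \code{delta_loo_ic},
#'   \code{se_diff}, \code{ci95}, \code{significant}.
#' @export
compare_loo <- function(a, b) {
  if (a$n != b$n)
    stop("models were evaluated on different numbers of observations")
  d <- a$pointwise$elpd_i - b$pointwise$elpd_i
  delta_elpd <- sum(d)
  se_elpd <- sqrt(a$n * stats::var(d))
  delta <- -2 * delta_elpd
  se <- 2 * se_elpd
  ci <- delta + c(-1, 1) * 1.96 * se
  structure(list(delta_loo_ic = delta, se_diff = se, ci95 = ci,
                 significant = ci[1] > 0 || ci[2] < 0),
            class = "loo_comparison")
}

#' Fit and rank the drop-one-predictor model ladder for one test
#'
#' Fits both model forms (linear and additive) with all four predictors
#' and with each predictor dropped in turn (ten fits), computes
#' PSIS-LOO for each, and compares every model with the one of smallest
#' LOO-IC. The selected model is the most parsimonious among those
#' whose LOO-IC difference to the best is not significant: fewest
#' predictors first, then the linear form before the additive one, then
#' smaller LOO-IC.
#'
#' @param cohort Filtered cohort table.
#' @param test_id Battery test id.
#' @param mcmc A \code{\link{mcmc_config}}.
#' @param k Spline basis size for the additive fits.
#' @param keep_fits Keep the ten fitted models in the result (memory!).
#' @return A \code{"selection_ladder"}: \code{table} (one row per
#'   model: form, dropped predictor, LOO-IC, SE, difference to best,
#'   significance), \code{selected} (the chosen \code{model_spec}),
#'   and optionally \code{fits}.
#' @export
run_selection_ladder <- function(cohort, test_id,
                                 mcmc = mcmc_config(), k = 8,
                                 keep_fits = FALSE) {
  all_pred <- c("age", "education", "gender", "language")
  ladder <- c(list(full = all_pred),
              stats::setNames(lapply(all_pred, setdiff, x = all_pred),
                              paste0("minus_", all_pred)))
  rows <- list(); fits <- list(); loos <- list()
  for (form in c("LMR", "GAM")) {
    for (nm in names(ladder)) {
      preds <- ladder[[nm]]
      if (form == "GAM" && !any(c("age", "education") %in% preds)) next
      spec <- model_spec(test_id, form = form, predictors = preds,
                         k = k)
      fit <- fit_normative_model(spec, cohort, mcmc = mcmc)
      loo <- compute_loo(fit)
      key <- paste(form, nm, sep = ".")
      loos[[key]] <- loo
      if (keep_fits) fits[[key]] <- fit
      rows[[key]] <- data.frame(
        model = key, form = form, dropped = sub("minus_", "", nm),
        n_predictors = length(preds),
        elpd = loo$elpd, loo_ic = loo$loo_ic, se = loo$se_loo_ic,
        max_pareto_k = max(c(-Inf, loo$pointwise$pareto_k[
          is.finite(loo$pointwise$pareto_k)])),
        n_high_k = loo$n_high_k)
    }
  }
  tab <- do.call(rbind, c(rows, make.row.names = FALSE))
  tab$dropped[tab$dropped == "full"] <- "none"
  best <- which.min(tab$loo_ic)
  delta <- se_d <- sig <- numeric(nrow(tab))
  for (i in seq_len(nrow(tab))) {
    cmp <- compare_loo(loos[[tab$model[i]]], loos[[tab$model[best]]])
    delta[i] <- cmp$delta_loo_ic
    se_d[i] <- cmp$se_diff
    sig[i] <- cmp$significant
  }
  tab$delta_vs_best <- delta
  tab$se_delta <- se_d
  tab$worse_than_best <- as.logical(sig)
  # parsimony tie-break among models statistically tied with the best
  cand <- which(!tab$worse_than_best)
  ord <- order(tab$n_predictors[cand],
               match(tab$form[cand], c("LMR", "GAM")),
               tab$loo_ic[cand])
  sel <- cand[ord[1]]
  selected <- model_spec(test_id, form = tab$form[sel],
                         predictors = ladder[[sub("^(LMR|GAM)\\.", "",
                                                  tab$model[sel])]],
                         k = k)
  structure(list(table = tab, selected = selected,
                 selected_model = tab$model[sel],
                 loos = loos,
                 fits = if (keep_fits) fits else NULL),
            class = "selection_ladder")
}
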