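# Bayesian model fitting: draw bookkeeping, agreement with the OLS
# closed form under flat priors, scale recovery, predictive contracts,
# convergence diagnostics.

test_that("the study MCMC profile retains exactly 4000 draws", {
  co <- make_cohort(150, list(default_truth("SDMT")),
                    demo_seed = 81, score_seed = 82)
  fit <- suppressWarnings(fit_normative_model(
    model_spec("SDMT", form = "LMR", predictors = c("age", "gender")),
    co, mcmc_config("paper", seed = 83)))
  expect_equal(nrow(fit$draws), 4000)
  expect_equal(max(fit$chain_id), 4)
  expect_equal(nrow(fit$loglik), 4000)
  expect_true(all(is.finite(fit$loglik)))
})

test_that("posterior means under flat priors match the OLS closed form", {
  co <- make_cohort(500, list(default_truth("SDMT")),
                    demo_seed = 84, score_seed = 85)
  spec <- model_spec("SDMT", form = "LMR",
                     predictors = c("age", "education", "gender"))
  fit <- fit_normative_model(spec, co,
                             mcmc_config(chains = 2, iterations = 2000,
                                         warmup = 500, seed = 86))
  ols <- stats::lm.fit(fit$design$X, fit$y)
  pm <- colMeans(fit$draws[, seq_len(fit$p)])
  # agreement within Monte-Carlo error of the posterior means
  mc_se <- apply(fit$draws[, seq_len(fit$p)], 2, sd) / sqrt(300)
  expect_true(all(abs(pm - ols$coefficients) < 3 * mc_se))
  # residual SD close to the OLS sigma-hat
  s_ols <- sqrt(sum(ols$residuals^2) / (500 - fit$p))
  expect_equal(mean(fit$draws[, "sigma"]), s_ols, tolerance = 0.03)
})

test_that("the residual SD is recovered from planted noise", {
  co <- make_cohort(1000, list(default_truth("SDMT", sigma = 5)),
                    demo_seed = 87, score_seed = 88)
  fit <- suppressWarnings(fit_normative_model(
    model_spec("SDMT", form = "GAM"), co, mcmc_quick(89)))
  expect_gt(mean(fit$draws[, "sigma"]), 4.5)
  expect_lt(mean(fit$draws[, "sigma"]), 5.5)
})

test_that("the fitted age smooth recovers the planted curve", {
  fit <- shared_sdmt_fit()
  grid <- data.frame(age = 18:86, edu_years = 14, sex = "m",
                     lang = "EN")
  mu_hat <- posterior_predict(fit, grid)$mu_hat
  truth <- default_truth("SDMT")
  mu_true <- true_mean(truth, grid)
  ctr <- function(x) x - mean(x)
  expect_gt(cor(ctr(mu_hat), ctr(mu_true)), 0.95)
})

test_that("posterior credible intervals cover planted gender/language effects", {
  # 20 replicate fits at modest n; nominal 95% coverage, demand >= 90%
  truth <- default_truth("SDMT")
  cover_g <- cover_l <- logical(20)
  for (r in 1:20) {
    co <- make_cohort(1200, list(truth), demo_seed = 900 + r,
                      score_seed = 950 + r)
    fit <- suppressWarnings(fit_normative_model(
      model_spec("SDMT", form = "LMR"), co, mcmc_quick(1000 + r)))
    hg <- hdi(fit$draws[, "genderf"])
    hl <- hdi(fit$draws[, "langDE"])
    cover_g[r] <- hg[1] <= 2.78 && 2.78 <= hg[2]
    cover_l[r] <- hl[1] <= -2.86 && -2.86 <= hl[2]
  }
  expect_gte(mean(cover_g), 0.9)
  expect_gte(mean(cover_l), 0.9)
})

test_that("predictive SD dominates the residual SD and intervals calibrate", {
  fit <- shared_sdmt_fit()
  grid <- expand.grid(age = c(20, 48, 80), edu_years = c(5, 14, 22),
                      sex = c("f", "m"), lang = c("EN", "PL"),
                      stringsAsFactors = FALSE)
  pp <- posterior_predict(fit, grid)
  expect_true(all(pp$sd_pred >= mean(fit$draws[, "sigma"])))
  expect_true(all(pp$upr > pp$lwr))

  # fresh data fall in the 95% predictive interval about 95% of the time
  co_new <- make_cohort(2000, list(default_truth("SDMT")),
                        demo_seed = 91, score_seed = 92)
  ppn <- posterior_predict(fit, co_new)
  cov <- mean(co_new$sdmt >= ppn$lwr & co_new$sdmt <= ppn$upr)
  expect_gt(cov, 0.93)
  expect_lt(cov, 0.97)
})

test_that("extrapolation beyond the training range is flagged", {
  fit <- shared_sdmt_fit()
  inside <- data.frame(age = 50, edu_years = 14, sex = "f",
                       lang = "EN")
  outside <- transform(inside, age = 101)
  expect_false(posterior_predict(fit, inside)$extrapolation)
  expect_true(posterior_predict(fit, outside)$extrapolation)
})

test_that("trail-making responses are fitted on the log scale", {
  fit <- shared_tmta_fit()
  expect_equal(fit$test$transform, "log")
  # the fitted response values are log seconds, so all far below 240
  expect_true(all(fit$y < log(241)))
  co_bad <- make_cohort(30, list(default_truth("TMTA")),
                        demo_seed = 93, score_seed = 94)
  co_bad$tmta[1] <- 0
  expect_error(
    suppressWarnings(fit_normative_model(
      model_spec("TMTA", predictors = c("age", "education")), co_bad,
      mcmc_quick())),
    "non-positive")
})

test_that("posterior predictive checks separate right from wrong models", {
  # strongly nonlinear truth: the additive fit replicates the data
  # better than the linear fit in most paired replicates
  truth <- default_truth("SDMT", age_slope = -0.5, age_quad = -1.5)
  co <- make_cohort(800, list(truth), demo_seed = 95, score_seed = 96)
  gam <- suppressWarnings(fit_normative_model(
    model_spec("SDMT", "GAM", predictors = c("age", "gender")), co,
    mcmc_quick(97)))
  lmr <- suppressWarnings(fit_normative_model(
    model_spec("SDMT", "LMR", predictors = c("age", "gender")), co,
    mcmc_quick(97)))
  g <- posterior_predictive_check(gam, n_rep = 20, seed = 98)
  l <- posterior_predictive_check(lmr, n_rep = 20, seed = 98)
  expect_equal(length(g$ks), 20)
  expect_lt(g$mean_ks, l$mean_ks)
})

test_that("split R-hat flags non-mixing chains and matches the formula", {
  fit <- shared_sdmt_fit()
  diag <- check_convergence(fit)
  expect_lt(diag$max_rhat, 1.01)
  expect_true(diag$pass)
  expect_identical(diag$divergences, 0L)

  # two chains stuck at different constants: R-hat blows up
  stuck <- cbind(rep(0, 100), rep(5, 100))
  expect_gt(split_rhat(stuck), 100)

  # direct-formula oracle on random draw arrays
  set.seed(99)
  for (r in 1:5) {
    x <- matrix(rnorm(400, mean = rep(c(0, 0.3), each = 200)),
                ncol = 2)
    expect_equal(split_rhat(x), brute_split_rhat(x), tolerance = 1e-12)
  }

  single <- fit
  single$chain_id <- rep(1L, nrow(fit$draws))
  expect_error(check_convergence(single), "two chains")
})
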