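# Shared fixtures, memoized so expensive fits are built once per run.

.fixture_env <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# small synthetic cohort with scores for the given truths
make_cohort <- function(n, truths, demo_seed = 1, score_seed = 2,
                        config = cohort_config()) {
  d <- sample_demographics(config, n, seed = demo_seed)
  sample_scores(d, truths, seed = score_seed)
}

# quick MCMC profile for tests that only need a working posterior
mcmc_quick <- function(seed = 1) {
  mcmc_config(chains = 2, iterations = 600, warmup = 300, seed = seed)
}

# a moderately sized full additive SDMT fit shared across test files
shared_sdmt_fit <- function() {
  cached("sdmt_fit", {
    co <- make_cohort(2500, list(default_truth("SDMT")),
                      demo_seed = 101, score_seed = 102)
    suppressWarnings(fit_normative_model(
      model_spec("SDMT", form = "GAM"), co,
      mcmc_config(chains = 2, iterations = 1600, warmup = 500,
                  seed = 103)))
  })
}

shared_sdmt_cohort <- function() {
  # the training data behind shared_sdmt_fit()
  cached("sdmt_cohort", make_cohort(2500, list(default_truth("SDMT")),
                                    demo_seed = 101, score_seed = 102))
}

# a small trail-making fit for sign/transform contracts
shared_tmta_fit <- function() {
  cached("tmta_fit", {
    co <- make_cohort(800, list(default_truth("TMTA")),
                      demo_seed = 111, score_seed = 112)
    suppressWarnings(fit_normative_model(
      model_spec("TMTA", form = "GAM",
                 predictors = c("age", "education", "gender")),
      co, mcmc_quick(113)))
  })
}

# independent oracle: exact leave-one-out by n refits
exact_refit_loo <- function(spec, cohort, mcmc, test_col) {
  n <- nrow(cohort)
  vapply(seq_len(n), function(i) {
    f <- suppressWarnings(fit_normative_model(spec, cohort[-i, ], mcmc))
    mu <- drop(design_matrix(f$design, cohort[i, , drop = FALSE]) %*%
                 t(f$draws[, seq_len(f$p), drop = FALSE]))
    yi <- transform_raw(f$test, cohort[[test_col]][i])
    log(mean(stats::dnorm(yi, mu, f$draws[, "sigma"])))
  }, numeric(1))
}

# independent oracle: split R-hat spelled out step by step
brute_split_rhat <- function(x) {
  n <- nrow(x)
  half <- floor(n / 2)
  halves <- list()
  for (c_ in seq_len(ncol(x))) {
    halves[[length(halves) + 1]] <- x[1:half, c_]
    halves[[length(halves) + 1]] <- x[(n - half + 1):n, c_]
  }
  m <- length(halves)
  nn <- half
  chain_means <- vapply(halves, mean, 0)
  chain_vars <- vapply(halves, stats::var, 0)
  W <- sum(chain_vars) / m
  B <- nn / (m - 1) * sum((chain_means - mean(chain_means))^2)
  var_plus <- (nn - 1) / nn * W + B / nn
  sqrt(var_plus / W)
}

# independent oracle: HDI by exhaustive scan over contiguous windows
brute_hdi <- function(draws, level) {
  x <- sort(draws)
  n <- length(x)
  m <- ceiling(level * n)
  best <- c(-Inf, Inf)
  for (i in 1:(n - m + 1)) {
    if (x[i + m - 1] - x[i] < best[2] - best[1])
      best <- c(x[i], x[i + m - 1])
  }
  best
}

# hand-enumerated screening toy: one violation per row plus one clean row
toy_screen_cohort <- function() {
  data.frame(
    subjid = sprintf("T%02d", 1:8),
    visit = c(2L, 1L, 1L, 1L, 1L, 1L, 1L, 1L),
    age = rep(50, 8), edu_years = c(12, 12, 12, NA, 12, 12, 12, 12),
    isced = rep(3L, 8),
    sex = rep("f", 8),
    lang = c("EN", "EN", "EN", "EN", NA, "EN", "EN", "EN"),
    hand = rep("r", 8),
    native_lang = c(TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE),
    vh_corrected = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE),
    hads = c(5, 5, 5, 5, 5, 11, 5, 5),
    mmse = c(30, 30, 30, 30, 30, 30, 26, 30),
    stringsAsFactors = FALSE
  )
}
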