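# Synthetic cohort generator: demographic marginals, generative score
# model, ground-truth z oracle, screening-violation injection.

test_that("sampling is reproducible and matches configured marginals", {
  cfg <- cohort_config()
  a <- sample_demographics(cfg, 3267, seed = 42)
  b <- sample_demographics(cfg, 3267, seed = 42)
  expect_identical(a, b)

  # moment-matched truncated normals hit the configured targets
  mc_se_age <- 14.61 / sqrt(3267)
  mc_se_edu <- 3.27 / sqrt(3267)
  expect_lt(abs(mean(a$age) - 46.99), 3 * mc_se_age)
  expect_lt(abs(mean(a$edu_years) - 14.66), 3 * mc_se_edu + 0.05)
  expect_lt(abs(sd(a$age) - 14.61), 3 * mc_se_age)
  expect_lt(abs(mean(a$sex == "f") - 0.605),
            3 * sqrt(0.605 * 0.395 / 3267))
  expect_true(all(a$age >= 18 & a$age <= 86))
  expect_true(all(a$edu_years >= 1 & a$edu_years <= 24))
  expect_true(all(a$lang %in% norm_languages()))
})

test_that("empty and point-mass configurations degenerate correctly", {
  cfg <- cohort_config()
  expect_equal(nrow(sample_demographics(cfg, 0, seed = 1)), 0)

  cfg0 <- cohort_config(age_mean = 48, age_sd = 0, edu_mean = 14,
                        edu_sd = 0, p_female = 1,
                        lang_probs = c(EN = 1))
  d <- sample_demographics(cfg0, 20, seed = 1)
  expect_true(all(d$age == 48))
  expect_true(all(d$edu_years == 14))
  expect_true(all(d$sex == "f"))
  expect_true(all(d$lang == "EN"))

  expect_error(cohort_config(lang_probs = c(EN = 0.6, DE = 0.2)),
               "sum to 1")
})

test_that("the bundled generator config reproduces the in-code default", {
  path <- system.file("extdata", "table1_default.json",
                      package = "cognorm")
  cfg <- cohort_config_from_json(path)
  ref <- cohort_config()
  expect_equal(cfg$age$mu, ref$age$mu, tolerance = 1e-6)
  expect_equal(cfg$lang_probs, ref$lang_probs)
})

test_that("true_mean is the additive ground-truth with exact offsets", {
  # constant model: every offset and curve zero
  flat <- default_truth("SDMT", intercept = 50, age_slope = 0,
                        age_quad = 0, edu_gain = 0, beta_gender = 0,
                        beta_language = setNames(
                          rep(0, 10), norm_languages()))
  d <- data.frame(age = c(20, 55, 80), edu_years = c(2, 12, 22),
                  sex = c("f", "m", "f"), lang = c("EN", "PL", "DA"))
  expect_equal(true_mean(flat, d), rep(50, 3))

  # a planted language offset shifts the mean by exactly that offset
  truth <- default_truth("SWRT")
  d_en <- data.frame(age = 40, edu_years = 14, sex = "f", lang = "EN")
  d_pl <- transform(d_en, lang = "PL")
  expect_equal(true_mean(truth, d_pl) - true_mean(truth, d_en), -7.80)

  # configured monotone-decreasing age curve decreases on a fine grid
  grid <- data.frame(age = seq(18, 86, by = 0.25), edu_years = 14,
                     sex = "m", lang = "EN")
  mu <- true_mean(default_truth("SDMT"), grid)
  expect_true(all(diff(mu) < 0))

  expect_error(true_mean(truth, transform(d_en, lang = "XX")),
               "unknown language")
})

test_that("score simulation honors the noise model and logs clipping", {
  d <- sample_demographics(cohort_config(), 400, seed = 7)

  # zero noise reproduces the ground-truth mean exactly
  t0 <- default_truth("SDMT", sigma = 0)
  co <- sample_scores(d, list(t0), seed = 1)
  expect_equal(co$sdmt, true_mean(t0, d))
  t0l <- default_truth("TMTA", sigma = 0)
  col <- sample_scores(d, list(t0l), seed = 1)
  expect_equal(col$tmta, exp(true_mean(t0l, d)))

  # clip events are logged and rare under the default truth
  big <- sample_scores(sample_demographics(cohort_config(), 4000,
                                           seed = 8),
                       lapply(battery_tests(), default_truth),
                       seed = 9)
  clip <- attr(big, "clip_log")
  expect_s3_class(clip, "data.frame")
  expect_true(all((clip$n_clipped_low + clip$n_clipped_high) / 4000
                  < 0.01))
})

test_that("a planted gender effect appears in the sample means", {
  cfg <- cohort_config()
  d <- sample_demographics(cfg, 20000, seed = 3)
  co <- sample_scores(d, list(default_truth("SDMT")), seed = 4)
  diff_fm <- mean(co$sdmt[co$sex == "f"]) - mean(co$sdmt[co$sex == "m"])
  # planted female advantage of 2.78, Monte-Carlo error ~ 0.15
  expect_lt(abs(diff_fm - 2.78), 3 * 10 * sqrt(1 / 12100 + 1 / 7900))
})

test_that("trail-making scores are log-normal around the planted mean", {
  cfg0 <- cohort_config(age_mean = 48, age_sd = 0, edu_mean = 14,
                        edu_sd = 0, p_female = 0,
                        lang_probs = c(EN = 1))
  d <- sample_demographics(cfg0, 20000, seed = 5)
  truth <- default_truth("TMTA", sigma = 0.3)
  co <- sample_scores(d, list(truth), seed = 6)
  mu_log <- true_mean(truth, d[1, ])
  # median of a log-normal is exp of the log-scale mean
  expect_equal(median(co$tmta), exp(mu_log), tolerance = 0.02)
})

test_that("the ground-truth z oracle is calibrated and sign-correct", {
  truth <- default_truth("SDMT")
  d <- data.frame(age = 40, edu_years = 14, sex = "f", lang = "EN")
  mu <- true_mean(truth, d)
  expect_equal(true_zscore(truth, d, mu), 0)

  # hand-computed case: one SD above the mean is z = +1
  expect_equal(true_zscore(truth, d, mu + truth$sigma), 1)

  # a slower-than-expected trail-making time scores negative
  ttmt <- default_truth("TMTA")
  mu_t <- exp(true_mean(ttmt, d))
  expect_lt(true_zscore(ttmt, d, mu_t * 1.5), 0)
  expect_error(true_zscore(ttmt, d, -3), "positive")

  # fully written-out arithmetic on a fixed parameter set
  tr <- default_truth("SDMT", intercept = 45, age_slope = -1.2,
                      age_quad = -0.65, edu_gain = 12, edu_tau = 7,
                      beta_gender = 2.78, sigma = 10)
  d2 <- data.frame(age = 55, edu_years = 8, sex = "f", lang = "DE")
  mu_hand <- 45 - 1.2 * (55 - 18) / 10 - 0.65 * ((55 - 35) / 10)^2 +
    12 * (1 - exp(-(8 - 1) / 7)) + 2.78 - 2.86
  expect_equal(true_zscore(tr, d2, 52), (52 - mu_hand) / 10)
})

test_that("z-scores of freshly simulated scores are standard normal", {
  cfg <- cohort_config()
  d <- sample_demographics(cfg, 10000, seed = 21)
  for (tid in c("SDMT", "TMTA")) {
    truth <- default_truth(tid)
    co <- sample_scores(d, list(truth), seed = 22)
    z <- true_zscore(truth, co, co[[tolower(tid)]])
    expect_lt(abs(mean(z)), 0.04)
    expect_gt(sd(z), 0.97)
    expect_lt(sd(z), 1.03)
  }
})

test_that("language-shift identity holds exactly for planted offsets", {
  truth <- default_truth("SWRT")
  raws <- c(60, 77, 95)
  d_pl <- data.frame(age = 34, edu_years = 13, sex = "f", lang = "PL")
  d_en <- transform(d_pl, lang = "EN")
  delta <- truth$beta_language[["PL"]]
  expect_equal(true_zscore(truth, d_pl, raws),
               true_zscore(truth, d_en, raws - delta))
})

test_that("screening violations are planted at the requested rates", {
  d <- sample_demographics(cohort_config(), 500, seed = 31)
  same <- inject_screening_violations(d, list(), seed = 1)
  expect_equal(same$hads, d$hads)
  expect_equal(same$visit, d$visit)

  all_dep <- inject_screening_violations(d, list(hads = 1), seed = 1)
  expect_true(all(all_dep$hads > 10))

  # independent injections: survivors ~ product of survival rates
  big <- sample_demographics(cohort_config(), 20000, seed = 32)
  rates <- list(hads = 0.2, mmse = 0.1, non_native = 0.15)
  inj <- inject_screening_violations(big, rates, seed = 33)
  surv <- apply_filters(inj)$cohort
  expect_equal(nrow(surv) / 20000, 0.8 * 0.9 * 0.85, tolerance = 0.02)
})

test_that("the cohort CSV dialect round-trips", {
  d <- sample_demographics(cohort_config(), 50, seed = 41)
  co <- sample_scores(d, list(default_truth("SDMT")), seed = 42)
  co$sdmt[3] <- NA
  path <- tempfile(fileext = ".csv")
  write_cohort_csv(co, path)
  back <- read_cohort_csv(path)
  expect_equal(back$sdmt, co$sdmt)
  expect_equal(back$subjid, co$subjid)
  expect_true(is.na(back$sdmt[3]))
})
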