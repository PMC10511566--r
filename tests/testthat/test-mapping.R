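# Normative probability mapping: percentiles, bands, z-scores from the
# model and from the lookup table, calculator entry points.

test_that("percentile identities hold", {
  expect_equal(to_percentile(0), 50)
  expect_equal(to_percentile(-1.6449), 5.0, tolerance = 1e-3)
  expect_equal(to_percentile(0.64), 73.9, tolerance = 0.05)
  expect_equal(to_percentile(-1.24), 10.7, tolerance = 0.05)
  z <- seq(-3, 3, by = 0.25)
  expect_equal(to_percentile(z) + to_percentile(-z), rep(100, length(z)))
  expect_true(all(diff(to_percentile(z)) > 0))
})

test_that("qualitative bands follow the z thresholds, boundaries inclusive", {
  expect_equal(as.character(classify_band(c(-2.5, -1.24, 0, 0.64, 1.5))),
               c("markedly below (red)", "below (orange)",
                 "normal (green)", "normal (green)", "above (blue)"))
  # "normal" spans [-1, 1] inclusive
  expect_equal(as.character(classify_band(c(-1, 1))),
               rep("normal (green)", 2))
  expect_equal(as.character(classify_band(-2)), "below (orange)")
})

test_that("bands and percentiles never disagree", {
  z <- seq(-4, 4, by = 0.01)
  res <- data.frame(z = z, percentile = to_percentile(z),
                    band = classify_band(z))
  p_lo <- to_percentile(-1); p_hi <- to_percentile(1)
  in_normal <- res$percentile >= p_lo & res$percentile <= p_hi
  expect_equal(in_normal, res$band == "normal (green)")
})

test_that("a raw score at the predictive mean scores z = 0", {
  fit <- shared_sdmt_fit()
  d <- data.frame(age = 48, edu_years = 14, sex = "f", lang = "EN")
  mu <- posterior_predict(fit, d)$mu_hat
  res <- compute_z(fit, d, mu)
  expect_equal(res$z, 0, tolerance = 1e-10)
  expect_equal(res$percentile, 50)
  expect_equal(as.character(res$band), "normal (green)")
  expect_error(compute_z(fit, d, 1e6), "admissible range")
})

test_that("sign contracts: more time never helps, more points never hurt", {
  tmta <- shared_tmta_fit()
  d <- data.frame(age = 48, edu_years = 14, sex = "f", lang = "EN")
  times <- seq(15, 200, by = 5)
  z_t <- vapply(times, function(t)
    compute_z(tmta, d, t)$z, numeric(1))
  expect_true(all(diff(z_t) < 0))

  sdmt <- shared_sdmt_fit()
  raws <- seq(10, 90, by = 5)
  z_s <- vapply(raws, function(r)
    compute_z(sdmt, d, r)$z, numeric(1))
  expect_true(all(diff(z_s) > 0))
})

test_that("a fitted language offset shifts z like a raw-score shift", {
  fit <- shared_sdmt_fit()
  # the fitted Polish offset, read from the posterior
  delta <- mean(fit$draws[, "langPL"])
  d_pl <- data.frame(age = 34, edu_years = 13, sex = "f", lang = "PL")
  d_en <- transform(d_pl, lang = "EN")
  z_pl <- compute_z(fit, d_pl, 50)$z
  z_en_shifted <- compute_z(fit, d_en, 50 - delta)$z
  # same predictive SD up to coefficient uncertainty between cells
  expect_equal(z_pl, z_en_shifted, tolerance = 0.02)
})

test_that("the lookup grid is complete and matches the model at nodes", {
  fit <- shared_sdmt_fit()
  lookup <- cached("sdmt_lookup",
                   build_lookup(list(SDMT = fit)))
  n_lang <- length(fit$design$lang_levels)
  expect_equal(nrow(lookup), 69 * 24 * 2 * n_lang)
  expect_false(any(is.na(lookup$mu)))
  expect_false(any(is.na(lookup$sd)))

  d_node <- data.frame(age = 48, edu_years = 14, sex = "m",
                       lang = "DE")
  direct <- compute_z(fit, d_node, 47)
  via_table <- lookup_z(lookup, "SDMT", d_node, 47)
  expect_equal(via_table$z, direct$z, tolerance = 1e-8)

  # adjacent-age cells vary smoothly
  en_m <- lookup[lookup$sex == "m" & lookup$lang == "EN" &
                   lookup$edu_years == 14, ]
  en_m <- en_m[order(en_m$age), ]
  expect_lt(max(abs(diff(en_m$mu))), 2)
})

test_that("nearest-node lookup agrees with the model off the grid", {
  fit <- shared_sdmt_fit()
  lookup <- cached("sdmt_lookup", build_lookup(list(SDMT = fit)))
  set.seed(7)
  n <- 200
  # education is recorded in whole years (the calculator's input);
  # ages may fall between the one-year grid nodes
  audit <- data.frame(
    age = runif(n, 18, 86), edu_years = sample(1:24, n, TRUE),
    sex = sample(c("f", "m"), n, TRUE),
    lang = sample(fit$design$lang_levels, n, TRUE),
    stringsAsFactors = FALSE)
  raw <- runif(n, 20, 80)
  z_direct <- compute_z(fit, audit, raw)$z
  z_table <- lookup_z(lookup, "SDMT", audit, raw)$z
  expect_lt(mean(abs(z_table - z_direct)), 0.02)
  expect_lt(max(abs(z_table - z_direct)), 0.05)

  outside <- data.frame(age = 10, edu_years = 14, sex = "f",
                        lang = "EN")
  expect_error(lookup_z(lookup, "SDMT", outside, 50), "hull")
})

test_that("lookup tables round-trip through CSV with their grid spec", {
  fit <- shared_sdmt_fit()
  lookup <- cached("sdmt_lookup", build_lookup(list(SDMT = fit)))
  path <- tempfile(fileext = ".csv")
  write_lookup(lookup, path)
  back <- read_lookup(path)
  expect_equal(nrow(back), nrow(lookup))
  d <- data.frame(age = 60, edu_years = 10, sex = "f", lang = "EN")
  expect_equal(lookup_z(back, "SDMT", d, 40)$z,
               lookup_z(lookup, "SDMT", d, 40)$z, tolerance = 1e-6)
})

test_that("the calculator validates requests and always reports in full", {
  fit <- shared_sdmt_fit()
  lookup <- cached("sdmt_lookup", build_lookup(list(SDMT = fit)))
  res <- score_raw(lookup, "SDMT", age = 48, edu_years = 14,
                   sex = "f", lang = "EN", raw = 50)
  expect_named(res, c("test", "z", "percentile", "band",
                      "extrapolation"))
  expect_error(score_raw(lookup, "SDMT", 48, 14, "f", "XX", 50),
               "valid codes")
  expect_error(score_raw(lookup, "SDMT", 48, 14, "x", "EN", 50),
               "sex")

  reqs <- data.frame(test = "SDMT", age = c(30, 50, 70),
                     edu_years = 14, sex = "m", lang = "EN",
                     raw = c(60, 50, 40), stringsAsFactors = FALSE)
  batch <- score_batch(lookup, reqs)
  expect_equal(nrow(batch), 3)
  # order preserved: same request order, row-by-row equality
  expect_equal(batch$z[2],
               score_raw(lookup, "SDMT", 50, 14, "m", "EN", 50)$z)
})
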