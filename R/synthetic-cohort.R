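# Synthetic normative cohort generator.
#
# Emulates the demographic marginals of the normative sample (age and
# education from truncated normals moment-matched to the published
# mean/SD, gender as a Bernoulli draw, ten administration languages at
# the published frequencies) and a ground-truth generative model for the
# eight cognitive scores: additive nonlinear age decline, saturating
# education gain, gender and language offsets, Gaussian noise on the
# model scale (log-normal raw scores for the timed trail-making tests).

#' Generator configuration for the synthetic cohort
#'
#' Defaults reproduce the published demographic marginals of the
#' normative sample: age mean 46.99 (SD 14.61) on [18, 86], education
#' mean 14.66 (SD 3.27) on [1, 24], 60.5\% female, and the ten
#' administration-language frequencies. Age and education samplers are
#' truncated normals whose parent parameters are moment-matched so the
#' post-truncation moments equal the targets. A zero SD gives a point
#' mass at the mean.
#'
#' @param age_mean,age_sd,age_range Age target moments and bounds (years).
#' @param edu_mean,edu_sd,edu_range Education target moments and bounds.
#' @param p_female Probability of female gender.
#' @param lang_probs Named probability vector over
#'   \code{\link{norm_languages}}; must sum to 1 within 1e-6.
#' @param hand_probs Named probabilities for handedness
#'   \code{c(r, l, mixed)}.
#' @return A list of class \code{"cohort_config"}.
#' @export
cohort_config <- function(age_mean = 46.99, age_sd = 14.61,
                          age_range = c(18, 86),
                          edu_mean = 14.66, edu_sd = 3.27,
                          edu_range = c(1, 24),
                          p_female = 0.605,
                          lang_probs = c(EN = 0.553, DE = 0.196,
                                         ES = 0.092, IT = 0.073,
                                         PL = 0.030, FRCA = 0.021,
                                         FR = 0.006, NL = 0.014,
                                         ESLA = 0.009, DA = 0.006),
                          hand_probs = c(r = 0.898, l = 0.077,
                                         mixed = 0.025)) {
  if (abs(sum(lang_probs) - 1) > 1e-6)
    stop("language frequencies must sum to 1 (got ", sum(lang_probs), ")")
  if (is.null(names(lang_probs)) ||
      !all(names(lang_probs) %in% norm_languages()))
    stop("lang_probs must be named with codes from norm_languages()")
  if (abs(sum(hand_probs) - 1) > 1e-6)
    stop("handedness frequencies must sum to 1")
  stopifnot(p_female >= 0, p_female <= 1, age_sd >= 0, edu_sd >= 0)
  cfg <- list(
    age = if (age_sd > 0)
      match_truncnorm(age_mean, age_sd, age_range[1], age_range[2])
    else list(point = age_mean),
    edu = if (edu_sd > 0)
      match_truncnorm(edu_mean, edu_sd, edu_range[1], edu_range[2])
    else list(point = edu_mean),
    p_female = p_female,
    lang_probs = lang_probs,
    hand_probs = hand_probs,
    targets = list(age_mean = age_mean, age_sd = age_sd,
                   edu_mean = edu_mean, edu_sd = edu_sd)
  )
  structure(cfg, class = "cohort_config")
}

#' Load a generator configuration from JSON
#'
#' Reads a JSON document with fields matching the arguments of
#' \code{\link{cohort_config}}. The bundled Table-1-calibrated default
#' lives at \code{system.file("extdata", "table1_default.json",
#' package = "cognorm")}.
#' @param path Path to a JSON config.
#' @return A \code{cohort_config}.
#' @export
cohort_config_from_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  cohort_config(age_mean = j$age_mean, age_sd = j$age_sd,
                age_range = j$age_range,
                edu_mean = j$edu_mean, edu_sd = j$edu_sd,
                edu_range = j$edu_range,
                p_female = j$p_female,
                lang_probs = unlist(j$lang_probs),
                hand_probs = unlist(j$hand_probs))
}

#' Sample cohort demographics
#'
#' Draws \code{n} participant rows: age and education from the
#' moment-matched truncated normals, gender, language and handedness
#' from their categorical distributions, and compliant screening values
#' (HADS in 0--10, MMSE in 27--30, native-language and corrected
#' vision/hearing flags set). Screening violations are planted
#' separately by \code{\link{inject_screening_violations}}.
#'
#' @param config A \code{\link{cohort_config}}.
#' @param n Number of participants.
#' @param seed Integer seed; identical inputs give identical cohorts.
#' @return A data.frame with columns \code{subjid}, \code{visit},
#'   \code{age}, \code{edu_years}, \code{isced}, \code{sex} (f/m),
#'   \code{lang}, \code{hand}, \code{native_lang}, \code{vh_corrected},
#'   \code{hads}, \code{mmse}.
#' @export
sample_demographics <- function(config, n, seed = 1L) {
  stopifnot(inherits(config, "cohort_config"), n >= 0)
  set.seed(seed)
  draw_cont <- function(c_, n) {
    if (!is.null(c_$point)) rep(c_$point, n) else rtruncnorm_matched(n, c_)
  }
  age <- draw_cont(config$age, n)
  edu <- round(draw_cont(config$edu, n))
  # rounding education to whole years can step outside the bounds
  if (!is.null(config$edu$lower))
    edu <- pmin(pmax(edu, config$edu$lower), config$edu$upper)
  sex <- ifelse(stats::runif(n) < config$p_female, "f", "m")
  lang <- sample(names(config$lang_probs), n, replace = TRUE,
                 prob = config$lang_probs)
  hand <- sample(names(config$hand_probs), n, replace = TRUE,
                 prob = config$hand_probs)
  data.frame(
    subjid = sprintf("S%06d", seq_len(n)),
    visit = rep(1L, n),
    age = age,
    edu_years = edu,
    isced = isced_from_years(edu),
    sex = sex,
    lang = lang,
    hand = hand,
    native_lang = rep(TRUE, n),
    vh_corrected = rep(TRUE, n),
    hads = sample(0:10, n, replace = TRUE,
                  prob = stats::dpois(0:10, 3.5)),
    mmse = sample(27:30, n, replace = TRUE,
                  prob = c(0.05, 0.12, 0.33, 0.50)),
    stringsAsFactors = FALSE
  )
}

# ---------------------------------------------------------------------
# Ground-truth generative model

#' Ground-truth parameters for the synthetic score model
#'
#' Per test: an intercept at the reference cell (age 18, 1 year of
#' education, male, English), a signed nonlinear age curve (linear in
#' decades plus a quadratic-in-decades term switched on beyond age 35,
#' giving the accelerating late-life decline), a saturating education
#' curve (exponential approach to an asymptotic gain, so returns
#' diminish with increasing schooling), a gender offset (female minus
#' male) and additive language offsets relative to English. Timed
#' trail-making tests are parameterised on the natural-log scale; the
#' published ratio-scale gender effects and log-scale language offsets
#' are planted directly. Defaults plant the published posterior means
#' for the gender and language effects of all eight tests.
#'
#' @param test_id Battery test id.
#' @param ... Named overrides of any parameter field.
#' @return A list of class \code{"truth_params"} with fields
#'   \code{intercept}, \code{age_slope}, \code{age_quad},
#'   \code{edu_gain}, \code{edu_tau}, \code{beta_gender},
#'   \code{beta_language} (named, EN = 0), \code{sigma}.
#' @export
default_truth <- function(test_id, ...) {
  test_id <- match.arg(toupper(test_id), battery_tests())
  p <- .default_truth[[test_id]]
  dots <- list(...)
  for (nm in names(dots)) {
    if (!nm %in% names(p)) stop("unknown truth parameter: ", nm)
    p[[nm]] <- dots[[nm]]
  }
  if (is.null(p$beta_language["EN"]) || p$beta_language[["EN"]] != 0)
    stop("English reference offset must be 0")
  stopifnot(p$sigma >= 0)
  p$test_id <- test_id
  structure(p, class = "truth_params")
}

.lang_offsets <- function(DE, ES, FR, FRCA, NL, IT, ESLA, PL, DA) {
  c(EN = 0, DE = DE, ES = ES, IT = IT, PL = PL, FRCA = FRCA,
    FR = FR, NL = NL, ESLA = ESLA, DA = DA)
}

# Gender and language offsets are the published posterior means; age and
# education curve magnitudes are chosen to give realistic score ranges
# and the qualitative shape of the published predictive curves (steep,
# accelerating age decline for processing-speed tests, shallow for
# fluency; strongest education gain for letter fluency, weakest for
# Stroop interference). Residual SDs roughly reproduce the published
# marginal score SDs after adding demographic variance.
.default_truth <- list(
  SDMT = list(intercept = 45, age_slope = -1.2, age_quad = -0.65,
              edu_gain = 12, edu_tau = 7, beta_gender = 2.78,
              beta_language = .lang_offsets(-2.86, -2.14, 2.46, 0.39,
                                            -0.05, -6.29, -6.57, -6.00,
                                            0.82),
              sigma = 10),
  CFT = list(intercept = 19, age_slope = -0.35, age_quad = -0.10,
             edu_gain = 5, edu_tau = 7, beta_gender = 0.32,
             beta_language = .lang_offsets(0.94, 0.07, 1.04, -1.50,
                                           2.71, -0.88, -2.19, -0.17,
                                           3.00),
             sigma = 4.8),
  SCNT = list(intercept = 72, age_slope = -1.3, age_quad = -0.70,
              edu_gain = 10, edu_tau = 7, beta_gender = 0.94,
              beta_language = .lang_offsets(-3.03, -1.70, 7.97, 2.06,
                                            1.35, -4.19, -8.15, -7.02,
                                            -0.83),
              sigma = 12),
  SWRT = list(intercept = 91, age_slope = -1.4, age_quad = -0.80,
              edu_gain = 12, edu_tau = 7, beta_gender = 0.59,
              beta_language = .lang_offsets(2.95, 7.28, 6.97, 2.14,
                                            2.97, 1.64, -3.91, -7.80,
                                            -4.38),
              sigma = 15),
  SIT = list(intercept = 42, age_slope = -1.1, age_quad = -0.60,
             edu_gain = 6, edu_tau = 7, beta_gender = 0.50,
             beta_language = .lang_offsets(-1.87, 1.25, 2.62, -0.13,
                                           2.10, -1.66, -2.51, -4.78,
                                           0.26),
             sigma = 9.5),
  # trail-making truths live on the natural-log scale
  TMTA = list(intercept = 3.42, age_slope = 0.04, age_quad = 0.025,
              edu_gain = -0.25, edu_tau = 7, beta_gender = log(1.02),
              beta_language = .lang_offsets(0.05, 0.18, -0.05, -0.02,
                                            -0.10, 0.24, 0.41, 0.24,
                                            -0.12),
              sigma = 0.35),
  TMTB = list(intercept = 4.00, age_slope = 0.05, age_quad = 0.030,
              edu_gain = -0.30, edu_tau = 7, beta_gender = log(0.98),
              beta_language = .lang_offsets(0.05, 0.21, -0.09, -0.08,
                                            -0.11, 0.27, 0.44, 0.23,
                                            -0.01),
              sigma = 0.45),
  LFT = list(intercept = 31, age_slope = -0.30, age_quad = -0.10,
             edu_gain = 14, edu_tau = 7, beta_gender = 1.33,
             beta_language = .lang_offsets(-4.19, -2.46, 5.09, -0.29,
                                           -5.06, -2.49, -0.38, 1.21,
                                           3.01),
             sigma = 10)
)

truth_f_age <- function(truth, age) {
  truth$age_slope * (age - 18) / 10 +
    truth$age_quad * (pmax(age - 35, 0) / 10)^2
}

truth_f_edu <- function(truth, edu) {
  truth$edu_gain * (1 - exp(-(edu - 1) / truth$edu_tau))
}

#' Ground-truth expected score on the model scale
#'
#' The generative mean: intercept + age curve + education curve + gender
#' offset (female) + language offset. For trail-making tests the value
#' is on the natural-log scale; use \code{\link{back_transform}} with
#' the test spec to return to seconds.
#'
#' @param truth A \code{\link{default_truth}} parameter set.
#' @param demographics A data.frame with columns \code{age},
#'   \code{edu_years}, \code{sex}, \code{lang} (or a single-row list).
#' @return Numeric vector of expected scores, model scale.
#' @export
true_mean <- function(truth, demographics) {
  stopifnot(inherits(truth, "truth_params"))
  d <- as.data.frame(demographics)
  unknown <- setdiff(unique(d$lang), names(truth$beta_language))
  if (length(unknown))
    stop("unknown language code(s): ", paste(unknown, collapse = ", "))
  truth$intercept +
    truth_f_age(truth, d$age) +
    truth_f_edu(truth, d$edu_years) +
    truth$beta_gender * (d$sex == "f") +
    unname(truth$beta_language[d$lang])
}

#' Simulate raw cognitive scores for a cohort
#'
#' Identity-scale tests are drawn Gaussian around the ground-truth mean
#' and clipped to the admissible range; trail-making tests are drawn
#' Gaussian on the log scale and exponentiated (log-normal times).
#' Clipping events are counted and attached as the \code{"clip_log"}
#' attribute rather than silently discarded.
#'
#' @param cohort Demographics table from \code{\link{sample_demographics}}.
#' @param truths Named list of \code{truth_params}, one per test to
#'   simulate; defaults to all eight battery tests at default truth.
#' @param seed Integer seed.
#' @return The cohort with one lower-case score column per test and a
#'   \code{clip_log} attribute (data.frame test/n_clipped_low/high).
#' @export
sample_scores <- function(cohort,
                          truths = lapply(battery_tests(), default_truth),
                          seed = 1L) {
  if (is.null(names(truths)) || !all(nzchar(names(truths))))
    names(truths) <- vapply(truths, `[[`, "", "test_id")
  set.seed(seed)
  n <- nrow(cohort)
  clip <- list()
  for (tid in names(truths)) {
    spec <- test_spec(tid)
    truth <- truths[[tid]]
    mu <- true_mean(truth, cohort)
    y <- mu + if (truth$sigma > 0) stats::rnorm(n, 0, truth$sigma) else 0
    raw <- back_transform(spec, y)
    lo <- sum(raw < spec$range[1]); hi <- sum(raw > spec$range[2])
    raw <- pmin(pmax(raw, spec$range[1]), spec$range[2])
    clip[[tid]] <- data.frame(test = tid, n_clipped_low = lo,
                              n_clipped_high = hi)
    cohort[[tolower(tid)]] <- raw
  }
  attr(cohort, "clip_log") <- do.call(rbind, c(clip,
                                               make.row.names = FALSE))
  cohort
}

#' Ground-truth normative z-score (oracle)
#'
#' The z-score implied by the generative model itself: the transformed
#' raw score centered at the ground-truth mean, divided by the
#' ground-truth residual SD, and sign-flipped for tests where lower raw
#' scores are better. Freshly simulated scores pushed through this
#' oracle are standard normal by construction, which the calibration
#' tests exploit.
#'
#' @inheritParams true_mean
#' @param raw Raw score(s), one per demographics row (or recycled).
#' @return Numeric z-scores.
#' @export
true_zscore <- function(truth, demographics, raw) {
  spec <- test_spec(truth$test_id)
  if (spec$transform == "log" && any(raw <= 0))
    stop("raw score must be positive for ", truth$test_id)
  z <- (transform_raw(spec, raw) - true_mean(truth, demographics)) /
    truth$sigma
  if (spec$direction == "lower_better") -z else z
}

#' Plant screening violations in a cohort
#'
#' Randomly marks rows with screening failures so the filter chain has
#' known work to do: depression scores above the HADS cut-off, MMSE at
#' or below the impairment cut-off, non-native-language administration,
#' uncorrected vision/hearing, missing education, and follow-up (non-
#' baseline) visits. Each violation is drawn independently at its rate;
#' injected flags are recorded in \code{injected_*} columns so expected
#' attrition counts are computable.
#'
#' @param cohort A cohort table.
#' @param rates Named list/vector with any of \code{hads}, \code{mmse},
#'   \code{non_native}, \code{uncorrected_vh}, \code{missing_edu},
#'   \code{non_baseline}; values in [0, 1]. Missing keys default to 0.
#' @param seed Integer seed.
#' @return The cohort with violations applied and injection flags added.
#' @export
inject_screening_violations <- function(cohort, rates = list(), seed = 1L) {
  keys <- c("hads", "mmse", "non_native", "uncorrected_vh",
            "missing_edu", "non_baseline")
  r <- stats::setNames(rep(0, length(keys)), keys)
  r[names(rates)] <- unlist(rates)
  if (any(r < 0 | r > 1)) stop("violation rates must be in [0, 1]")
  set.seed(seed)
  n <- nrow(cohort)
  flag <- function(p) stats::runif(n) < p
  v_hads <- flag(r[["hads"]])
  v_mmse <- flag(r[["mmse"]])
  v_nat <- flag(r[["non_native"]])
  v_vh <- flag(r[["uncorrected_vh"]])
  v_edu <- flag(r[["missing_edu"]])
  v_bl <- flag(r[["non_baseline"]])
  cohort$hads[v_hads] <- sample(11:21, sum(v_hads), replace = TRUE)
  cohort$mmse[v_mmse] <- sample(20:26, sum(v_mmse), replace = TRUE)
  cohort$native_lang[v_nat] <- FALSE
  cohort$vh_corrected[v_vh] <- FALSE
  cohort$edu_years[v_edu] <- NA_real_
  cohort$isced[v_edu] <- NA_integer_
  cohort$visit[v_bl] <- 2L
  cohort$injected_hads <- v_hads
  cohort$injected_mmse <- v_mmse
  cohort$injected_non_native <- v_nat
  cohort$injected_uncorrected_vh <- v_vh
  cohort$injected_missing_edu <- v_edu
  cohort$injected_non_baseline <- v_bl
  cohort
}

#' Read/write the cohort CSV dialect
#'
#' Plain CSV, one row per participant-visit; missing values are empty
#' fields. Column order and names are fixed so files round-trip.
#' @param cohort Cohort data.frame.
#' @param path File path.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  na.strings = c("", "NA"))
}
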