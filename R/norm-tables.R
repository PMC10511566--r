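# Stratified mean/SD table norms and posterior effect summaries.

#' Age-group bins used by the table norms
#'
#' Ten bins: 18--24, then five-year bins, then 65 and above, coded as
#' left-closed right-open intervals.
#' @return Character vector of bin labels, in order.
#' @keywords internal
age_bins <- function() {
  c("[18,25)", "[25,30)", "[30,35)", "[35,40)", "[40,45)", "[45,50)",
    "[50,55)", "[55,60)", "[60,65)", "[65,86]")
}

.age_bin_of <- function(age) {
  breaks <- c(18, 25, 30, 35, 40, 45, 50, 55, 60, 65, 86.000001)
  cut(age, breaks = breaks, labels = age_bins(), right = FALSE,
      include.lowest = TRUE)
}

#' Stratified mean/SD table norms
#'
#' Cells are keyed by age group, education band (at most 12 vs more
#' than 12 years), gender and language; each holds the cell count,
#' sample mean and sample SD (n - 1 denominator; SD is NA when n < 2).
#'
#' @param cohort Filtered cohort with score columns.
#' @param tests Test ids to tabulate.
#' @param strata Character subset of \code{c("age_group", "edu_band",
#'   "sex", "lang")}; a zero-length value gives whole-sample rows.
#' @return Data.frame with one row per non-empty cell per test:
#'   stratifiers, \code{test}, \code{n}, \code{M}, \code{SD}.
#' @export
build_norm_table <- function(cohort, tests = battery_tests(),
                             strata = c("age_group", "edu_band", "sex",
                                        "lang")) {
  if (length(strata))
    strata <- match.arg(strata,
                        c("age_group", "edu_band", "sex", "lang"),
                        several.ok = TRUE)
  if (nrow(cohort) == 0)
    return(data.frame(test = character(), n = integer(),
                      M = numeric(), SD = numeric()))
  cohort$age_group <- as.character(.age_bin_of(cohort$age))
  cohort$edu_band <- ifelse(cohort$edu_years <= 12, "<=12", ">12")
  out <- list()
  for (tid in tests) {
    col <- tolower(tid)
    if (!col %in% names(cohort)) next
    d <- cohort[!is.na(cohort[[col]]), , drop = FALSE]
    g <- if (length(strata)) d[, strata, drop = FALSE]
         else data.frame(all = rep("all", nrow(d)))
    agg <- stats::aggregate(d[[col]], by = as.list(g), FUN = length)
    names(agg)[ncol(agg)] <- "n"
    agg$M <- stats::aggregate(d[[col]], by = as.list(g),
                              FUN = mean)$x
    agg$SD <- stats::aggregate(d[[col]], by = as.list(g), FUN =
      function(v) if (length(v) >= 2) stats::sd(v) else NA_real_)$x
    agg <- cbind(test = tid, agg)
    out[[tid]] <- agg
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Highest-density interval of a posterior sample
#'
#' The shortest contiguous interval of the sorted draws containing
#' \code{ceiling(level * n)} of them.
#'
#' @param draws Numeric vector of at least 100 posterior draws.
#' @param level Probability mass, in (0, 1).
#' @return Length-2 numeric \code{c(lower, upper)}.
#' @export
hdi <- function(draws, level = 0.95) {
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  n <- length(draws)
  if (n < 100) stop("need at least 100 draws for an HDI")
  x <- sort(draws)
  m <- ceiling(level * n)
  widths <- x[m:n] - x[1:(n - m + 1)]
  i <- which.min(widths)
  c(x[i], x[i + m - 1])
}

#' Posterior summary of the gender effect
#'
#' Posterior mean and 95 percent HDI of the female-minus-male
#' coefficient; positive values mean females score higher. For the
#' log-scale trail-making models the exponentiated draws are reported
#' (a multiplicative ratio of times; values above 1 mean longer, i.e.
#' worse, times for females).
#'
#' @param fit A \code{"normative_fit"} with gender among the
#'   predictors.
#' @param level HDI mass.
#' @return One-row data.frame: \code{test}, \code{effect}, \code{M},
#'   \code{hdi_lower}, \code{hdi_upper}, \code{scale}.
#' @export
summarize_gender_effect <- function(fit, level = 0.95) {
  if (!"gender" %in% fit$spec$predictors)
    stop("effect not in model: gender")
  d <- fit$draws[, "genderf"]
  ratio <- fit$test$transform == "log"
  if (ratio) d <- exp(d)
  h <- hdi(d, level)
  data.frame(test = fit$spec$test_id, effect = "gender (female - male)",
             M = mean(d), hdi_lower = h[1], hdi_upper = h[2],
             scale = if (ratio) "ratio" else "additive")
}

#' Posterior summaries of the language effects
#'
#' Per-language posterior mean and 95 percent HDI relative to the
#' reference (English); the reference row is structurally zero.
#' Trail-making effects are reported on the log scale (labelled).
#'
#' @param fit A \code{"normative_fit"} with language among the
#'   predictors.
#' @param level HDI mass.
#' @return Data.frame with one row per fitted language level.
#' @export
summarize_language_effects <- function(fit, level = 0.95) {
  if (!"language" %in% fit$spec$predictors)
    stop("effect not in model: language")
  levels <- fit$design$lang_levels
  ref <- levels[1]
  scale <- if (fit$test$transform == "log") "log" else "additive"
  rows <- list(data.frame(test = fit$spec$test_id, language = ref,
                          M = 0, hdi_lower = 0, hdi_upper = 0,
                          scale = scale))
  for (lv in levels[-1]) {
    d <- fit$draws[, paste0("lang", lv)]
    h <- hdi(d, level)
    rows[[lv]] <- data.frame(test = fit$spec$test_id, language = lv,
                             M = mean(d), hdi_lower = h[1],
                             hdi_upper = h[2], scale = scale)
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}
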