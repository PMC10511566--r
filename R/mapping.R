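# Normative probability mapping: raw score -> z-score, percentile and
# qualitative band, either directly from a fitted model or through a
# dense lookup table (the local analogue of the online calculator).

#' Percentile for a normative z-score
#'
#' 100 times the standard normal CDF; strictly increasing in z.
#' @param z Numeric z-scores.
#' @return Percentiles in (0, 100).
#' @export
to_percentile <- function(z) 100 * stats::pnorm(z)

#' Qualitative band for a normative z-score
#'
#' A score is "normal" when its z is within one SD of zero (boundaries
#' inclusive); bands below are "below" (z in [-2, -1)) and "markedly
#' below" (z < -2); above one SD is "above". Each band carries the
#' calculator's color code.
#' @param z Numeric z-scores.
#' @return Factor with levels "markedly below (red)", "below (orange)",
#'   "normal (green)", "above (blue)".
#' @export
classify_band <- function(z) {
  bands <- c("markedly below (red)", "below (orange)",
             "normal (green)", "above (blue)")
  idx <- ifelse(z < -2, 1L, ifelse(z < -1, 2L, ifelse(z <= 1, 3L, 4L)))
  factor(bands[idx], levels = bands)
}

.norm_score <- function(z, extrapolation = FALSE) {
  data.frame(z = z, percentile = to_percentile(z),
             band = classify_band(z),
             extrapolation = extrapolation)
}

#' Normative score from a fitted model
#'
#' z = (transformed raw - predictive mean) / predictive SD, sign-
#' flipped for tests where lower raw scores are better (the transform
#' is applied to the raw score first, then the flip). The predictive SD
#' integrates posterior coefficient uncertainty and residual noise.
#'
#' @param fit A \code{"normative_fit"} for the test.
#' @param demographics Data.frame of demographics (one row per score).
#' @param raw Raw score(s).
#' @return Data.frame with \code{z}, \code{percentile}, \code{band},
#'   \code{extrapolation}.
#' @export
compute_z <- function(fit, demographics, raw) {
  spec <- fit$test
  if (any(raw < spec$range[1] | raw > spec$range[2]))
    stop(sprintf("raw score outside admissible range [%g, %g] for %s",
                 spec$range[1], spec$range[2], spec$test_id))
  pp <- posterior_predict(fit, demographics)
  z <- (transform_raw(spec, raw) - pp$mu_hat) / pp$sd_pred
  if (spec$direction == "lower_better") z <- -z
  .norm_score(z, pp$extrapolation)
}

#' Build a dense lookup table for the normative calculator
#'
#' Evaluates the predictive mean and SD of each test's selected model
#' on the full grid of (age, education, gender, language) so that raw
#' scores can later be standardized without touching the posterior
#' draws.
#'
#' @param fits Named list of \code{"normative_fit"}s (names = test
#'   ids).
#' @param age_grid,edu_grid Numeric grid nodes (default: one-year steps
#'   over 18--86 and 1--24).
#' @param genders,languages Categorical axes. Languages default to the
#'   levels present in each fit.
#' @return A \code{"lookup_table"}: data.frame with the axes plus
#'   \code{test}, \code{mu}, \code{sd} (model scale), and a
#'   \code{grid_spec} attribute.
#' @export
build_lookup <- function(fits, age_grid = 18:86, edu_grid = 1:24,
                         genders = c("f", "m"), languages = NULL) {
  if (is.null(names(fits)) || !all(nzchar(names(fits))))
    stop("fits must be a named list keyed by test id")
  out <- list()
  for (tid in names(fits)) {
    fit <- fits[[tid]]
    langs <- languages
    if (is.null(langs))
      langs <- if (!is.null(fit$design$lang_levels))
        fit$design$lang_levels else "EN"
    grid <- expand.grid(age = age_grid, edu_years = edu_grid,
                        sex = genders, lang = langs,
                        KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
    pp <- posterior_predict(fit, grid)
    grid$test <- tid
    grid$mu <- pp$mu_hat
    grid$sd <- pp$sd_pred
    out[[tid]] <- grid
  }
  tab <- do.call(rbind, c(out, make.row.names = FALSE))
  structure(tab, class = c("lookup_table", "data.frame"),
            grid_spec = list(age_grid = age_grid, edu_grid = edu_grid,
                             genders = genders))
}

#' Normative score from a lookup table
#'
#' Age and education are rounded to the nearest grid node (documented
#' nearest-node semantics; with one-year steps the rounding error in z
#' is negligible), the cell's predictive mean/SD are read off, and the
#' same z formula as \code{\link{compute_z}} is applied.
#'
#' @param table A \code{"lookup_table"}.
#' @param test_id Battery test id.
#' @param demographics Data.frame with \code{age}, \code{edu_years},
#'   \code{sex}, \code{lang}.
#' @param raw Raw score(s).
#' @return Data.frame with \code{z}, \code{percentile}, \code{band}.
#' @export
lookup_z <- function(table, test_id, demographics, raw) {
  gs <- attr(table, "grid_spec")
  d <- as.data.frame(demographics)
  nearest <- function(x, grid)
    vapply(x, function(v) grid[which.min(abs(grid - v))], numeric(1))
  if (any(d$age < min(gs$age_grid) - 0.5 |
          d$age > max(gs$age_grid) + 0.5 |
          d$edu_years < min(gs$edu_grid) - 0.5 |
          d$edu_years > max(gs$edu_grid) + 0.5))
    stop(sprintf(
      "demographics outside the table hull (age %g-%g, education %g-%g)",
      min(gs$age_grid), max(gs$age_grid), min(gs$edu_grid),
      max(gs$edu_grid)))
  sub <- table[table$test == test_id, , drop = FALSE]
  if (nrow(sub) == 0) stop("no lookup cells for test ", test_id)
  key <- function(age, edu, sex, lang)
    paste(age, edu, sex, lang, sep = "|")
  cell_of <- stats::setNames(seq_len(nrow(sub)),
                             key(sub$age, sub$edu_years, sub$sex,
                                 sub$lang))
  idx <- cell_of[key(nearest(d$age, gs$age_grid),
                     nearest(d$edu_years, gs$edu_grid),
                     d$sex, d$lang)]
  if (any(is.na(idx)))
    stop("no lookup cell for the requested gender/language combination")
  spec <- test_spec(test_id)
  z <- (transform_raw(spec, raw) - sub$mu[idx]) / sub$sd[idx]
  if (spec$direction == "lower_better") z <- -z
  .norm_score(unname(z))
}

#' Persist / load a lookup table (CSV + JSON sidecar)
#' @param table A \code{"lookup_table"}.
#' @param path CSV path; the sidecar is written next to it as
#'   \code{<path>.json}.
#' @export
write_lookup <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  gs <- attr(table, "grid_spec")
  jsonlite::write_json(gs, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_lookup
#' @export
read_lookup <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  gs <- jsonlite::read_json(paste0(path, ".json"),
                            simplifyVector = TRUE)
  structure(tab, class = c("lookup_table", "data.frame"),
            grid_spec = gs)
}

#' Score a raw test result (calculator entry point)
#'
#' The local analogue of the online normative calculator: validates the
#' request, standardizes the raw score against the lookup table (or a
#' fitted model) and reports z, percentile and qualitative band
#' together.
#'
#' @param source A \code{"lookup_table"} or a \code{"normative_fit"}.
#' @param test_id Battery test id.
#' @param age,edu_years Numeric demographics.
#' @param sex \code{"f"} or \code{"m"}.
#' @param lang Language code.
#' @param raw Raw score.
#' @return One-row data.frame with \code{test}, \code{z},
#'   \code{percentile}, \code{band}.
#' @export
score_raw <- function(source, test_id, age, edu_years, sex, lang, raw) {
  if (!lang %in% norm_languages())
    stop("unknown language '", lang, "'; valid codes: ",
         paste(norm_languages(), collapse = ", "))
  if (!sex %in% c("f", "m")) stop("sex must be 'f' or 'm'")
  d <- data.frame(age = age, edu_years = edu_years, sex = sex,
                  lang = lang, stringsAsFactors = FALSE)
  res <- if (inherits(source, "lookup_table"))
    lookup_z(source, test_id, d, raw)
  else compute_z(source, d, raw)
  cbind(data.frame(test = toupper(test_id)), res)
}

#' @rdname score_raw
#' @param requests Data.frame with columns \code{test}, \code{age},
#'   \code{edu_years}, \code{sex}, \code{lang}, \code{raw}; one output
#'   row per request, order preserved.
#' @export
score_batch <- function(source, requests) {
  out <- lapply(seq_len(nrow(requests)), function(i) {
    r <- requests[i, ]
    score_raw(source, r$test, r$age, r$edu_years, r$sex, r$lang, r$raw)
  })
  do.call(rbind, c(out, make.row.names = FALSE))
}
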