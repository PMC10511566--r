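# Inclusion/exclusion screening chain for the normative cohort.
#
# The chain mirrors the study's selection narrative: keep the first
# baseline visit, require native-language administration with corrected
# vision/hearing, require education and language to be recorded, remove
# probable depression (HADS > 10) and possible cognitive impairment
# (MMSE <= 26). Removals are conjunctive, so the surviving set does not
# depend on the order; the per-step attrition report does.

#' Screening criteria for cohort selection
#'
#' @param baseline_only Keep only visit 1.
#' @param require_native_language Drop non-native administrations.
#' @param require_corrected_vision_hearing Drop uncorrected vision/hearing.
#' @param require_education_and_language_present Drop rows missing
#'   education years or language code.
#' @param hads_max Exclusive upper bound on HADS: scores strictly above
#'   are removed (default 10, so HADS = 10 is retained).
#' @param mmse_min_exclusive Scores at or below this MMSE value are
#'   removed (default 26, so MMSE = 27 is retained).
#' @param drop_missing_screen If TRUE, rows with missing HADS/MMSE are
#'   removed at the respective step; default FALSE (exclusion requires
#'   evidence of depression/impairment, not mere missingness).
#' @param order Evaluation order of the report steps.
#' @return A list of class \code{"filter_criteria"}.
#' @export
filter_criteria <- function(baseline_only = TRUE,
                            require_native_language = TRUE,
                            require_corrected_vision_hearing = TRUE,
                            require_education_and_language_present = TRUE,
                            hads_max = 10,
                            mmse_min_exclusive = 26,
                            drop_missing_screen = FALSE,
                            order = c("baseline", "native_language",
                                      "vision_hearing", "missing_fields",
                                      "hads", "mmse")) {
  stopifnot(hads_max >= 0, hads_max <= 21,
            mmse_min_exclusive >= 0, mmse_min_exclusive <= 30)
  structure(list(baseline_only = baseline_only,
                 require_native_language = require_native_language,
                 require_corrected_vision_hearing =
                   require_corrected_vision_hearing,
                 require_education_and_language_present =
                   require_education_and_language_present,
                 hads_max = hads_max,
                 mmse_min_exclusive = mmse_min_exclusive,
                 drop_missing_screen = drop_missing_screen,
                 order = order),
            class = "filter_criteria")
}

# returns a logical keep-vector for one named criterion
.filter_keep <- function(cohort, step, criteria) {
  n <- nrow(cohort)
  miss_ok <- !criteria$drop_missing_screen
  switch(step,
    baseline = if (criteria$baseline_only)
      cohort$visit == 1L else rep(TRUE, n),
    native_language = if (criteria$require_native_language)
      cohort$native_lang %in% TRUE else rep(TRUE, n),
    vision_hearing = if (criteria$require_corrected_vision_hearing)
      cohort$vh_corrected %in% TRUE else rep(TRUE, n),
    missing_fields = if (criteria$require_education_and_language_present)
      !is.na(cohort$edu_years) & !is.na(cohort$lang) &
        nzchar(as.character(cohort$lang)) else rep(TRUE, n),
    hads = ifelse(is.na(cohort$hads), miss_ok,
                  cohort$hads <= criteria$hads_max),
    mmse = ifelse(is.na(cohort$mmse), miss_ok,
                  cohort$mmse > criteria$mmse_min_exclusive),
    stop("unknown filter step: ", step)
  )
}

#' Apply the screening chain and report per-step attrition
#'
#' @param cohort A cohort table with columns \code{visit},
#'   \code{native_lang}, \code{vh_corrected}, \code{edu_years},
#'   \code{lang}, \code{hads}, \code{mmse}.
#' @param criteria A \code{\link{filter_criteria}}.
#' @return List with \code{cohort} (surviving rows) and \code{report}, a
#'   data.frame of (criterion, n_before, n_removed, n_after) whose
#'   counts telescope to \code{final_n} (attribute).
#' @export
apply_filters <- function(cohort, criteria = filter_criteria()) {
  needed <- c("visit", "native_lang", "vh_corrected", "edu_years",
              "lang", "hads", "mmse")
  missing_cols <- setdiff(needed, names(cohort))
  if (length(missing_cols))
    stop("cohort is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  kept <- cohort
  rows <- list()
  for (step in criteria$order) {
    n_before <- nrow(kept)
    keep <- .filter_keep(kept, step, criteria)
    kept <- kept[keep, , drop = FALSE]
    rows[[step]] <- data.frame(criterion = step, n_before = n_before,
                               n_removed = n_before - nrow(kept),
                               n_after = nrow(kept))
  }
  report <- do.call(rbind, c(rows, make.row.names = FALSE))
  attr(report, "final_n") <- nrow(kept)
  list(cohort = kept, report = report)
}

#' Per-test completeness of the cognitive battery
#'
#' @param cohort A cohort table carrying score columns.
#' @param tests Test ids to count (default: the full battery).
#' @return List with \code{per_test} (data.frame test/n_complete) and
#'   \code{all_complete}, the number of rows with every test present.
#' @export
summarize_battery_completeness <- function(cohort,
                                           tests = battery_tests()) {
  cols <- tolower(tests)
  present <- matrix(FALSE, nrow(cohort), length(cols))
  for (j in seq_along(cols)) {
    if (cols[j] %in% names(cohort))
      present[, j] <- !is.na(cohort[[cols[j]]])
  }
  per_test <- data.frame(test = tests,
                         n_complete = colSums(present))
  list(per_test = per_test,
       all_complete = sum(rowSums(present) == length(cols)))
}

#' Serialize an attrition report
#' @param report Report data.frame from \code{\link{apply_filters}}.
#' @param path Output path; \code{".json"} writes JSON, anything else a
#'   plain-text table.
#' @export
write_filter_report <- function(report, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(list(steps = report,
                              final_n = attr(report, "final_n")),
                         path, auto_unbox = TRUE, digits = NA)
  } else {
    txt <- c(sprintf("%-16s %9s %9s %9s", "criterion", "n_before",
                     "n_removed", "n_after"),
             sprintf("%-16s %9d %9d %9d", report$criterion,
                     report$n_before, report$n_removed, report$n_after),
             sprintf("final_n = %d", attr(report, "final_n")))
    writeLines(txt, path)
  }
  invisible(path)
}
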