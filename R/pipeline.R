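# End-to-end driver: simulate -> screen -> model ladder -> select ->
# refit selected model -> lookup table -> table norms -> effect
# summaries, with every artifact written to disk. The numbered scripts
# under analysis/ are thin narrative wrappers over this function and
# the individual stages.

#' Run the full normative-data pipeline on a synthetic cohort
#'
#' @param out_dir Output directory (created if needed).
#' @param n Cohort size before screening.
#' @param tests Test ids to model (default SDMT and SWRT; the full
#'   battery multiplies runtime by four).
#' @param config Generator configuration.
#' @param violation_rates Screening-violation rates passed to
#'   \code{\link{inject_screening_violations}}.
#' @param mcmc A \code{\link{mcmc_config}}.
#' @param seed Master seed; stage seeds are derived from it.
#' @param run_ladder Fit the full ten-model selection ladder per test
#'   (otherwise the full additive model is used directly).
#' @param age_grid,edu_grid Lookup-table grids.
#' @return Invisibly, a list with the per-stage results and artifact
#'   paths.
#' @export
run_pipeline <- function(out_dir, n = 3267,
                         tests = c("SDMT", "SWRT"),
                         config = cohort_config(),
                         violation_rates = list(hads = 0.05,
                                                mmse = 0.03,
                                                non_native = 0.04,
                                                missing_edu = 0.02),
                         mcmc = mcmc_config(),
                         seed = 1L, run_ladder = TRUE,
                         age_grid = 18:86, edu_grid = 1:24) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  note <- function(...) message(sprintf(...))

  note("[simulate] n = %d", n)
  truths <- stats::setNames(lapply(tests, default_truth), tests)
  cohort <- sample_demographics(config, n, seed = seed)
  cohort <- sample_scores(cohort, truths, seed = seed + 1L)
  cohort <- inject_screening_violations(cohort, violation_rates,
                                        seed = seed + 2L)
  paths$cohort <- file.path(out_dir, "cohort.csv")
  write_cohort_csv(cohort, paths$cohort)

  note("[filter] screening chain")
  flt <- apply_filters(cohort)
  paths$filter_report <- file.path(out_dir, "filter_report.json")
  write_filter_report(flt$report, paths$filter_report)
  norm_cohort <- flt$cohort

  fits <- list(); ladders <- list(); selections <- list()
  for (tid in tests) {
    if (run_ladder) {
      note("[select] %s: ten-model ladder", tid)
      lad <- run_selection_ladder(norm_cohort, tid, mcmc = mcmc)
      ladders[[tid]] <- lad$table
      selections[[tid]] <- lad$selected
    } else {
      selections[[tid]] <- model_spec(tid, form = "GAM")
    }
    note("[fit] %s: %s(%s)", tid, selections[[tid]]$form,
         paste(selections[[tid]]$predictors, collapse = ","))
    fits[[tid]] <- fit_normative_model(selections[[tid]], norm_cohort,
                                       mcmc = mcmc)
  }
  if (run_ladder) {
    paths$selection <- file.path(out_dir, "selection_ladder.csv")
    utils::write.csv(do.call(rbind, c(lapply(names(ladders),
      function(t) cbind(test = t, ladders[[t]])),
      make.row.names = FALSE)), paths$selection, row.names = FALSE)
  }

  note("[lookup] predictive grid")
  lookup <- build_lookup(fits, age_grid = age_grid,
                         edu_grid = edu_grid)
  paths$lookup <- file.path(out_dir, "lookup_table.csv")
  write_lookup(lookup, paths$lookup)

  note("[norms] stratified tables and effect summaries")
  norms <- build_norm_table(norm_cohort, tests = tests)
  paths$norm_tables <- file.path(out_dir, "norm_tables.csv")
  utils::write.csv(norms, paths$norm_tables, row.names = FALSE)
  eff <- list()
  for (tid in tests) {
    f <- fits[[tid]]
    if ("gender" %in% f$spec$predictors)
      eff[[paste0(tid, "_gender")]] <- summarize_gender_effect(f)
  }
  if (length(eff)) {
    paths$effects <- file.path(out_dir, "gender_effects.csv")
    utils::write.csv(do.call(rbind, c(eff, make.row.names = FALSE)),
                     paths$effects, row.names = FALSE)
  }

  invisible(list(cohort = cohort, normative_cohort = norm_cohort,
                 filter_report = flt$report, ladders = ladders,
                 selections = selections, fits = fits,
                 lookup = lookup, norm_tables = norms,
                 paths = paths))
}
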