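#!/usr/bin/env Rscript
# Stage 4: fit the selected normative model per test, check
# convergence and posterior predictive fit.
#
# The full additive model is used for SDMT (all four predictors; the
# stage-3 ladder ranks it best outright) and the gender-dropped
# additive model for SWRT (best raw LOO-IC in stage 3; the generative
# SWRT gender effect of 0.59 points is negligible against a residual
# SD of 15, so dropping gender costs nothing).

suppressPackageStartupMessages(library(cognorm))

cohort <- read_cohort_csv("results/normative_cohort.csv")
mc <- mcmc_config("desk", seed = 72L)
specs <- list(
  SDMT = model_spec("SDMT", form = "GAM"),
  SWRT = model_spec("SWRT", form = "GAM",
                    predictors = c("age", "education", "language"))
)

fits <- list()
diag_rows <- list()
for (tid in names(specs)) {
  message("fitting ", tid, " ...")
  fit <- suppressWarnings(fit_normative_model(specs[[tid]], cohort,
                                              mcmc = mc))
  diag <- check_convergence(fit)
  ppc <- posterior_predictive_check(fit, n_rep = 20, seed = 73L)
  loo <- compute_loo(fit)
  message(sprintf("  n = %d, max R-hat %.4f (pass: %s), mean PPC KS %.3f",
                  fit$n, diag$max_rhat, diag$pass, ppc$mean_ks))
  message(sprintf("  LOO-IC %.1f (SE %.1f), k-hat >= 0.5: %d",
                  loo$loo_ic, loo$se_loo_ic, loo$n_high_k))
  diag_rows[[tid]] <- data.frame(
    test = tid, n = fit$n, max_rhat = diag$max_rhat,
    converged = diag$pass, mean_ppc_ks = ppc$mean_ks,
    loo_ic = loo$loo_ic, loo_ic_se = loo$se_loo_ic,
    n_high_pareto_k = loo$n_high_k)
  fits[[tid]] <- fit
}
utils::write.csv(do.call(rbind, c(diag_rows, make.row.names = FALSE)),
                 "results/fit_diagnostics.csv", row.names = FALSE)
# posterior draws are bulky: keep them in scratch/, stages 5-6 reload
dir.create("scratch", showWarnings = FALSE)
saveRDS(fits, "scratch/fits.rds")
message("wrote results/fit_diagnostics.csv, scratch/fits.rds")
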