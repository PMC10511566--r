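#!/usr/bin/env Rscript
# Stage 5: stratified table norms and posterior effect summaries.
#
# Table norms: cell mean/SD stratified by ten age groups, the
# education dichotomy (<= 12 vs > 12 years), gender and language.
# Effect summaries: posterior mean + 95% HDI of the gender coefficient
# and of each language offset relative to English.

suppressPackageStartupMessages(library(cognorm))

cohort <- read_cohort_csv("results/normative_cohort.csv")
fits <- readRDS("scratch/fits.rds")

norms <- build_norm_table(cohort)
utils::write.csv(norms, "results/norm_tables.csv", row.names = FALSE)
message(sprintf("table norms: %d non-empty cells across %d tests",
                nrow(norms), length(unique(norms$test))))

eff_g <- list(); eff_l <- list()
for (tid in names(fits)) {
  f <- fits[[tid]]
  if ("gender" %in% f$spec$predictors) {
    eff_g[[tid]] <- summarize_gender_effect(f)
    message(sprintf("%s gender effect: M = %.2f, 95%% HDI [%.2f, %.2f] (%s)",
                    tid, eff_g[[tid]]$M, eff_g[[tid]]$hdi_lower,
                    eff_g[[tid]]$hdi_upper, eff_g[[tid]]$scale))
  }
  if ("language" %in% f$spec$predictors)
    eff_l[[tid]] <- summarize_language_effects(f)
}
if (length(eff_g))
  utils::write.csv(do.call(rbind, c(eff_g, make.row.names = FALSE)),
                   "results/gender_effects.csv", row.names = FALSE)
lang_tab <- do.call(rbind, c(eff_l, make.row.names = FALSE))
utils::write.csv(lang_tab, "results/language_effects.csv",
                 row.names = FALSE)
message("language offsets relative to English:")
for (i in seq_len(nrow(lang_tab)))
  message(sprintf("  %s %-4s M = %6.2f [%6.2f, %6.2f]",
                  lang_tab$test[i], lang_tab$language[i],
                  lang_tab$M[i], lang_tab$hdi_lower[i],
                  lang_tab$hdi_upper[i]))
message("wrote results/norm_tables.csv, results/gender_effects.csv, results/language_effects.csv")
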