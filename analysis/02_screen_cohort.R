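#!/usr/bin/env Rscript
# Stage 2: apply the inclusion/exclusion screening chain.
#
# Baseline visit only; native-language administration with corrected
# vision/hearing; education and language recorded; HADS <= 10 (no
# evidence of ongoing depression); MMSE > 26 (no evidence of cognitive
# impairment). The per-step attrition report is the flow-chart of the
# selection process.

suppressPackageStartupMessages(library(cognorm))

cohort <- read_cohort_csv("results/cohort.csv")
res <- apply_filters(cohort)

write_filter_report(res$report, "results/filter_report.json")
write_filter_report(res$report, "results/filter_report.txt")
write_cohort_csv(res$cohort, "results/normative_cohort.csv")

print(res$report)
message(sprintf("normative sample: n = %d of %d",
                attr(res$report, "final_n"), nrow(cohort)))
comp <- summarize_battery_completeness(res$cohort)
message(sprintf("complete battery: n = %d", comp$all_complete))
message("wrote results/normative_cohort.csv, results/filter_report.{json,txt}")
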