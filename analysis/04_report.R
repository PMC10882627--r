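#!/usr/bin/env Rscript
# Full study report: runs both arms end to end and renders the tables,
# JSON summary and topographic figures under results/report/.
# Usage: Rscript analysis/04_report.R

suppressPackageStartupMessages(library(somnistate))
cohort <- if (file.exists("results/cohort/cohort.rds"))
  readRDS("results/cohort/cohort.rds") else load_cohort("results/cohort")

config <- study_config(seed = 99)
report <- run_study(cohort, config)
files <- render_report(report, "results/report")
cat("Rendered", length(files), "files under results/report/\n")
print(report)
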