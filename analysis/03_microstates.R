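#!/usr/bin/env Rscript
# NREM-3 microstate arm: average reference, 1-40 Hz, modified k-means
# (K = 4, 20 restarts) at GFP peaks per subject, group and grand-mean
# templates sorted against the canonical maps, backfitting of the GM
# templates, temporal parameters and transition statistics with Wilcoxon /
# Bonferroni comparisons.
#
# Reads results/cohort (from 01), writes results/microstates/.
# Usage: Rscript analysis/03_microstates.R

suppressPackageStartupMessages(library(somnistate))
cohort <- if (file.exists("results/cohort/cohort.rds"))
  readRDS("results/cohort/cohort.rds") else load_cohort("results/cohort")

config <- study_config(seed = 99)
cat("Running the microstate arm on stage", config$ms_stage, "...\n")
ms <- run_microstate_arm(cohort, config)

dir.create("results/microstates", showWarnings = FALSE, recursive = TRUE)
write.csv(ms$parameter_tests, "results/microstates/parameter_tests.csv",
          row.names = FALSE)
write.csv(ms$transition_tests, "results/microstates/transition_tests.csv",
          row.names = FALSE)

gevs <- 100 * ms$gev
grp <- ms$groups[names(gevs)]
cat(sprintf("\nGEV: patients %.2f%%, controls %.2f%% (K = %d maps)\n",
            mean(gevs[grp == "patient"]), mean(gevs[grp == "control"]),
            config$K))
cat("GM-to-canonical correlations:",
    sprintf("%.3f", diag(ms$correlations$gm_vs_canonical)), "\n")
if (length(ms$excluded))
  cat("Excluded subjects:", paste(ms$excluded, collapse = ", "), "\n")

thr <- bonferroni_threshold(config$alpha, config$transition_m)
tt <- ms$transition_tests
cat(sprintf("\nTransitions below the corrected threshold (%0.4f):\n", thr))
print(tt[tt$raw_p < thr,
         c("from", "to", "patient_mean", "control_mean", "raw_p")],
      row.names = FALSE)
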