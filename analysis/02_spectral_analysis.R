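#!/usr/bin/env Rscript
# Spectral arm: linked-mastoid reference, 0.5-30 Hz zero-phase FIR,
# multitaper (DPSS, 0.5 Hz half-bandwidth) relative band power per stage,
# cluster-based permutation tests per (stage, band) cell with BH-FDR across
# cells, and per-channel FDR flags.
#
# Reads results/cohort (from 01), writes results/spectral/.
# Usage: Rscript analysis/02_spectral_analysis.R

suppressPackageStartupMessages(library(somnistate))
cohort <- if (file.exists("results/cohort/cohort.rds"))
  readRDS("results/cohort/cohort.rds") else load_cohort("results/cohort")

config <- study_config(seed = 99)
cat("Running the spectral arm over stages",
    paste(config$spectral_stages, collapse = ", "), "...\n")
sp <- run_spectral_arm(cohort, config)

dir.create("results/spectral", showWarnings = FALSE, recursive = TRUE)
write.csv(sp$table, "results/spectral/band_power.csv", row.names = FALSE)
write.csv(sp$cell_fdr, "results/spectral/cells.csv", row.names = FALSE)
write.csv(sp$flags, "results/spectral/channel_flags.csv",
          row.names = FALSE)

cat("\nPer-cell results (min cluster p, FDR-adjusted):\n")
print(sp$cell_fdr, row.names = FALSE)
sig <- sp$cell_fdr[sp$cell_fdr$significant, ]
for (i in seq_len(nrow(sig))) {
  d <- sp$difference[[sig$stage[i]]][[sig$band[i]]]
  cat(sprintf("  %s/%s: mean patient-control difference %+.4f (%s)\n",
              sig$stage[i], sig$band[i], mean(d),
              if (mean(d) > 0) "higher in patients" else
                "lower in patients"))
}
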