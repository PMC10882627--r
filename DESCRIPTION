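Package: somnistate
Title: Sleep EEG Spectral and Microstate Group Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An all-night sleep-EEG analysis workflow for two-group clinical
    studies: stage-resolved relative band power from multitaper (DPSS)
    spectral estimates with cluster-based permutation and FDR statistics,
    and NREM-3 EEG microstate analysis (polarity-invariant modified k-means
    at global field power peaks, template validation by spatial correlation,
    backfitting, temporal parameters and transition statistics with
    Wilcoxon/Bonferroni comparisons). Includes a seeded synthetic cohort
    generator with known spectral and microstate ground truth, and minimal
    EDF input/output, so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    yaml
Config/testthat/edition: 3
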