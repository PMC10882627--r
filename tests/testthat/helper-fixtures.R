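# Shared fixtures, built in code.

# four exactly orthogonal, average-referenced, unit-norm maps on 19 channels
orthogonal_templates <- function(nch = 19) {
  set.seed(424)
  M <- matrix(rnorm(nch * 4), nch, 4)
  M <- sweep(M, 2, colMeans(M))
  Q <- qr.Q(qr(M))
  Q <- sweep(Q, 2, colMeans(Q))       # re-centre (QR can break zero-mean)
  Q <- sweep(Q, 2, sqrt(colSums(Q^2)), "/")
  rownames(Q) <- montage_1020()$labels[seq_len(nch)]
  Q
}

# a tiny, quick cohort for pipeline tests: 4 + 4 subjects, one compressed
# sleep cycle of 7.5 minutes
smoke_config <- function(seed = 1, ...) {
  synthetic_config(n_subjects_per_group = 4, night_minutes = 7.5,
                   arousal_rate = 0, seed = seed, ...)
}

smoke_study_config <- function(...) {
  study_config(n_perm = 200, n_restarts = 5, ...)
}
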