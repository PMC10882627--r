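test_that("hypnograms have the right epoch count and arousal behaviour", {
  h <- make_hypnogram(480, 30, arousal_rate = 0, seed = 1)
  expect_equal(nrow(h), 960)
  expect_true(all(h$arousal_fraction == 0))
  expect_setequal(unique(h$stage), c("W", "N1", "N2", "N3", "REM"))

  h2 <- make_hypnogram(1, 30, arousal_rate = 10, seed = 1)
  expect_equal(nrow(h2), 2)

  expect_error(make_hypnogram(-5), "positive")
  expect_error(make_hypnogram(0.4, 30), "whole epochs")
})

test_that("arousal marking matches the Poisson rate over many seeds", {
  rate <- 10; minutes <- 480
  marked <- vapply(1:20, function(s) {
    h <- make_hypnogram(minutes, 30, arousal_rate = rate, seed = s)
    sum(h$arousal_fraction > 0)
  }, 0)
  # each 3-15 s arousal marks 1-2 epochs; expected count in [k, 2k]
  k <- rate * minutes / 60
  expect_gt(mean(marked), k * 0.5)
  expect_lt(mean(marked), k * 3)
})

test_that("canonical templates are average-referenced with the expected
          geometry", {
  ct <- make_canonical_templates(montage_1020())
  expect_equal(ncol(ct$maps), 4)
  expect_true(all(abs(colSums(ct$maps)) < 1e-10))
  expect_equal(unname(sqrt(colSums(ct$maps^2))), rep(1, 4))
  # A and B near-uncorrelated, mirroring the normative template pair
  expect_lt(abs(spatial_correlation(ct$maps[, "A"], ct$maps[, "B"])), 0.3)
  # sign flip is perfectly anticorrelated
  expect_equal(spatial_correlation(ct$maps[, "C"], -ct$maps[, "C"]), -1)
  expect_error(make_canonical_templates(list()), "montage")
})

test_that("microstate sequences follow the transition matrix and dwell law", {
  P <- matrix(1 / 3, 4, 4); diag(P) <- 0
  seq1 <- simulate_microstate_sequence(P, 90, 1e6, 250, seed = 2)
  r <- rle(seq1)
  # mean dwell within 5% of 90 ms
  expect_lt(abs(mean(r$lengths) / 250 * 1000 - 90) / 90, 0.05)
  # no self-transitions
  expect_true(all(diff(r$values) != 0 | r$values[-1] != r$values[-length(r$values)]))
  # empirical transition rows match the matrix within 0.02
  emp <- matrix(0, 4, 4)
  from <- r$values[-length(r$values)]; to <- r$values[-1]
  for (i in 1:4) for (j in 1:4)
    emp[i, j] <- sum(from == i & to == j) / max(1, sum(from == i))
  expect_lt(max(abs(emp - P)), 0.02)

  # deterministic alternating chain
  P2 <- matrix(0, 4, 4); P2[3, 4] <- 1; P2[4, 3] <- 1
  P2[1, 2] <- 1; P2[2, 1] <- 1
  s <- simulate_microstate_sequence(P2, 90, 5000, 250, seed = 3, start = 3)
  rv <- rle(s)$values
  expect_true(all(rv %in% c(3, 4)))
  expect_true(all(diff(rv) != 0))

  bad <- P; diag(bad) <- 0.1
  expect_error(simulate_microstate_sequence(bad, 90, 100, 250), "diagonal")
})

test_that("simulated EEG is deterministic and respects the null effect", {
  uni <- matrix(1 / 3, 4, 4); diag(uni) <- 0
  null_tm <- list(control = uni, patient = uni)
  cfg0 <- smoke_config(theta_effect = 1,
                       ms_transition_matrix_per_group = null_tm)
  hyp <- make_hypnogram(7.5, 30, 0, seed = 5)
  a <- simulate_eeg(hyp, cfg0, "patient", seed = 11)
  b <- simulate_eeg(hyp, cfg0, "control", seed = 11)
  expect_identical(a$recording$data, b$recording$data)

  cfg1 <- smoke_config(theta_effect = 1.3)
  p <- simulate_eeg(hyp, cfg1, "patient", seed = 11)
  c2 <- simulate_eeg(hyp, cfg1, "control", seed = 11)
  expect_false(identical(p$recording$data, c2$recording$data))

  # truth label sequence covers exactly the N3 samples
  L <- 30 * cfg1$sampling_rate
  expect_length(p$truth$ms_labels, sum(hyp$stage == "N3") * L)
})

test_that("cohorts are reproducible and sized correctly", {
  cfg <- smoke_config(seed = 9)
  co1 <- simulate_cohort(cfg)
  co2 <- simulate_cohort(cfg)
  expect_equal(length(co1$recordings), 8)
  expect_equal(length(co1$hypnograms), 8)
  expect_identical(co1$recordings[["P03"]]$data, co2$recordings[["P03"]]$data)
  expect_identical(co1$hypnograms, co2$hypnograms)
  expect_equal(sum(co1$group_labels == "patient"), 4)

  # degenerate 1-per-group cohort builds without crashing
  tiny <- simulate_cohort(synthetic_config(n_subjects_per_group = 1,
                                           night_minutes = 2, seed = 1))
  expect_length(tiny$recordings, 2)
  # ... but the statistics refuse it
  expect_error(run_spectral_arm(tiny, smoke_study_config()), ">= 2")
})

test_that("cohort round-trips through the on-disk format", {
  cfg <- synthetic_config(n_subjects_per_group = 1, night_minutes = 2,
                          arousal_rate = 20, seed = 4)
  co <- simulate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- load_cohort(dir)
  expect_identical(names(back$recordings), names(co$recordings))
  expect_identical(unname(back$group_labels), unname(co$group_labels))
  # EDF quantization: worst-case half step of the 16-bit physical range
  for (id in names(co$recordings)) {
    X <- co$recordings[[id]]$data
    step <- (max(X) - min(X)) / 65535
    expect_lt(max(abs(X - back$recordings[[id]]$data)), step)
    expect_equal(back$hypnograms[[id]]$stage, co$hypnograms[[id]]$stage)
    expect_equal(back$hypnograms[[id]]$arousal_fraction,
                 co$hypnograms[[id]]$arousal_fraction, tolerance = 1e-6)
  }
})
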