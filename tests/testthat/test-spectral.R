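test_that("DPSS tapers match an independent implementation", {
  lines <- readLines("fixture-dpss-n64-nw3.txt")
  lines <- lines[!startsWith(lines, "#")]
  vals <- lapply(strsplit(lines, " "), as.numeric)
  ref <- do.call(rbind, vals[1:5])          # 5 x 64 tapers
  ref_lambda <- vals[[6]]
  dp <- dpss_tapers(64, 3, 5)
  for (k in 1:5) {
    v <- dp$tapers[, k]
    if (sum(v * ref[k, ]) < 0) v <- -v
    expect_lt(max(abs(v - ref[k, ])), 1e-10)
  }
  expect_lt(max(abs(dp$eigenvalues - ref_lambda)), 1e-8)
  # orthonormality at production size
  big <- dpss_tapers(7500, 15)
  expect_equal(ncol(big$tapers), 29)
  expect_lt(max(abs(crossprod(big$tapers) - diag(29))), 1e-10)
  expect_true(all(diff(big$eigenvalues) <= 1e-12))
})

test_that("multitaper PSD satisfies Parseval and localizes tones", {
  set.seed(10)
  fs <- 250
  # white noise: integral of the density ~ variance (Monte-Carlo, 20 epochs)
  ints <- vars <- numeric(20)
  for (i in 1:20) {
    x <- matrix(rnorm(fs * 30), 1)
    ps <- multitaper_psd(x, fs)
    ints[i] <- band_power(ps, 0, fs / 2)
    vars[i] <- mean(x^2) - mean(x)^2
  }
  expect_lt(abs(mean(ints) - 1), 0.05)
  # Parseval holds per-epoch within 1%
  expect_lt(max(abs(ints / vars - 1)), 0.01)

  # pure 6 Hz tone peaks at 6 Hz within the half-bandwidth
  t <- (0:(fs * 30 - 1)) / fs
  ps <- multitaper_psd(matrix(sin(2 * pi * 6 * t), 1), fs)
  fpk <- ps$frequencies[which.max(ps$power[1, ])]
  expect_lt(abs(fpk - 6), 0.5)

  # zero signal -> all-zero PSD
  ps0 <- multitaper_psd(matrix(0, 2, fs * 30), fs)
  expect_true(all(ps0$power == 0))

  expect_error(multitaper_psd(matrix(0, 1, fs), fs), "2 s")
})

test_that("band power integrates a flat density exactly and is additive", {
  fs <- 250; nf <- 3751
  flat <- structure(list(frequencies = seq(0, fs / 2, length.out = nf),
                         power = matrix(2, 1, nf), taper_count = 1),
                    class = "power_spectrum")
  expect_equal(unname(band_power(flat, 0.5, 4)), 2 * 3.5)
  d <- band_power(flat, 0.5, 4) + band_power(flat, 4, 8)
  expect_equal(unname(d), unname(band_power(flat, 0.5, 8)), tolerance = 1e-12)
  expect_error(band_power(flat, 100, 130), "range")
})

test_that("relative power normalizes against the filtered range", {
  set.seed(11)
  fs <- 250
  # flat-spectrum ratio: delta share of the 0.5-30 range = 3.5/29.5,
  # Monte-Carlo over 10 epochs
  rel_delta <- vapply(1:10, function(i) {
    ps <- multitaper_psd(matrix(rnorm(fs * 30), 1), fs)
    relative_power(ps)$relative["delta", 1]
  }, 0)
  expect_lt(abs(mean(rel_delta) - 3.5 / 29.5), 0.01)
  ps <- multitaper_psd(matrix(rnorm(fs * 30 * 2), 2), fs)
  rp <- relative_power(ps)
  expect_true(all(rp$relative >= 0 & rp$relative <= 1))

  # a pure theta tone is ~all theta
  t <- (0:(fs * 30 - 1)) / fs
  ps6 <- multitaper_psd(matrix(sin(2 * pi * 6 * t), 1), fs)
  rp6 <- relative_power(ps6)
  expect_gt(rp6$relative["theta", 1], 0.98)

  # scale invariance
  ps2 <- multitaper_psd(matrix(2 * sin(2 * pi * 6 * t), 1), fs)
  expect_equal(relative_power(ps2)$relative, rp6$relative,
               tolerance = 1e-10)
})

test_that("stage-group tables aggregate per subject and difference maps
          are antisymmetric under group swap", {
  cfg <- smoke_config(seed = 21)
  hyp <- make_hypnogram(5, 30, 0, seed = 1)
  sc <- study_config()
  subs <- list(
    s1 = simulate_eeg(hyp, cfg, "patient", seed = 1),
    s2 = simulate_eeg(hyp, cfg, "patient", seed = 2),
    s3 = simulate_eeg(hyp, cfg, "control", seed = 3),
    s4 = simulate_eeg(hyp, cfg, "control", seed = 4))
  sets <- lapply(subs, function(s)
    segment_epochs(rereference(s$recording, "linked-mastoid"), hyp))
  groups <- c(s1 = "patient", s2 = "patient", s3 = "control",
              s4 = "control")
  out <- stage_group_table(sets, groups, stages = "N2")
  expect_true(all(c("subject", "group", "stage", "channel", "band",
                    "rel_power", "abs_power") %in% names(out$table)))
  expect_true(all(out$table$rel_power > 0 & out$table$rel_power < 1))

  swapped <- c(s1 = "control", s2 = "control", s3 = "patient",
               s4 = "patient")
  out2 <- stage_group_table(sets, swapped, stages = "N2")
  expect_equal(out2$difference$N2$theta, -out$difference$N2$theta,
               tolerance = 1e-12)

  # identical groups -> near-zero difference map
  same <- stage_group_table(sets[c(1, 1, 2, 2)] |>
                              stats::setNames(c("a", "b", "c", "d")),
                            c(a = "patient", b = "control", c = "patient",
                              d = "control"), stages = "N2")
  expect_lt(max(abs(same$difference$N2$theta)), 1e-12)
})
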