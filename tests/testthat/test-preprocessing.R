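make_tone <- function(freq, fs = 250, secs = 60, nch = 2) {
  t <- (0:(fs * secs - 1)) / fs
  x <- sin(2 * pi * freq * t)
  eeg_recording(matrix(rep(x, each = nch), nch), fs,
                paste0("ch", seq_len(nch)))
}

test_that("band-pass filter has the right pass/stop behaviour and zero
          phase", {
  rec <- make_tone(10)
  out <- bandpass_filter(rec, 0.5, 30)
  core <- out$data[1, 2000:12000]
  expect_lt(abs(max(abs(core)) - 1), 0.02)      # passband gain within 2%

  rec45 <- make_tone(45)
  out45 <- bandpass_filter(rec45, 1, 40)
  expect_lt(max(abs(out45$data[1, 2000:12000])), 0.1)  # > 90% attenuation

  # symmetric impulse input -> symmetric output (zero net phase)
  n <- 4001
  imp <- matrix(0, 2, n); imp[, (n + 1) / 2] <- 1
  reci <- eeg_recording(imp, 250, c("a", "b"))
  y <- bandpass_filter(reci, 0.5, 30)$data[1, ]
  expect_equal(y, rev(y), tolerance = 1e-12)

  expect_error(bandpass_filter(rec, 40, 10), "Nyquist")
  expect_error(bandpass_filter(rec, 0, 30), "Nyquist")
})

test_that("downsampling preserves duration and passband content", {
  t <- (0:(1000 * 60 - 1)) / 1000
  x <- sin(2 * pi * 5 * t)
  rec <- eeg_recording(rbind(x, x), 1000, c("a", "b"))
  out <- downsample(rec, 250)
  expect_equal(out$srate, 250)
  expect_equal(ncol(out$data), 15000)
  # 5 Hz tone identical within 1% away from edges
  ref <- sin(2 * pi * 5 * (0:14999) / 250)
  core <- 1000:14000
  expect_lt(max(abs(out$data[1, core] - ref[core])), 0.01)

  expect_identical(downsample(rec, 1000), rec)
  expect_error(downsample(rec, 2000), "above")
  expect_error(downsample(rec, 300), "divide")
})

test_that("filter and downsample commute on a passband tone", {
  t <- (0:(1000 * 30 - 1)) / 1000
  x <- sin(2 * pi * 5 * t)
  rec <- eeg_recording(rbind(x, x), 1000, c("a", "b"))
  a <- downsample(bandpass_filter(rec, 0.5, 30), 250)
  b <- bandpass_filter(downsample(rec, 250), 0.5, 30)
  core <- 2000:5000
  expect_lt(max(abs(a$data[1, core] - b$data[1, core])), 0.02)
})

test_that("re-referencing follows its definitions", {
  set.seed(1)
  X <- matrix(rnorm(21 * 500), 21)
  labels <- montage_1020(include_mastoids = TRUE)$labels
  rec <- eeg_recording(X, 250, labels)

  avg <- rereference(rec, "average")
  expect_lt(max(abs(colSums(avg$data))), 1e-9)
  expect_equal(nrow(avg$data), 19)
  # idempotent
  again <- rereference(avg, "average")
  expect_equal(again$data, avg$data, tolerance = 1e-12)

  # zero mastoids leave the data unchanged apart from the channel drop
  X2 <- X; X2[20:21, ] <- 0
  rec2 <- eeg_recording(X2, 250, labels)
  lm <- rereference(rec2, "linked-mastoid")
  expect_equal(lm$data, X2[1:19, ], ignore_attr = TRUE)
  expect_false(any(c("M1", "M2") %in% lm$labels))

  rec3 <- eeg_recording(X[1:19, ], 250, labels[1:19])
  expect_error(rereference(rec3, "linked-mastoid"), "M1 and M2")
})

test_that("epoch segmentation applies the strict >15% arousal rule and
          partitions the hypnogram", {
  fs <- 250; L <- 30 * fs
  hyp <- hypnogram(c(rep("N3", 10), rep("REM", 5)),
                   c(5 / 30, 0.15, rep(0, 13)), 30)
  rec <- eeg_recording(matrix(rnorm(2 * 15 * L), 2), fs, c("a", "b"))
  es <- segment_epochs(rec, hyp)
  # epoch 1: 5 s arousal = fraction 0.167 > 0.15 -> excluded
  # epoch 2: fraction exactly 0.15 -> retained (not *more than* 15%)
  expect_length(es$stages$N3, 9)
  expect_length(es$stages$REM, 5)
  expect_equal(unname(es$excluded["N3"]), 1L)
  expect_false(0L %in% es$epoch_ids$N3)
  expect_true(1L %in% es$epoch_ids$N3)
  # partition: every epoch retained or excluded exactly once
  expect_equal(sum(lengths(es$stages)) + sum(es$excluded), nrow(hyp))

  # edge exclusion drops epochs overlapping the filter transients
  es2 <- segment_epochs(rec, hyp, edge_samples = 250)
  expect_false(0L %in% unlist(es2$epoch_ids))
  expect_false(14L %in% unlist(es2$epoch_ids))
  expect_equal(sum(lengths(es2$stages)) + sum(es2$excluded), nrow(hyp))

  long <- hypnogram(rep("N3", 20), 0, 30)
  expect_error(segment_epochs(rec, long), "longer")
})

test_that("operations leave their input recordings unmodified", {
  rec <- make_tone(10, secs = 10)
  snapshot <- rec$data + 0
  invisible(bandpass_filter(rec, 0.5, 30))
  invisible(rereference(eeg_recording(rbind(rec$data, 0, 0), rec$srate,
                                      c("a", "b", "M1", "M2")),
                        "linked-mastoid"))
  expect_identical(rec$data, snapshot)
})

test_that("EDF I/O round-trips and fails informatively", {
  cfg <- synthetic_config(night_minutes = 1, arousal_rate = 0, seed = 2)
  hyp <- hypnogram(c("N2", "N2"), 0, 30)
  sim <- simulate_eeg(hyp, cfg, "control", seed = 3)
  f <- withr::local_tempfile(fileext = ".edf")
  write_edf(sim$recording, f)
  back <- read_edf(f)
  step <- (max(sim$recording$data) - min(sim$recording$data)) / 65535
  expect_lt(max(abs(back$data - sim$recording$data)), step)
  expect_identical(back$labels, sim$recording$labels)
  expect_equal(back$srate, 250)
  expect_equal(sum(!back$labels %in% c("M1", "M2")), 19)
  expect_false(is.null(back$montage))

  expect_error(read_edf(file.path(tempdir(), "nope.edf")), "no such file")

  # unknown channel label without a montage override
  weird <- eeg_recording(matrix(rnorm(2 * 250), 2), 250, c("XX1", "XX2"))
  f2 <- withr::local_tempfile(fileext = ".edf")
  write_edf(weird, f2)
  expect_error(read_edf(f2), "unknown channel")
  m <- montage(c("XX1", "XX2"), rbind(c(0, 0), c(1, 0)))
  ok <- read_edf(f2, montage = m)
  expect_identical(ok$labels, c("XX1", "XX2"))
})
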