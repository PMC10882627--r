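test_that("global field power matches hand-computed values", {
  expect_equal(global_field_power(c(1, -1)), 1)
  expect_equal(global_field_power(c(5, 5, 5)), 0)
  expect_equal(global_field_power(c(2, 0, -2, 0)), sqrt(2))
  expect_error(global_field_power(matrix(1, 1, 3)), "2 channels")
})

test_that("GFP peaks are strict interior local maxima", {
  g <- c(1, 3, 1, 5, 1)
  expect_equal(gfp_peaks(g), c(2, 4))
  expect_length(gfp_peaks(1:10), 0)
  # rectified-sinusoid-shaped trace: ~20 peaks per second at 10 Hz
  t <- (0:249) / 250
  npk <- length(gfp_peaks(abs(sin(2 * pi * 10 * t)) + 1e-6 * t))
  expect_true(abs(npk - 20) <= 1)
})

test_that("spatial correlation reproduces the printed-formula identities", {
  u <- c(0.4, -1.2, 0.8)
  expect_equal(spatial_correlation(u, u), 1)
  expect_equal(spatial_correlation(u, -u), -1)
  expect_equal(spatial_correlation(c(1, 0, -1), c(0, 1, -1)), 0.5)
  # symmetry, positive-scale invariance, bounds
  set.seed(2)
  for (i in 1:20) {
    a <- rnorm(19); b <- rnorm(19)
    r <- spatial_correlation(a, b)
    expect_equal(spatial_correlation(b, a), r)
    expect_equal(spatial_correlation(3.7 * a, b), r)
    expect_lte(abs(r), 1)
  }
  expect_error(spatial_correlation(rep(1, 4), rnorm(4)), "zero-variance")
})

test_that("modified k-means recovers planted orthogonal templates exactly", {
  Q <- orthogonal_templates()
  set.seed(31)
  n <- 400
  truth <- sample(1:4, n, replace = TRUE)
  amp <- runif(n, 0.5, 2) * sample(c(-1, 1), n, replace = TRUE)
  maps <- Q[, truth] * rep(amp, each = nrow(Q))
  ts <- modified_kmeans(maps, K = 4, n_restarts = 5, seed = 1)
  expect_equal(ts$gev, 1, tolerance = 1e-9)
  sorted <- sort_templates(ts, template_set(Q, channels = rownames(Q)))
  expect_true(all(attr(sorted, "correlations") > 0.999))

  # determinism
  ts2 <- modified_kmeans(maps, K = 4, n_restarts = 5, seed = 1)
  expect_identical(ts$maps, ts2$maps)

  # global sign flip: bitwise-identical clustering up to template sign
  ts_neg <- modified_kmeans(-maps, K = 4, n_restarts = 5, seed = 1)
  expect_equal(abs(ts_neg$maps), abs(ts$maps), tolerance = 1e-12)
  # positive rescaling: same recovered set up to permutation and sign
  ts_sc <- modified_kmeans(2.5 * maps, K = 4, n_restarts = 5, seed = 1)
  s_sc <- sort_templates(ts_sc, template_set(Q, channels = rownames(Q)))
  expect_true(all(attr(s_sc, "correlations") > 0.999))
  expect_equal(ts_sc$gev, 1, tolerance = 1e-9)

  expect_error(modified_kmeans(maps[, 1:3], K = 4), "fewer maps")
})

test_that("GEV behaves at its extremes and grows with K", {
  Q <- orthogonal_templates()
  n <- 100
  set.seed(5)
  truth <- sample(1:4, n, replace = TRUE)
  maps <- Q[, truth] * rep(runif(n, 0.5, 3), each = nrow(Q))
  expect_equal(gev(maps, truth, Q), 1)
  # adversarial labels onto orthogonal templates explain nothing
  wrong <- (truth %% 4) + 1
  expect_equal(gev(maps, wrong, Q), 0, tolerance = 1e-20)

  # nested fits: more templates never explain less
  noisy <- maps + matrix(rnorm(length(maps), 0, 0.3), nrow(maps))
  fit_gev <- function(K) modified_kmeans(noisy, K, n_restarts = 5,
                                         seed = 3)$gev
  g2 <- fit_gev(2); g3 <- fit_gev(3); g4 <- fit_gev(4)
  expect_true(g3 >= g2 - 1e-9 && g4 >= g3 - 1e-9)
})

test_that("template sorting finds the permutation and fixes signs", {
  Q <- orthogonal_templates()
  ref <- template_set(Q, channels = rownames(Q))
  shuffled <- template_set(Q[, c(3, 1, 4, 2)] %*% diag(c(-1, 1, -1, 1)),
                           channels = rownames(Q))
  sorted <- sort_templates(shuffled, ref)
  expect_equal(unname(attr(sorted, "correlations")), rep(1, 4),
               tolerance = 1e-12)
  expect_equal(sorted$maps, ref$maps, ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_identical(sorted$labels, ref$labels)

  # duplicated maps: deterministic tie-break, no error
  dup <- template_set(Q[, c(1, 1, 3, 4)], channels = rownames(Q))
  s2 <- sort_templates(dup, ref)
  expect_s3_class(s2, "template_set")

  expect_error(sort_templates(template_set(Q[, 1:3]), ref), "differ in K")
})

test_that("grand means are idempotent and respect sign alignment", {
  Q <- orthogonal_templates()
  ref <- template_set(Q, channels = rownames(Q))
  gm1 <- grand_mean(list(ref, ref))
  expect_equal(gm1$maps, ref$maps, ignore_attr = TRUE, tolerance = 1e-12)
  # a sign-flipped copy is fixed by sorting before averaging
  flipped <- sort_templates(template_set(-Q, channels = rownames(Q)), ref)
  gm2 <- grand_mean(list(ref, flipped))
  expect_equal(gm2$maps, ref$maps, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("backfitting reproduces a planted construction and ignores
          polarity", {
  Q <- orthogonal_templates()
  ts <- template_set(Q, channels = rownames(Q))
  truth <- rep(c(1L, 3L, 2L, 4L, 2L), each = 25)
  amp <- runif(length(truth), 0.5, 2)
  X <- Q[, truth] * rep(amp, each = nrow(Q))
  seg <- backfit(X, ts, srate = 250)
  expect_identical(seg$labels, truth)
  seg_neg <- backfit(-X, ts, srate = 250)
  expect_identical(seg_neg$labels, truth)

  # zero-variance samples inherit the previous label
  X2 <- X; X2[, 30] <- 0
  seg2 <- backfit(X2, ts, srate = 250)
  expect_equal(seg2$labels[30], seg2$labels[29])

  # short-run smoothing merges a 2-sample blip into its neighbours
  X3 <- X
  X3[, 40:41] <- Q[, 4] * 3
  seg3 <- backfit(X3, ts, srate = 250, min_ms = 20)
  expect_identical(seg3$labels, truth)
})

test_that("microstate metrics match a hand count and satisfy the
          bookkeeping identity", {
  lab <- c(1, 1, 2, 2, 3, 3, 1, 1)
  seg <- structure(list(labels = lab, gfp = rep(1, 8), srate = 250,
                        class_labels = c("A", "B", "C")),
                   class = "ms_segmentation")
  m <- microstate_metrics(seg, K = 3)
  expect_equal(m$per_class$coverage, c(0.5, 0.25, 0.25))
  expect_equal(m$per_class$duration_ms, rep(8, 3))
  expect_equal(m$transitions[cbind(c(1, 2, 3), c(2, 3, 1))], rep(1 / 3, 3))
  expect_equal(sum(m$transitions), 1)

  # degenerate single-class segmentation
  seg1 <- structure(list(labels = rep(2, 100), gfp = rep(1, 100),
                         srate = 250, class_labels = c("A", "B")),
                    class = "ms_segmentation")
  m1 <- microstate_metrics(seg1, K = 2)
  expect_equal(m1$per_class$coverage, c(0, 1))
  expect_equal(sum(m1$transition_counts), 0)

  # occurrence x duration ~ coverage on random sequences
  set.seed(8)
  for (i in 1:5) {
    lab <- rep(sample(1:4, 60, replace = TRUE), times = rpois(60, 20) + 1)
    seg <- structure(list(labels = lab, gfp = runif(length(lab)),
                          srate = 250, class_labels = LETTERS[1:4]),
                     class = "ms_segmentation")
    m <- microstate_metrics(seg, K = 4)
    ok <- m$per_class$coverage > 0
    expect_equal(m$per_class$occurrence[ok] *
                   m$per_class$duration_ms[ok] / 1000,
                 m$per_class$coverage[ok], tolerance = 0.05)
  }
})
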