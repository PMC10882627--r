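test_that("Wilcoxon rank-sum gives exact small-sample p-values", {
  r <- wilcoxon_ranksum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$raw_p, 0.1)
  expect_true(r$exact)
  expect_equal(r$statistic, 6)            # rank-sum of {1,2,3}

  same <- wilcoxon_ranksum(c(2, 4, 6), c(2, 4, 6))
  expect_equal(same$raw_p, 1)

  expect_error(wilcoxon_ranksum(1, c(1, 2)), ">= 2")
})

test_that("exact and approximate Wilcoxon paths agree for n = 10 + 10", {
  set.seed(3)
  for (i in 1:10) {
    x <- rnorm(10); y <- rnorm(10, 0.3)
    exact <- stats::wilcox.test(x, y, exact = TRUE)$p.value
    approx <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
    expect_lt(abs(exact - approx), 0.02)
    # the package picks the exact path here
    expect_true(wilcoxon_ranksum(x, y)$exact)
  }
})

test_that("Bonferroni arithmetic and monotonicity", {
  expect_equal(bonferroni(0.01, 16), 0.16)
  expect_equal(bonferroni(0.2, 16), 1)
  expect_equal(round(bonferroni_threshold(0.05, 12), 4), 0.0042)
  expect_equal(n_transition_pairs(4), 12)
  p <- sort(runif(20))
  expect_true(all(diff(bonferroni(p, 7)) >= 0))
  expect_error(bonferroni(1.2, 3), "outside")
})

test_that("BH FDR reproduces the hand-computed step-up", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  p <- runif(50)
  expect_true(all(bh_fdr(p) >= p))
  expect_error(bh_fdr(numeric(0)), "empty")
})

test_that("cluster permutation test is deterministic, exchangeable and
          finds planted clusters", {
  mont <- montage_1020()
  set.seed(40)
  nA <- 10; nB <- 10
  A <- matrix(rnorm(nA * 19), nA, 19, dimnames = list(NULL, mont$labels))
  B <- matrix(rnorm(nB * 19), nB, 19, dimnames = list(NULL, mont$labels))
  r1 <- cluster_permutation_test(A, B, mont, n_perm = 300, seed = 5)
  r2 <- cluster_permutation_test(A, B, mont, n_perm = 300, seed = 5)
  expect_identical(r1$clusters, r2$clusters)
  expect_identical(r1$null_max, r2$null_max)

  # reordering subjects within a group changes nothing
  r3 <- cluster_permutation_test(A[nA:1, ], B, mont, n_perm = 300, seed = 5)
  expect_equal(r3$t, r1$t)
  expect_equal(r3$min_p, r1$min_p)

  # a strong shift at 5 adjacent channels forms one significant cluster
  chs <- c("Fp1", "Fp2", "F3", "Fz", "F4")
  hits <- 0
  for (s in 1:10) {
    set.seed(100 + s)
    A2 <- matrix(rnorm(17 * 19), 17, 19, dimnames = list(NULL, mont$labels))
    B2 <- matrix(rnorm(17 * 19), 17, 19, dimnames = list(NULL, mont$labels))
    A2[, chs] <- A2[, chs] + 2
    r <- cluster_permutation_test(A2, B2, mont, n_perm = 300, seed = s)
    sig <- Filter(function(cl) cl$p < 0.05, r$clusters)
    if (length(sig) &&
        any(vapply(sig, function(cl)
          all(match(chs, mont$labels) %in% cl$channels), TRUE)))
      hits <- hits + 1
  }
  expect_gte(hits, 9)

  expect_error(cluster_permutation_test(A[1, , drop = FALSE], B, mont),
               ">= 2")
  expect_warning(cluster_permutation_test(A, B, mont, n_perm = 50,
                                          seed = 1), "coarse")
})

test_that("clusters honour montage adjacency", {
  mont <- montage_1020()
  adj <- somnistate:::adjacency_index(mont, mont$labels)
  # symmetric, irreflexive
  for (i in seq_along(adj)) {
    expect_false(i %in% adj[[i]])
    for (j in adj[[i]]) expect_true(i %in% adj[[j]])
  }
  # frontal and occipital electrodes are not neighbours
  expect_false(match("O1", mont$labels) %in%
                 adj[[match("Fp1", mont$labels)]])
  # a supra-threshold pair split across the scalp forms two clusters
  t_vec <- rep(0, 19)
  t_vec[match(c("Fp1", "O2"), mont$labels)] <- 5
  cl <- somnistate:::t_clusters(t_vec, 2, adj)
  expect_length(cl, 2)
})

test_that("Wilcoxon has usable power at the study's sample size", {
  set.seed(77)
  rej <- 0; reps <- 1000
  for (i in seq_len(reps)) {
    x <- rnorm(17, 1); y <- rnorm(17, 0)
    if (stats::wilcox.test(x, y, exact = FALSE)$p.value < 0.05)
      rej <- rej + 1
  }
  expect_gt(rej / reps, 0.5)
})
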