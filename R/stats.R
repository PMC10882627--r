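# Group statistics: Wilcoxon rank-sum with Bonferroni correction for
# microstate parameters and transitions; channel-wise cluster-based
# permutation with Monte-Carlo p-values and BH-FDR for spectral
# topographies.

#' Wilcoxon rank-sum test for two independent samples
#'
#' Two-sided; exact enumeration when the pooled sample has at most 20
#' observations and no ties, normal approximation with tie and continuity
#' correction otherwise (via [stats::wilcox.test]).
#'
#' @param x,y numeric samples with at least 2 observations each
#' @return object of class `test_result`: list with `statistic` (rank-sum
#'   W of `x`), `raw_p`, `corrected_p`, `correction`, `m`
#' @export
wilcoxon_ranksum <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) stop("need >= 2 observations per group")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y) <= 20) && !ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = !exact))
  structure(list(statistic = unname(wt$statistic) +
                   length(x) * (length(x) + 1) / 2,  # U -> rank-sum W
                 raw_p = wt$p.value, corrected_p = wt$p.value,
                 correction = "none", m = 1L, exact = exact),
            class = "test_result")
}

#' Bonferroni correction
#'
#' @param p raw p-value in \[0, 1\]
#' @param m number of comparisons
#' @return corrected p, `min(1, m * p)`
#' @export
bonferroni <- function(p, m) {
  if (any(p < 0 | p > 1)) stop("p outside [0, 1]")
  if (m < 1) stop("m must be >= 1")
  pmin(1, m * p)
}

#' Bonferroni-corrected significance threshold
#'
#' The per-test threshold `alpha / m`; e.g. alpha 0.05 over the 12 directed
#' transitions among 4 microstate classes gives 0.0042 (4 d.p.).
#'
#' @param alpha family-wise level
#' @param m number of comparisons
#' @export
bonferroni_threshold <- function(alpha = 0.05, m) alpha / m

#' Number of directed transitions between K classes
#'
#' Ordered pairs without self-transitions: `K * (K - 1)`.
#' @param K number of classes
#' @export
n_transition_pairs <- function(K) K * (K - 1L)

#' Benjamini-Hochberg FDR adjustment
#'
#' @param pvals vector of p-values
#' @return adjusted p-values (same order)
#' @export
bh_fdr <- function(pvals) {
  if (!length(pvals)) stop("empty p-value list")
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) stop("p outside [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

# pooled-variance two-sample t per column; X: subjects x channels
pooled_t <- function(XA, XB) {
  nA <- nrow(XA); nB <- nrow(XB)
  mA <- colMeans(XA); mB <- colMeans(XB)
  vA <- colSums(sweep(XA, 2, mA)^2)
  vB <- colSums(sweep(XB, 2, mB)^2)
  sp <- sqrt((vA + vB) / (nA + nB - 2) * (1 / nA + 1 / nB))
  (mA - mB) / sp
}

# connected components of supra-threshold channels (one t vector)
t_clusters <- function(t, thresh, adj_idx) {
  clusters <- list()
  for (sgn in c(1, -1)) {
    mask <- if (sgn > 0) t > thresh else t < -thresh
    seen <- rep(FALSE, length(t))
    for (i in seq_along(t)) {
      if (!mask[i] || seen[i]) next
      comp <- integer(0)
      stack <- i
      seen[i] <- TRUE
      while (length(stack)) {
        u <- stack[length(stack)]
        stack <- stack[-length(stack)]
        comp <- c(comp, u)
        for (v in adj_idx[[u]])
          if (mask[v] && !seen[v]) { seen[v] <- TRUE; stack <- c(stack, v) }
      }
      clusters[[length(clusters) + 1]] <-
        list(channels = sort(comp), mass = sum(t[comp]), sign = sgn)
    }
  }
  clusters
}

#' Cluster-based permutation test over channels
#'
#' Per-channel pooled-variance t-values; channels exceeding the two-sided
#' `cluster_alpha` critical value form clusters under montage adjacency;
#' the cluster statistic is the within-cluster sum of t. The null
#' distribution is the maximum absolute cluster mass over `n_perm` random
#' group relabelings; each observed cluster gets the Monte-Carlo p-value
#' `(1 + #\{null >= observed\}) / (1 + n_perm)`.
#'
#' @param groupA,groupB subjects x channels matrices (same channel order)
#' @param adjacency list of integer neighbour indices per channel (e.g.
#'   from a [montage] via the channel order), or a [montage] whose labels
#'   match `colnames(groupA)`
#' @param n_perm number of permutations (values below 100 warn)
#' @param cluster_alpha two-sided cluster-forming alpha on the t
#'   distribution
#' @param seed RNG seed
#' @return object of class `cluster_result`: `t` (channel t-values),
#'   `clusters` (channel sets, masses, p-values), `min_p`, `t_crit`,
#'   `channel_p` (uncorrected per-channel two-sided t-test p-values)
#' @export
cluster_permutation_test <- function(groupA, groupB, adjacency,
                                     n_perm = 1000, cluster_alpha = 0.05,
                                     seed = 1) {
  groupA <- as.matrix(groupA); groupB <- as.matrix(groupB)
  if (nrow(groupA) < 2 || nrow(groupB) < 2)
    stop("need >= 2 subjects per group")
  nch <- ncol(groupA)
  if (inherits(adjacency, "montage"))
    adjacency <- adjacency_index(adjacency, colnames(groupA))
  if (length(adjacency) != nch)
    stop("adjacency does not cover all channels")
  if (n_perm < 100) warning("n_perm < 100 gives a coarse Monte-Carlo p")
  nA <- nrow(groupA); nB <- nrow(groupB); n <- nA + nB
  X <- rbind(groupA, groupB)
  df <- n - 2
  t_crit <- stats::qt(1 - cluster_alpha / 2, df)
  t_obs <- pooled_t(groupA, groupB)
  clusters <- t_clusters(t_obs, t_crit, adjacency)
  null_max <- with_seed(seed, {
    # indicator matrix of group-A membership per permutation
    P <- matrix(0, n_perm, n)
    for (p in seq_len(n_perm)) P[p, sample.int(n, nA)] <- 1
    S1 <- P %*% X
    Q1 <- P %*% X^2
    S <- matrix(colSums(X), n_perm, nch, byrow = TRUE)
    Q <- matrix(colSums(X^2), n_perm, nch, byrow = TRUE)
    m1 <- S1 / nA
    m2 <- (S - S1) / nB
    v1 <- Q1 - nA * m1^2
    v2 <- (Q - Q1) - nB * m2^2
    sp <- sqrt((v1 + v2) / df * (1 / nA + 1 / nB))
    Tm <- (m1 - m2) / sp
    Tm[!is.finite(Tm)] <- 0
    max_cluster_mass_cpp(Tm, t_crit, adjacency)
  })
  for (i in seq_along(clusters))
    clusters[[i]]$p <- (1 + sum(null_max >= abs(clusters[[i]]$mass))) /
      (1 + n_perm)
  min_p <- if (length(clusters)) min(vapply(clusters, `[[`, 0, "p")) else 1
  channel_p <- 2 * stats::pt(abs(t_obs), df, lower.tail = FALSE)
  structure(list(t = t_obs, t_crit = t_crit, clusters = clusters,
                 min_p = min_p, channel_p = channel_p, n_perm = n_perm,
                 null_max = null_max),
            class = "cluster_result")
}

#' Hedges' g (descriptive effect size)
#'
#' Bias-corrected standardized mean difference between two samples.
#' @param x,y numeric samples
#' @export
hedges_g <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp <- sqrt(((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) /
               (nx + ny - 2))
  J <- 1 - 3 / (4 * (nx + ny) - 9)
  J * (mean(x) - mean(y)) / sp
}
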