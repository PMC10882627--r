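# NREM-3 microstate machinery: GFP, GFP peaks, polarity-invariant modified
# k-means, GEV, spatial correlation (the printed dissimilarity-index formula,
# numerically a spatial Pearson correlation on average-referenced maps),
# template sorting/grand means, backfitting and temporal metrics.

#' Microstate template set
#'
#' @param maps channels x K numeric matrix; each column a topographic map
#' @param labels K unique class labels (default A, B, C, ...)
#' @param level one of "subject", "group", "grand-mean", "canonical"
#' @param channels channel labels bound to the rows
#' @param gev global explained variance achieved when fitting, or NA
#' @return object of class `template_set`
#' @export
template_set <- function(maps, labels = LETTERS[seq_len(ncol(maps))],
                         level = "subject", channels = rownames(maps),
                         gev = NA_real_) {
  maps <- as.matrix(maps)
  if (ncol(maps) < 2) stop("a template set needs K >= 2 maps")
  if (anyDuplicated(labels)) stop("labels must be unique")
  level <- match.arg(level, c("subject", "group", "grand-mean", "canonical"))
  if (!is.na(gev) && (gev < 0 || gev > 1)) stop("gev must lie in [0, 1]")
  maps <- apply(maps, 2, function(v) {
    v <- v - mean(v)
    nv <- sqrt(sum(v^2))
    if (nv == 0) stop("all-zero template map")
    v / nv
  })
  rownames(maps) <- channels
  colnames(maps) <- labels
  structure(list(maps = maps, labels = as.character(labels), level = level,
                 channels = channels, gev = gev),
            class = "template_set")
}

#' @export
print.template_set <- function(x, ...) {
  cat(sprintf("<template_set> K=%d (%s), level=%s, GEV=%s\n",
              ncol(x$maps), paste(x$labels, collapse = ""), x$level,
              ifelse(is.na(x$gev), "NA", sprintf("%.3f", x$gev))))
  invisible(x)
}

#' Global field power
#'
#' Spatial standard deviation (1/n population form) across channels of an
#' average-referenced sample. For a matrix, one value per column (sample).
#'
#' @param x numeric vector (one map) or channels x samples matrix
#' @return GFP in the units of `x`
#' @export
global_field_power <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("GFP needs at least 2 channels")
  mu <- colMeans(x)
  sqrt(colMeans(x^2) - mu^2)
}

#' GFP peak samples
#'
#' Indices at which the GFP trace is a strict local maximum (greater than
#' both neighbours); endpoints are never peaks.
#'
#' @param data channels x samples matrix, or a precomputed GFP vector
#' @return integer sample indices
#' @export
gfp_peaks <- function(data) {
  g <- if (is.matrix(data)) global_field_power(data) else as.numeric(data)
  n <- length(g)
  if (n < 3) stop("need at least 3 samples")
  idx <- 2:(n - 1)
  idx[g[idx] > g[idx - 1] & g[idx] > g[idx + 1]]
}

#' Spatial correlation between two topographic maps
#'
#' `sum(u*v) / sqrt(sum(u^2) * sum(v^2))` on average-referenced maps, which
#' equals the spatial Pearson product-moment correlation coefficient.
#'
#' @param u,v numeric vectors over the same channel set
#' @return value in \[-1, 1\]
#' @export
spatial_correlation <- function(u, v) {
  if (length(u) != length(v)) stop("maps must share a channel set")
  u <- u - mean(u); v <- v - mean(v)
  du <- sum(u^2); dv <- sum(v^2)
  if (du == 0 || dv == 0) stop("zero-variance map: correlation undefined")
  sum(u * v) / sqrt(du * dv)
}

# column-normalized (zero-mean, unit-norm) copy of a channels x m matrix
normalize_maps <- function(M) {
  M <- sweep(M, 2, colMeans(M))
  nv <- sqrt(colSums(M^2))
  nv[nv == 0] <- 1
  sweep(M, 2, nv, "/")
}

#' Global explained variance
#'
#' GFP-weighted fraction of topographic variance explained by the labelled
#' templates: `sum((gfp_t * corr(u_t, T_label_t))^2) / sum(gfp_t^2)`.
#'
#' @param data channels x samples matrix (average-referenced)
#' @param labels per-sample template index (1..K), NA samples are skipped
#' @param templates a [template_set] or channels x K matrix
#' @return fraction in \[0, 1\]
#' @export
gev <- function(data, labels, templates) {
  M <- if (inherits(templates, "template_set")) templates$maps else templates
  g <- global_field_power(data)
  if (all(g == 0)) stop("all-zero GFP")
  U <- normalize_maps(sweep(data, 2, colMeans(data)))
  ok <- !is.na(labels)
  corr <- colSums(U[, ok, drop = FALSE] * M[, labels[ok], drop = FALSE])
  sum((g[ok] * corr)^2) / sum(g^2)
}

#' Polarity-invariant modified k-means clustering of topographic maps
#'
#' Clusters maps (typically those at GFP peaks) into K classes ignoring
#' polarity: maps are assigned to the template with the largest squared
#' spatial correlation, and each template is updated to the dominant
#' eigenvector of the outer-product sum of its assigned maps. The procedure
#' is restarted `n_restarts` times from random distinct maps (restart r uses
#' seed `seed + r - 1`) and the restart with the highest GEV wins.
#'
#' @param maps channels x m matrix of maps to cluster
#' @param K number of classes
#' @param n_restarts random restarts (default 20)
#' @param tol convergence tolerance on the GEV improvement
#' @param max_iter iteration cap per restart
#' @param seed base RNG seed
#' @param gfp optional per-map field-power weights; defaults to the spatial
#'   SD of each map column
#' @return a [template_set] (level "subject") with `gev` set; attribute
#'   `assignment` holds the final map-to-class labelling
#' @export
modified_kmeans <- function(maps, K, n_restarts = 20, tol = 1e-7,
                            max_iter = 300, seed = 1, gfp = NULL) {
  maps <- as.matrix(maps)
  m <- ncol(maps)
  if (K < 2) stop("K must be >= 2")
  if (m < K) stop("fewer maps (", m, ") than clusters (", K, ")")
  if (is.null(gfp)) gfp <- global_field_power(maps)
  U <- normalize_maps(sweep(maps, 2, colMeans(maps)))
  g2 <- sum(gfp^2)
  best <- list(gev = -Inf)
  for (r in seq_len(n_restarts)) {
    res <- with_seed(seed + r - 1L, {
      Tm <- U[, sample.int(m, K), drop = FALSE]
      prev_gev <- -Inf; assign_ <- NULL; gev_r <- 0
      for (it in seq_len(max_iter)) {
        C <- crossprod(Tm, U)                    # K x m correlations
        assign_ <- max.col(t(C^2), ties.method = "first")
        hit <- abs(C[cbind(assign_, seq_len(m))])
        gev_r <- sum((gfp * hit)^2) / g2
        for (k in seq_len(K)) {
          sel <- assign_ == k
          if (!any(sel)) {                       # empty cluster: re-seed
            worst <- which.min(hit)
            Tm[, k] <- U[, worst]
            assign_[worst] <- k
            next
          }
          Vk <- U[, sel, drop = FALSE]
          ev <- eigen(tcrossprod(Vk), symmetric = TRUE)
          tk <- ev$vectors[, 1]
          Tm[, k] <- (tk - mean(tk)) / sqrt(sum((tk - mean(tk))^2))
        }
        if (gev_r - prev_gev < tol && it > 1) break
        prev_gev <- gev_r
      }
      list(gev = gev_r, maps = Tm, assignment = assign_)
    })
    if (res$gev > best$gev) best <- res
  }
  best$gev <- min(max(best$gev, 0), 1)   # guard rounding at exact fits
  out <- template_set(best$maps, labels = LETTERS[seq_len(K)],
                      level = "subject", channels = rownames(maps),
                      gev = best$gev)
  attr(out, "assignment") <- best$assignment
  out
}

#' Sort a template set against a reference
#'
#' Finds the one-to-one assignment maximizing the total absolute spatial
#' correlation (all K! permutations are scored; K is small), relabels maps
#' with the reference labels, and flips each map's sign so that its
#' correlation with its reference is positive. Ties are broken by map index.
#'
#' @param ts,reference [template_set]s over the same channels with equal K
#' @return the sorted [template_set]; attributes `correlations` (per-class
#'   matched values) and `assignment` (reference class -> original map index)
#' @export
sort_templates <- function(ts, reference) {
  A <- ts$maps; R <- reference$maps
  K <- ncol(A)
  if (ncol(R) != K) stop("template sets differ in K")
  C <- crossprod(R, A)                 # K_ref x K_ts correlations
  perms <- permutations_of(K)
  score <- apply(perms, 1, function(p) sum(abs(C[cbind(seq_len(K), p)])))
  bestp <- perms[which.max(score), ]   # which.max: first maximum = tie-break
  maps <- A[, bestp, drop = FALSE]
  corr <- C[cbind(seq_len(K), bestp)]
  flip <- ifelse(corr < 0, -1, 1)
  maps <- sweep(maps, 2, flip, "*")
  out <- template_set(maps, labels = reference$labels, level = ts$level,
                      channels = ts$channels, gev = ts$gev)
  attr(out, "correlations") <- abs(corr)
  attr(out, "assignment") <- bestp
  out
}

permutations_of <- function(K) {
  if (K == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(K - 1)
  out <- matrix(0L, 0, K)
  for (i in seq_len(K)) {
    rest <- setdiff(seq_len(K), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  out
}

#' Grand mean of sorted template sets
#'
#' Averages the sign-aligned maps of template sets that were all sorted
#' against the same reference, then re-normalizes.
#'
#' @param sets list of sorted [template_set]s with identical labels
#' @param level level tag for the result (default "grand-mean")
#' @return a [template_set]
#' @export
grand_mean <- function(sets, level = "grand-mean") {
  labs <- sets[[1]]$labels
  for (s in sets)
    if (!identical(s$labels, labs))
      stop("sets must be sorted against a common reference first")
  M <- Reduce(`+`, lapply(sets, function(s) s$maps)) / length(sets)
  template_set(M, labels = labs, level = level,
               channels = sets[[1]]$channels)
}

#' Backfit templates to continuous data
#'
#' Labels every sample with the template of largest squared spatial
#' correlation (polarity ignored). Runs shorter than `min_ms` are optionally
#' merged into the neighbouring run with the higher mean correlation
#' (default: no smoothing). Zero-variance samples inherit the previous
#' label; a leading zero-variance stretch takes the first valid label.
#'
#' @param data channels x samples matrix
#' @param templates a [template_set]
#' @param srate sampling rate in Hz
#' @param min_ms minimum run length in ms (0 = no smoothing)
#' @return object of class `ms_segmentation`: list with `labels` (1..K),
#'   `gfp`, `srate` and the template labels
#' @export
backfit <- function(data, templates, srate, min_ms = 0) {
  M <- templates$maps
  g <- global_field_power(data)
  U <- sweep(data, 2, colMeans(data))
  nv <- sqrt(colSums(U^2))
  degenerate <- nv == 0
  nv[degenerate] <- 1
  U <- sweep(U, 2, nv, "/")
  C <- crossprod(M, U)                  # K x n
  lab <- max.col(t(C^2), ties.method = "first")
  if (any(degenerate)) {
    lab[degenerate] <- NA
    lab <- fill_forward(lab)
  }
  if (min_ms > 0) lab <- merge_short_runs(lab, abs(C), min_samples =
                                            ceiling(min_ms / 1000 * srate))
  structure(list(labels = lab, gfp = g, srate = srate,
                 class_labels = templates$labels),
            class = "ms_segmentation")
}

fill_forward <- function(lab) {
  if (all(is.na(lab))) stop("no valid samples to label")
  first <- which(!is.na(lab))[1]
  if (first > 1) lab[seq_len(first - 1)] <- lab[first]
  for (i in seq_along(lab)) if (is.na(lab[i])) lab[i] <- lab[i - 1]
  lab
}

# Merge runs shorter than min_samples into the neighbouring run whose
# template correlates better, on average, with the short run's own samples
# (absC = K x n matrix of |spatial correlation| per template). Operates in
# run space for speed; shortest runs are resolved first.
merge_short_runs <- function(lab, absC, min_samples) {
  if (min_samples <= 1) return(lab)
  r <- rle(lab)
  vals <- r$values
  lens <- r$lengths
  en <- cumsum(lens)
  st <- en - lens + 1
  # per-class cumulative correlation sums for O(1) span means
  csum <- apply(absC, 1, function(row) c(0, cumsum(row)))  # (n+1) x K
  span_mean <- function(k, a, b) (csum[b + 1, k] - csum[a, k]) / (b - a + 1)
  alive <- rep(TRUE, length(vals))
  prv <- c(NA, seq_len(length(vals) - 1))
  nxt <- c(seq_len(length(vals))[-1], NA)
  repeat {
    short <- which(alive & lens < min_samples)
    if (!length(short) || sum(alive) <= 1) break
    i <- short[which.min(lens[short])]
    l <- prv[i]; rgt <- nxt[i]
    tgt <- if (is.na(l)) rgt
    else if (is.na(rgt)) l
    else if (span_mean(vals[l], st[i], en[i]) >=
             span_mean(vals[rgt], st[i], en[i])) l else rgt
    if (is.na(tgt)) break
    # absorb run i into tgt, extending tgt's sample span
    lens[tgt] <- lens[tgt] + lens[i]
    st[tgt] <- min(st[tgt], st[i])
    en[tgt] <- max(en[tgt], en[i])
    vals[i] <- vals[tgt]
    alive[i] <- FALSE
    if (!is.na(prv[i])) nxt[prv[i]] <- nxt[i]
    if (!is.na(nxt[i])) prv[nxt[i]] <- prv[i]
    # coalesce now-adjacent runs of the same class
    a <- if (identical(tgt, l)) l else prv[tgt]
    b <- if (identical(tgt, l)) nxt[tgt] else tgt
    if (!is.na(a) && !is.na(b) && alive[a] && alive[b] &&
        vals[a] == vals[b]) {
      lens[a] <- lens[a] + lens[b]
      st[a] <- min(st[a], st[b])
      en[a] <- max(en[a], en[b])
      alive[b] <- FALSE
      if (!is.na(nxt[b])) prv[nxt[b]] <- a
      nxt[a] <- nxt[b]
    }
  }
  keep <- which(alive)
  rep(vals[keep], lens[keep])
}

#' Temporal and transition metrics of a microstate segmentation
#'
#' Coverage (fraction of samples), mean run duration (ms), occurrence
#' (runs per second), mean GFP per class, and the observed transition
#' counts between consecutive distinct runs, normalized both globally
#' (all ordered pairs sum to 1) and per row.
#'
#' @param seg an `ms_segmentation` from [backfit]
#' @param K number of classes (defaults to the segmentation's template count)
#' @return object of class `ms_metrics`: list with `per_class` data.frame,
#'   `transitions` (global proportions, zero diagonal), `transitions_row`
#'   (row-stochastic over visited states), `transition_counts`
#' @export
microstate_metrics <- function(seg, K = length(seg$class_labels)) {
  lab <- seg$labels
  n <- length(lab)
  secs <- n / seg$srate
  r <- rle(lab)
  cls <- seq_len(K)
  coverage <- as.numeric(tabulate(lab, K)) / n
  duration <- occurrence <- mgfp <- numeric(K)
  for (k in cls) {
    runs <- r$lengths[r$values == k]
    duration[k] <- if (length(runs)) mean(runs) / seg$srate * 1000 else 0
    occurrence[k] <- length(runs) / secs
    mgfp[k] <- if (any(lab == k)) mean(seg$gfp[lab == k]) else 0
  }
  counts <- matrix(0, K, K, dimnames = list(seg$class_labels,
                                            seg$class_labels))
  if (length(r$values) > 1) {
    from <- r$values[-length(r$values)]
    to <- r$values[-1]
    for (i in seq_along(from)) counts[from[i], to[i]] <-
        counts[from[i], to[i]] + 1
  }
  total <- sum(counts)
  trans <- if (total > 0) counts / total else counts
  rs <- rowSums(counts)
  trow <- counts / ifelse(rs == 0, 1, rs)
  per_class <- data.frame(class = seg$class_labels, coverage = coverage,
                          duration_ms = duration, occurrence = occurrence,
                          gfp = mgfp)
  structure(list(per_class = per_class, transitions = trans,
                 transitions_row = trow, transition_counts = counts),
            class = "ms_metrics")
}

#' @export
print.ms_metrics <- function(x, ...) {
  cat("<ms_metrics>\n")
  print(x$per_class, row.names = FALSE)
  invisible(x)
}
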