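# Orchestration of the full two-group study on a cohort: spectral arm
# (mastoid reference, 0.5-30 Hz, multitaper relative band power, cluster
# permutation + FDR) and NREM-3 microstate arm (average reference, 1-40 Hz,
# modified k-means templates at subject/group/grand-mean level, backfitting,
# Wilcoxon + Bonferroni statistics on temporal parameters and transitions).

#' Study configuration
#'
#' Bundles every tunable of the pipeline with the study defaults: spectral
#' arm filtered 0.5-30 Hz against linked mastoids, microstate arm filtered
#' 1-40 Hz against the average reference and restricted to NREM 3, K = 4
#' templates from 20 k-means restarts, cluster permutation with 1000
#' relabelings, Bonferroni m = 16 for the 4x4 temporal parameters and
#' m = 12 for directed transitions.
#'
#' @param spectral_band,ms_band filter pass-bands per arm (Hz)
#' @param filter_order FIR order at the nominal 1 kHz rate
#' @param target_rate working sampling rate after downsampling (Hz)
#' @param spectral_stages stages entering the spectral comparison (WAKE is
#'   excluded by default)
#' @param ms_stage stage for the microstate arm
#' @param K number of microstate classes
#' @param n_restarts modified k-means restarts
#' @param half_bandwidth multitaper half-bandwidth (Hz)
#' @param bands spectral bands, see [spectral_bands]
#' @param arousal_threshold epoch-rejection threshold on arousal fraction
#' @param cluster_alpha cluster-forming alpha
#' @param n_perm permutations for the cluster test
#' @param alpha family-wise level for reporting
#' @param temporal_m Bonferroni coefficient for temporal parameters
#' @param transition_m Bonferroni coefficient for transitions
#' @param ms_reference "canonical" or "grand-mean": sorting reference for
#'   template alignment
#' @param exclusion_r subjects whose best template-to-reference absolute
#'   correlation falls below this are excluded from microstate statistics
#' @param smooth_ms minimum microstate run length (ms) enforced when
#'   backfitting for the metric tables
#' @param seed RNG seed for clustering restarts and permutations
#' @return object of class `study_config`
#' @export
study_config <- function(spectral_band = c(0.5, 30), ms_band = c(1, 40),
                         filter_order = 1000, target_rate = 250,
                         spectral_stages = c("N1", "N2", "N3", "REM"),
                         ms_stage = "N3", K = 4, n_restarts = 20,
                         half_bandwidth = 0.5, bands = spectral_bands(),
                         arousal_threshold = 0.15, cluster_alpha = 0.05,
                         n_perm = 1000, alpha = 0.05, temporal_m = 16,
                         transition_m = 12,
                         ms_reference = c("canonical", "grand-mean"),
                         exclusion_r = 0.5, smooth_ms = 20, seed = 1) {
  structure(list(spectral_band = spectral_band, ms_band = ms_band,
                 filter_order = filter_order, target_rate = target_rate,
                 spectral_stages = spectral_stages, ms_stage = ms_stage,
                 K = K, n_restarts = n_restarts,
                 half_bandwidth = half_bandwidth, bands = bands,
                 arousal_threshold = arousal_threshold,
                 cluster_alpha = cluster_alpha, n_perm = n_perm,
                 alpha = alpha, temporal_m = temporal_m,
                 transition_m = transition_m,
                 ms_reference = match.arg(ms_reference),
                 exclusion_r = exclusion_r, smooth_ms = smooth_ms,
                 seed = as.integer(seed)),
            class = "study_config")
}

# per-subject preprocessing for one arm; returns an epoch_set
preprocess_arm <- function(rec, hyp, config, arm = c("spectral", "ms")) {
  arm <- match.arg(arm)
  rec <- downsample(rec, config$target_rate)
  if (arm == "spectral") {
    rec <- rereference(rec, "linked-mastoid")
    band <- config$spectral_band
  } else {
    rec <- rereference(rec, "average")
    band <- config$ms_band
  }
  rec <- bandpass_filter(rec, band[1], band[2], config$filter_order)
  ord <- attr(rec, "filter")$order
  segment_epochs(rec, hyp, config$arousal_threshold, edge_samples = ord,
                 demean = (arm == "ms"), detrend = (arm == "ms"))
}

#' Run the spectral arm of the study
#'
#' For every configured stage and band: subject-level relative band powers
#' (mean over retained epochs), the patient-minus-control difference
#' topography, a cluster-based permutation test within the cell, and two
#' second-level corrections: BH-FDR across the cells' minimum cluster
#' p-values, and BH-FDR across all channel-wise t-test p-values
#' (channels x stages x bands) for per-channel significance flags.
#'
#' @param cohort a `synthetic_cohort` (or compatible list with
#'   `recordings`, `hypnograms`, `group_labels`)
#' @param config a [study_config]
#' @return list with `table`, `difference`, `tests` (per stage/band),
#'   `cell_fdr` (data.frame of cells with FDR-adjusted cluster p), `flags`
#'   (per-channel FDR flags), `log`
#' @export
run_spectral_arm <- function(cohort, config = study_config()) {
  groups <- cohort$group_labels
  if (min(table(groups)) < 2) stop("need >= 2 subjects per group")
  log <- character(0)
  epoch_sets <- lapply(names(cohort$recordings), function(sid)
    preprocess_arm(cohort$recordings[[sid]], cohort$hypnograms[[sid]],
                   config, "spectral"))
  names(epoch_sets) <- names(cohort$recordings)
  sgt <- stage_group_table(epoch_sets, groups,
                           stages = config$spectral_stages,
                           bands = config$bands,
                           half_bandwidth = config$half_bandwidth,
                           total_range = config$spectral_band)
  tab <- sgt$table
  mont <- cohort$recordings[[1]]$montage
  tests <- list()
  cells <- list()
  chan_rows <- list()
  cell_seed <- config$seed
  for (st in config$spectral_stages) {
    tests[[st]] <- list()
    for (b in names(config$bands)) {
      sub <- tab[tab$stage == st & tab$band == b, ]
      if (!nrow(sub)) {
        log <- c(log, sprintf("cell %s/%s missing; skipped", st, b))
        next
      }
      wide <- stats::reshape(sub[c("subject", "group", "channel",
                                   "rel_power")],
                             idvar = c("subject", "group"),
                             timevar = "channel", direction = "wide")
      ch <- sub$channel[sub$subject == sub$subject[1]]
      M <- as.matrix(wide[, -(1:2)])
      colnames(M) <- ch
      A <- M[wide$group == "patient", , drop = FALSE]
      B <- M[wide$group == "control", , drop = FALSE]
      if (nrow(A) < 2 || nrow(B) < 2) {
        log <- c(log, sprintf("cell %s/%s lacks a group; skipped", st, b))
        next
      }
      cell_seed <- cell_seed + 1L
      cr <- cluster_permutation_test(A, B, mont, n_perm = config$n_perm,
                                     cluster_alpha = config$cluster_alpha,
                                     seed = cell_seed)
      tests[[st]][[b]] <- cr
      cells[[length(cells) + 1]] <- data.frame(stage = st, band = b,
                                               min_cluster_p = cr$min_p)
      chan_rows[[length(chan_rows) + 1]] <-
        data.frame(stage = st, band = b, channel = colnames(M),
                   t = cr$t, p = cr$channel_p, row.names = NULL)
    }
  }
  cell_fdr <- do.call(rbind, cells)
  cell_fdr$fdr_p <- bh_fdr(cell_fdr$min_cluster_p)
  cell_fdr$significant <- cell_fdr$fdr_p < config$alpha
  flags <- do.call(rbind, chan_rows)
  flags$fdr_p <- bh_fdr(flags$p)
  flags$significant <- flags$fdr_p < config$alpha
  list(table = tab, difference = sgt$difference, tests = tests,
       cell_fdr = cell_fdr, flags = flags, n_epochs = sgt$n_epochs,
       log = log)
}

#' Run the NREM-3 microstate arm of the study
#'
#' Subject templates (modified k-means at GFP peaks) are pooled into group
#' templates, group templates into grand-mean (GM) templates; all sets are
#' sorted against the configured reference. Subjects whose best
#' template-to-GM absolute correlation falls below `exclusion_r` are
#' excluded from statistics. Per-subject temporal parameters and transition
#' probabilities come from backfitting the GM templates; groups are
#' compared with Wilcoxon rank-sum tests under Bonferroni correction
#' (m = `temporal_m` for the 4x4 parameters, m = `transition_m` for the
#' directed transitions).
#'
#' @param cohort a `synthetic_cohort`
#' @param config a [study_config]
#' @return list with `subject_templates`, `group_templates`, `gm`,
#'   `correlations` (template correlation matrices), `metrics` (per-subject
#'   `ms_metrics`), `parameter_tests`, `transition_tests`, `excluded`,
#'   `gev` (per-subject), `log`
#' @export
run_microstate_arm <- function(cohort, config = study_config()) {
  groups <- cohort$group_labels
  subjects <- names(cohort$recordings)
  mont <- cohort$recordings[[1]]$montage
  canonical <- make_canonical_templates(mont)
  K <- config$K
  log <- character(0)
  n3_data <- list()
  subj_templates <- list()
  seed_i <- config$seed + 1000L
  for (sid in subjects) {
    es <- preprocess_arm(cohort$recordings[[sid]], cohort$hypnograms[[sid]],
                         config, "ms")
    eps <- es$stages[[config$ms_stage]]
    if (is.null(eps) || !length(eps)) {
      log <- c(log, sprintf("subject %s has no retained %s epochs; excluded",
                            sid, config$ms_stage))
      next
    }
    X <- do.call(cbind, eps)
    scalp <- setdiff(es$labels, c("M1", "M2"))
    X <- X[scalp, , drop = FALSE]
    peaks <- gfp_peaks(X)
    if (length(peaks) < K) {
      log <- c(log, sprintf("subject %s: %d GFP peaks < K; excluded",
                            sid, length(peaks)))
      next
    }
    seed_i <- seed_i + 100L
    ts <- modified_kmeans(X[, peaks, drop = FALSE], K,
                          n_restarts = config$n_restarts, seed = seed_i)
    n3_data[[sid]] <- X
    subj_templates[[sid]] <- ts
  }
  subjects <- names(subj_templates)
  if (length(subjects) < 4) stop("too few subjects with usable N3 data")
  pool_group <- function(g) {
    ids <- subjects[groups[subjects] == g]
    maps <- do.call(cbind, lapply(subj_templates[ids],
                                  function(t) t$maps))
    ts <- modified_kmeans(maps, K, n_restarts = config$n_restarts,
                          seed = config$seed + ifelse(g == "patient", 7L,
                                                      11L),
                          gfp = rep(1, ncol(maps)))
    ts$level <- "group"
    ts
  }
  grp <- list(control = pool_group("control"),
              patient = pool_group("patient"))
  grp <- lapply(grp, sort_templates, reference = canonical)
  gm <- grand_mean(grp, level = "grand-mean")
  if (config$ms_reference == "grand-mean") {
    grp <- lapply(grp, sort_templates, reference = gm)
    gm <- grand_mean(grp, level = "grand-mean")
  }
  sorted_subj <- lapply(subj_templates, sort_templates, reference = gm)
  excl <- character(0)
  subj_corr <- vapply(sorted_subj,
                      function(s) max(attr(s, "correlations")), 0)
  for (sid in subjects) {
    if (subj_corr[sid] < config$exclusion_r) {
      excl <- c(excl, sid)
      log <- c(log, sprintf(
        "subject %s excluded: best template-to-GM |r| = %.2f < %.2f",
        sid, subj_corr[sid], config$exclusion_r))
    }
  }
  kept <- setdiff(subjects, excl)
  metrics <- list()
  gev_subj <- numeric(0)
  for (sid in kept) {
    seg <- backfit(n3_data[[sid]], gm, config$target_rate,
                   min_ms = config$smooth_ms)
    metrics[[sid]] <- microstate_metrics(seg, K)
    gev_subj[sid] <- gev(n3_data[[sid]], seg$labels, gm)
  }
  # group comparisons
  params <- c("coverage", "duration_ms", "occurrence", "gfp")
  p_rows <- list()
  for (par in params) for (k in seq_len(K)) {
    val <- vapply(metrics, function(m) m$per_class[[par]][k], 0)
    x <- val[groups[kept] == "patient"]
    y <- val[groups[kept] == "control"]
    wt <- wilcoxon_ranksum(x, y)
    p_rows[[length(p_rows) + 1]] <- data.frame(
      parameter = par, class = gm$labels[k],
      patient_mean = mean(x), patient_sd = stats::sd(x),
      control_mean = mean(y), control_sd = stats::sd(y),
      statistic = wt$statistic, raw_p = wt$raw_p,
      corrected_p = bonferroni(wt$raw_p, config$temporal_m),
      correction = "bonferroni", m = config$temporal_m)
  }
  parameter_tests <- do.call(rbind, p_rows)
  t_rows <- list()
  for (i in seq_len(K)) for (j in seq_len(K)) {
    if (i == j) next
    val <- vapply(metrics, function(m) m$transitions[i, j], 0)
    x <- val[groups[kept] == "patient"]
    y <- val[groups[kept] == "control"]
    wt <- wilcoxon_ranksum(x, y)
    t_rows[[length(t_rows) + 1]] <- data.frame(
      from = gm$labels[i], to = gm$labels[j],
      patient_mean = mean(x), control_mean = mean(y),
      statistic = wt$statistic, raw_p = wt$raw_p,
      corrected_p = bonferroni(wt$raw_p, config$transition_m),
      correction = "bonferroni", m = config$transition_m)
  }
  transition_tests <- do.call(rbind, t_rows)
  corr_mat <- function(a, b) {
    M <- crossprod(a$maps, b$maps)
    dimnames(M) <- list(a$labels, b$labels)
    M
  }
  correlations <- list(
    patient_vs_control = corr_mat(grp$patient, grp$control),
    patient_vs_gm = corr_mat(grp$patient, gm),
    control_vs_gm = corr_mat(grp$control, gm),
    gm_vs_canonical = corr_mat(gm, canonical),
    subject_to_gm = subj_corr)
  list(subject_templates = sorted_subj, group_templates = grp, gm = gm,
       canonical = canonical, correlations = correlations,
       metrics = metrics, parameter_tests = parameter_tests,
       transition_tests = transition_tests, excluded = excl,
       gev = gev_subj, kept = kept, groups = groups[kept], log = log)
}

#' Run the full study
#'
#' @param cohort a `synthetic_cohort` or a directory written by
#'   [write_cohort]
#' @param config a [study_config]
#' @return object of class `study_report` with `spectral`, `microstate`,
#'   `config` and a run `log`
#' @export
run_study <- function(cohort, config = study_config()) {
  if (is.character(cohort)) cohort <- load_cohort(cohort)
  spectral <- run_spectral_arm(cohort, config)
  microstate <- run_microstate_arm(cohort, config)
  structure(list(spectral = spectral, microstate = microstate,
                 config = config,
                 log = c(spectral$log, microstate$log)),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n spectral cells:\n")
  print(x$spectral$cell_fdr, row.names = FALSE)
  sig <- x$microstate$transition_tests
  sig <- sig[sig$corrected_p < x$config$alpha, c("from", "to",
                                                 "corrected_p")]
  cat(" significant transitions:\n")
  if (nrow(sig)) print(sig, row.names = FALSE) else cat("  (none)\n")
  invisible(x)
}
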