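# Seeded synthetic sleep-EEG cohorts with known spectral and microstate
# ground truth. Band-limited background activity is synthesized directly in
# the frequency domain (random-phase spectra restricted to each band),
# mixed through smooth random spatial patterns to induce channel
# correlation, and scaled per epoch by stage-dependent band weights. NREM-3
# epochs additionally carry a planted microstate component: four quasi-stable
# topographies switching by a semi-Markov process, each run expressed as a
# 10 Hz sinusoidal activation of its template.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

default_stage_weights <- function() {
  w <- rbind(W   = c(0.15, 0.15, 0.40, 0.30),
             N1  = c(0.30, 0.30, 0.15, 0.25),
             N2  = c(0.45, 0.25, 0.10, 0.20),
             N3  = c(0.65, 0.15, 0.05, 0.15),
             REM = c(0.35, 0.30, 0.10, 0.25))
  colnames(w) <- c("delta", "theta", "alpha", "residual")
  w
}

default_transition_matrices <- function() {
  uni <- matrix(1 / 3, 4, 4); diag(uni) <- 0
  dimnames(uni) <- list(LETTERS[1:4], LETTERS[1:4])
  pat <- rbind(A = c(0, 0.15, 0.425, 0.425),
               B = c(0.15, 0, 0.425, 0.425),
               C = c(0.25, 0.25, 0, 0.50),
               D = c(0.25, 0.25, 0.50, 0))
  colnames(pat) <- LETTERS[1:4]
  list(control = uni, patient = pat)
}

#' Configuration of a synthetic two-group sleep-EEG cohort
#'
#' Defaults mirror the study conditions the pipeline targets: two groups of
#' 17 subjects, 19-channel 10-20 EEG (plus mastoid reference channels) at
#' 250 Hz, 30-s staged epochs, stage-dependent band-power profiles with a
#' multiplicative theta elevation (`theta_effect`) in the patient group's
#' N2 and REM sleep, and an NREM-3 microstate process over four canonical
#' topographies with group-specific transition matrices (patients: A<->B
#' reduced, C<->D elevated).
#'
#' @param n_subjects_per_group subjects per group
#' @param n_channels scalp channel count (19-channel 10-20 supported)
#' @param sampling_rate Hz
#' @param epoch_length seconds
#' @param night_minutes simulated recording length per subject
#' @param stage_band_weights stage x band matrix of relative power weights
#'   (rows sum to 1; bands delta/theta/alpha/residual)
#' @param stage_rms per-stage channel RMS amplitude in microvolts
#' @param theta_effect multiplicative factor on the patient group's theta
#'   weight in N2 and REM
#' @param subject_weight_sd log-normal SD of per-subject band-weight jitter
#' @param ms_templates planted microstate [template_set] (default: canonical
#'   maps built from the montage)
#' @param ms_transition_matrix_per_group list with `control` and `patient`
#'   K x K row-stochastic matrices, zero diagonal
#' @param ms_mean_duration mean microstate dwell time (ms)
#' @param ms_amplitude activation amplitude of the planted topographies
#'   (microvolts; see vignette for the calibration rationale)
#' @param ms_osc_freq activation oscillation frequency (Hz)
#' @param arousal_rate expected arousals per hour
#' @param seed integer RNG seed
#' @return object of class `synthetic_config`
#' @export
synthetic_config <- function(n_subjects_per_group = 17,
                             n_channels = 19,
                             sampling_rate = 250,
                             epoch_length = 30,
                             night_minutes = 480,
                             stage_band_weights = default_stage_weights(),
                             stage_rms = c(W = 15, N1 = 18, N2 = 25,
                                           N3 = 40, REM = 20),
                             theta_effect = 1.3,
                             subject_weight_sd = 0.08,
                             ms_templates = NULL,
                             ms_transition_matrix_per_group =
                               default_transition_matrices(),
                             ms_mean_duration = 90,
                             ms_amplitude = 600,
                             ms_osc_freq = 10,
                             arousal_rate = 5,
                             seed = 1) {
  if (n_subjects_per_group < 1) stop("need at least one subject per group")
  if (n_channels != 19) stop("only the 19-channel 10-20 layout is supported")
  w <- as.matrix(stage_band_weights)
  if (any(w < 0)) stop("band weights must be non-negative")
  if (any(abs(rowSums(w) - 1) > 1e-8)) stop("stage weights must sum to 1")
  if (ms_mean_duration <= 0) stop("ms_mean_duration must be positive")
  if (sampling_rate <= 2 * 30)
    stop("sampling_rate must exceed twice the highest band edge (30 Hz)")
  mont <- montage_1020(include_mastoids = TRUE)
  if (is.null(ms_templates))
    ms_templates <- make_canonical_templates(montage_1020())
  for (g in c("control", "patient")) {
    P <- ms_transition_matrix_per_group[[g]]
    if (is.null(P)) stop("transition matrix missing for group ", g)
    if (any(diag(P) != 0)) stop("transition matrix must have zero diagonal")
    if (any(P < 0) || any(abs(rowSums(P) - 1) > 1e-8))
      stop("transition matrix rows must be stochastic")
  }
  structure(list(n_subjects_per_group = n_subjects_per_group,
                 n_channels = n_channels, sampling_rate = sampling_rate,
                 epoch_length = epoch_length, night_minutes = night_minutes,
                 stage_band_weights = w, stage_rms = stage_rms,
                 theta_effect = theta_effect,
                 subject_weight_sd = subject_weight_sd,
                 ms_templates = ms_templates,
                 ms_transition_matrix_per_group =
                   ms_transition_matrix_per_group,
                 ms_mean_duration = ms_mean_duration,
                 ms_amplitude = ms_amplitude, ms_osc_freq = ms_osc_freq,
                 arousal_rate = arousal_rate, seed = as.integer(seed),
                 montage = mont),
            class = "synthetic_config")
}

#' Generate a plausible hypnogram
#'
#' Builds repeated sleep cycles (W, N1, N2, N3, N2, REM) with seeded
#' jitter on the per-stage proportions; cycles are compressed for short
#' total durations so every stage remains represented. Arousals arrive at
#' Poisson times with uniform 3-15 s lengths and are recorded only as
#' per-epoch overlap fractions (they do not alter the signal).
#'
#' @param total_minutes night length (must divide into whole epochs)
#' @param epoch_length epoch length in seconds
#' @param arousal_rate expected arousals per hour
#' @param seed RNG seed
#' @return a [hypnogram]
#' @export
make_hypnogram <- function(total_minutes, epoch_length = 30,
                           arousal_rate = 0, seed = 1) {
  if (total_minutes <= 0) stop("total_minutes must be positive")
  n_epochs <- total_minutes * 60 / epoch_length
  if (abs(n_epochs - round(n_epochs)) > 1e-9)
    stop("total_minutes must divide into whole epochs")
  n_epochs <- as.integer(round(n_epochs))
  seg_stage <- c("W", "N1", "N2", "N3", "N2", "REM")
  seg_w <- c(1, 2, 5, 6, 3, 4) / 21
  with_seed(seed, {
    n_cycles <- max(1L, as.integer(round(total_minutes / 105)))
    per_cycle <- diff(round(seq(0, n_epochs, length.out = n_cycles + 1)))
    stages <- character(0)
    for (cy in seq_len(n_cycles)) {
      w <- seg_w * runif(length(seg_w), 0.85, 1.15)
      w <- w / sum(w)
      alloc <- floor(w * per_cycle[cy])
      rem <- per_cycle[cy] - sum(alloc)
      if (rem > 0) {
        extra <- order(w * per_cycle[cy] - alloc, decreasing = TRUE)[
          seq_len(rem)]
        alloc[extra] <- alloc[extra] + 1
      }
      stages <- c(stages, rep(seg_stage, alloc))
    }
    af <- numeric(n_epochs)
    if (arousal_rate > 0) {
      hours <- total_minutes / 60
      k <- rpois(1, arousal_rate * hours)
      if (k > 0) {
        onset <- runif(k, 0, total_minutes * 60)
        len <- runif(k, 3, 15)
        for (i in seq_len(k)) {
          e0 <- floor(onset[i] / epoch_length)
          e1 <- floor(min(onset[i] + len[i], total_minutes * 60 - 1e-9) /
                        epoch_length)
          for (e in e0:e1) {
            lo <- max(onset[i], e * epoch_length)
            hi <- min(onset[i] + len[i], (e + 1) * epoch_length)
            af[e + 1] <- min(1, af[e + 1] + (hi - lo) / epoch_length)
          }
        }
      }
    }
    hypnogram(stages, af, epoch_length)
  })
}

#' Canonical microstate template maps from electrode geometry
#'
#' Builds the literature's four prototypical topographies parametrically
#' from 2-D electrode positions: A and B are the two diagonal gradients
#' (left-occipital/right-frontal and mirror image), C is the
#' anterior-posterior gradient, D a fronto-central extremum against the
#' periphery. Maps are average-referenced and unit-normalized.
#'
#' @param mont a [montage] with at least 4 positioned electrodes
#' @return a [template_set] with level "canonical" and labels A-D
#' @export
make_canonical_templates <- function(mont) {
  if (!inherits(mont, "montage")) stop("montage required")
  scalp <- setdiff(mont$labels, c("M1", "M2"))
  if (length(scalp) < 4) stop("need >= 4 positioned electrodes")
  p <- mont$positions[scalp, , drop = FALSE]
  x <- p[, "x"]; y <- p[, "y"]
  maps <- cbind(A = (x + y) / sqrt(2),
                B = (y - x) / sqrt(2),
                C = y,
                D = exp(-((x^2 + (y - 0.1)^2)) / 0.35))
  template_set(maps, labels = c("A", "B", "C", "D"), level = "canonical",
               channels = scalp)
}

#' Simulate a semi-Markov microstate label sequence
#'
#' Dwell times are geometric with the stated mean (memoryless, consistent
#' with a first-order transition matrix); successors are drawn from the
#' transition row, so consecutive runs never share a state.
#'
#' @param transition_matrix K x K row-stochastic matrix with zero diagonal
#' @param mean_duration mean dwell time in ms
#' @param n_samples sequence length
#' @param sampling_rate Hz
#' @param seed RNG seed
#' @param start optional fixed start state (default: uniform draw)
#' @return integer vector of state indices (1..K), length `n_samples`
#' @export
simulate_microstate_sequence <- function(transition_matrix, mean_duration,
                                         n_samples, sampling_rate, seed = 1,
                                         start = NULL) {
  P <- as.matrix(transition_matrix)
  K <- nrow(P)
  if (ncol(P) != K) stop("transition matrix must be square")
  if (any(diag(P) != 0)) stop("transition matrix must have zero diagonal")
  if (any(P < 0) || any(abs(rowSums(P) - 1) > 1e-8))
    stop("rows must be stochastic")
  m <- mean_duration / 1000 * sampling_rate
  if (m < 2) stop("mean_duration must be at least 2 samples")
  with_seed(seed, {
    # draw generously many runs, extend if needed
    labels <- integer(0)
    state <- if (is.null(start)) sample.int(K, 1) else as.integer(start)
    total <- 0L
    while (total < n_samples) {
      nrun <- max(64L, ceiling((n_samples - total) / m * 1.5))
      dwell <- 1L + rgeom(nrun, prob = 1 / m)
      for (d in dwell) {
        labels <- c(labels, list(rep.int(state, d)))
        total <- total + d
        state <- sample.int(K, 1, prob = P[state, ])
        if (total >= n_samples) break
      }
    }
    unlist(labels)[seq_len(n_samples)]
  })
}

band_edges <- function() {
  list(delta = c(0.5, 4), theta = c(4, 8), alpha = c(8, 12),
       residual = c(12, 30))
}

# band-limited unit-variance noise sources synthesized in the frequency
# domain: random-phase spectrum supported on [low, high] Hz only
band_noise_sources <- function(n, fs, low, high, n_src) {
  freqs <- seq(0, fs, length.out = n + 1)[seq_len(n)]
  sel <- which((freqs >= low & freqs <= high) |
                 (freqs >= fs - high & freqs <= fs - low))
  out <- matrix(0, n, n_src)
  for (j in seq_len(n_src)) {
    spec <- complex(real = rep(0, n), imaginary = rep(0, n))
    half <- sel[freqs[sel] <= fs / 2]
    amp <- rnorm(length(half)); ph <- runif(length(half), 0, 2 * pi)
    spec[half] <- complex(modulus = abs(amp), argument = ph)
    # hermitian counterpart
    idx <- half[half > 1]
    spec[n - idx + 2] <- Conj(spec[idx])
    s <- Re(stats::fft(spec, inverse = TRUE)) / n
    out[, j] <- s / stats::sd(s)
  }
  out
}

# smooth random spatial mixing patterns over electrode positions
smooth_patterns <- function(pos, n_src) {
  x <- pos[, "x"]; y <- pos[, "y"]
  basis <- cbind(1, x, y, x * y, x^2 - mean(x^2), y^2 - mean(y^2))
  A <- basis %*% matrix(rnorm(ncol(basis) * n_src), ncol = n_src)
  sweep(A, 2, sqrt(colMeans(A^2)), "/")
}

# Band mixing = stereotyped band topography shared by all subjects (drawn
# from a fixed per-band seed) plus a milder individual perturbation, so
# channel-level band-power profiles are consistent across subjects the way
# scalp band topographies are, while subjects still differ.
band_mixing <- function(pos, n_src, band_index, individual_sd = 0.35) {
  shared <- with_seed(151200 + band_index, smooth_patterns(pos, n_src))
  indiv <- smooth_patterns(pos, n_src)      # subject RNG stream
  A <- shared + individual_sd * indiv
  sweep(A, 2, sqrt(colMeans(A^2)), "/")
}

#' Simulate one subject's night of EEG
#'
#' Per stage-epoch the scalp signal is the sum of band-limited,
#' channel-correlated noise components scaled by the stage's band weights
#' (theta multiplied by `theta_effect` for patients in N2 and REM); NREM-3
#' epochs add the planted microstate component. Mastoid reference channels
#' (M1, M2) carry low-amplitude independent noise.
#'
#' @param hyp a [hypnogram]
#' @param config a [synthetic_config]
#' @param group "patient" or "control"
#' @param seed RNG seed
#' @return list with `recording` (an [eeg_recording] with 21 channels) and
#'   `truth` (realized N3 label sequence, N3 sample indices, realized band
#'   weights)
#' @export
simulate_eeg <- function(hyp, config, group, seed = 1) {
  group <- match.arg(group, c("patient", "control"))
  fs <- config$sampling_rate
  L <- as.integer(config$epoch_length * fs)
  n_ep <- nrow(hyp)
  n <- n_ep * L
  mont <- config$montage
  scalp <- setdiff(mont$labels, c("M1", "M2"))
  nch <- length(scalp)
  stages_present <- unique(hyp$stage)
  missing_w <- setdiff(stages_present, rownames(config$stage_band_weights))
  if (length(missing_w))
    stop("stage(s) missing from stage_band_weights: ",
         paste(missing_w, collapse = ", "))
  bands <- band_edges()
  with_seed(seed, {
    # per-subject realized band weights (log-normal jitter, stage x band)
    jit <- exp(matrix(rnorm(nrow(config$stage_band_weights) * length(bands),
                            0, config$subject_weight_sd),
                      nrow(config$stage_band_weights)))
    w_real <- config$stage_band_weights * jit
    dimnames(w_real) <- dimnames(config$stage_band_weights)
    if (group == "patient")
      w_real[c("N2", "REM"), "theta"] <-
        w_real[c("N2", "REM"), "theta"] * config$theta_effect
    X <- matrix(0, nch, n)
    stage_of_sample <- rep(hyp$stage, each = L)
    for (b in names(bands)) {
      src <- band_noise_sources(n, fs, bands[[b]][1], bands[[b]][2], 6)
      A <- band_mixing(mont$positions[scalp, , drop = FALSE], 6,
                       match(b, names(bands)))
      comp <- A %*% t(src)
      comp <- comp / sqrt(mean(comp^2))
      scale <- sqrt(w_real[stage_of_sample, b]) *
        config$stage_rms[stage_of_sample]
      X <- X + sweep(comp, 2, scale, "*")
    }
    # planted microstate component in N3
    n3_ep <- which(hyp$stage == "N3")
    n3_idx <- integer(0)
    ms_labels <- integer(0)
    if (length(n3_ep)) {
      n3_idx <- as.integer(outer(seq_len(L), (n3_ep - 1) * L, `+`))
      P <- config$ms_transition_matrix_per_group[[group]]
      ms_labels <- simulate_microstate_sequence(
        P, config$ms_mean_duration, length(n3_idx), fs,
        seed = sample.int(.Machine$integer.max - 1, 1))
      r <- rle(ms_labels)
      act <- numeric(length(ms_labels))
      pos <- 0L
      for (i in seq_along(r$lengths)) {
        d <- r$lengths[i]
        tt <- seq_len(d) / fs
        act[pos + seq_len(d)] <- sin(2 * pi * config$ms_osc_freq * tt +
                                       runif(1, 0, 2 * pi))
        pos <- pos + d
      }
      Tm <- config$ms_templates$maps[scalp, , drop = FALSE]
      X[, n3_idx] <- X[, n3_idx] +
        Tm[, ms_labels, drop = FALSE] *
        rep(config$ms_amplitude * act, each = nch)
    }
    mast <- matrix(rnorm(2 * n, 0, 2), 2, n)
    data <- rbind(X, mast)
    rec <- eeg_recording(data, fs, c(scalp, "M1", "M2"), mont)
    list(recording = rec,
         truth = list(ms_labels = ms_labels, n3_sample_index = n3_idx,
                      weights = w_real, group = group))
  })
}

#' Simulate a full two-group cohort
#'
#' One recording and hypnogram per subject, with per-subject seeds derived
#' deterministically from the configuration seed.
#'
#' @param config a [synthetic_config]
#' @return object of class `synthetic_cohort`: lists `recordings`,
#'   `hypnograms`, named `group_labels` (subject -> patient/control),
#'   `truth` (config plus per-subject truth records)
#' @export
simulate_cohort <- function(config) {
  n <- config$n_subjects_per_group
  ids <- c(sprintf("C%02d", seq_len(n)), sprintf("P%02d", seq_len(n)))
  groups <- stats::setNames(rep(c("control", "patient"), each = n), ids)
  seeds <- with_seed(config$seed,
                     matrix(sample.int(.Machine$integer.max - 1, 2 * 2 * n),
                            ncol = 2))
  recordings <- hypnograms <- truths <- stats::setNames(
    vector("list", length(ids)), ids)
  for (i in seq_along(ids)) {
    hyp <- make_hypnogram(config$night_minutes, config$epoch_length,
                          config$arousal_rate, seed = seeds[i, 1])
    sim <- simulate_eeg(hyp, config, groups[[i]], seed = seeds[i, 2])
    recordings[[i]] <- sim$recording
    hypnograms[[i]] <- hyp
    truths[[i]] <- sim$truth
  }
  structure(list(recordings = recordings, hypnograms = hypnograms,
                 group_labels = groups,
                 truth = list(config = config, subjects = truths)),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d subjects (%d patient / %d control)\n",
              length(x$recordings), sum(x$group_labels == "patient"),
              sum(x$group_labels == "control")))
  invisible(x)
}

#' Write a cohort to a directory / load it back
#'
#' Recordings are written as EDF, hypnograms as CSV, group membership as
#' `groups.csv`; the ground truth goes to a JSON sidecar (without the raw
#' label sequences, which are reproducible from the config seed).
#'
#' @param cohort a `synthetic_cohort`
#' @param dir target directory (created if needed)
#' @return `dir` (write) / a `synthetic_cohort` without truth (load)
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- names(cohort$recordings)
  for (id in ids) {
    write_edf(cohort$recordings[[id]], file.path(dir, paste0(id, ".edf")))
    write_hypnogram(cohort$hypnograms[[id]],
                    file.path(dir, paste0(id, "_hypnogram.csv")))
  }
  utils::write.csv(data.frame(subject = ids,
                              group = unname(cohort$group_labels[ids])),
                   file.path(dir, "groups.csv"), row.names = FALSE)
  cfg <- cohort$truth$config
  meta <- list(seed = cfg$seed, n_subjects_per_group = cfg$n_subjects_per_group,
               sampling_rate = cfg$sampling_rate,
               night_minutes = cfg$night_minutes,
               theta_effect = cfg$theta_effect,
               ms_mean_duration = cfg$ms_mean_duration)
  jsonlite::write_json(meta, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_cohort
#' @param epoch_length epoch length (s) for the hypnograms
#' @export
load_cohort <- function(dir, epoch_length = 30) {
  gt <- utils::read.csv(file.path(dir, "groups.csv"),
                        stringsAsFactors = FALSE)
  ids <- gt$subject
  recordings <- hypnograms <- stats::setNames(vector("list", length(ids)),
                                              ids)
  for (id in ids) {
    recordings[[id]] <- read_edf(file.path(dir, paste0(id, ".edf")))
    hypnograms[[id]] <- read_hypnogram(
      file.path(dir, paste0(id, "_hypnogram.csv")), epoch_length)
  }
  structure(list(recordings = recordings, hypnograms = hypnograms,
                 group_labels = stats::setNames(gt$group, ids),
                 truth = NULL),
            class = "synthetic_cohort")
}
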