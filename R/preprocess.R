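# Reading, filtering, downsampling, re-referencing and stage-labelled
# epoching. Filtering follows the study recipe: windowed-sinc (Hamming)
# linear-phase FIR, applied forward and backward for zero net phase. The
# nominal order (1000) refers to the 1 kHz acquisition rate; when filtering
# at a lower rate the order is scaled by the rate ratio so the impulse
# response keeps its duration.

fir_kernel <- function(low, high, order, fs) {
  h <- signal::fir1(order, c(low, high) / (fs / 2), type = "pass")
  # forward + backward pass == single convolution with h * rev(h)
  stats::convolve(h, h, type = "open")
}

#' Zero-phase band-pass FIR filter
#'
#' Two-way (forward-backward) application of a Hamming-window FIR band-pass,
#' implemented as one FFT convolution with the filter's autocorrelation
#' kernel. Output length equals input length; the first and last `order`
#' samples contain edge transients (they are excluded from epoching by
#' [segment_epochs] when `edge_samples` is passed).
#'
#' @param rec an [eeg_recording]
#' @param low,high band edges in Hz (0 < low < high < Nyquist)
#' @param order FIR order at the nominal 1 kHz acquisition rate; scaled by
#'   `rec$srate / 1000` before use
#' @return filtered [eeg_recording]
#' @export
bandpass_filter <- function(rec, low, high, order = 1000) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!(low > 0 && low < high && high < rec$srate / 2))
    stop("need 0 < low < high < Nyquist")
  ord <- round(order * rec$srate / 1000)
  if (ord < 2) stop("filter order too small")
  if (ord %% 2 == 1) ord <- ord + 1
  g <- fir_kernel(low, high, ord, rec$srate)
  Y <- fir_filt_cpp(t(rec$data), g)
  out <- eeg_recording(t(Y), rec$srate, rec$labels, rec$montage)
  attr(out, "filter") <- list(low = low, high = high, order = ord)
  out
}

#' Downsample a recording
#'
#' Integer-factor decimation preceded by a zero-phase anti-alias low-pass
#' (cutoff at 80% of the new Nyquist). `target == srate` is the identity.
#'
#' @param rec an [eeg_recording]
#' @param target new sampling rate (must divide `rec$srate`)
#' @return resampled [eeg_recording]
#' @export
downsample <- function(rec, target) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (target > rec$srate) stop("target rate above the sampling rate")
  if (target == rec$srate) return(rec)
  fac <- rec$srate / target
  if (abs(fac - round(fac)) > 1e-9)
    stop("target must divide the sampling rate")
  fac <- round(fac)
  ord <- max(60, round(10 * fac) * 2)
  h <- signal::fir1(ord, 0.8 / fac)
  g <- stats::convolve(h, h, type = "open")
  Y <- fir_filt_cpp(t(rec$data), g)
  sel <- seq(1, nrow(Y), by = fac)
  eeg_recording(t(Y[sel, , drop = FALSE]), target, rec$labels, rec$montage)
}

#' Re-reference a recording
#'
#' `linked-mastoid`: subtract the per-sample mean of M1 and M2, then drop
#' both mastoid channels. `average`: subtract the per-sample mean over all
#' retained channels, so data sum to zero across channels at every sample.
#'
#' @param rec an [eeg_recording]
#' @param scheme "linked-mastoid" or "average"
#' @param drop_mastoids for the average scheme, drop M1/M2 (if present)
#'   before averaging
#' @return re-referenced [eeg_recording]
#' @export
rereference <- function(rec, scheme = c("linked-mastoid", "average"),
                        drop_mastoids = TRUE) {
  scheme <- match.arg(scheme)
  X <- rec$data
  labels <- rec$labels
  if (scheme == "linked-mastoid") {
    if (!all(c("M1", "M2") %in% labels))
      stop("linked-mastoid reference requires channels M1 and M2")
    ref <- colMeans(X[c("M1", "M2"), , drop = FALSE])
    keep <- setdiff(labels, c("M1", "M2"))
    X <- sweep(X[keep, , drop = FALSE], 2, ref)
    labels <- keep
  } else {
    if (drop_mastoids && any(c("M1", "M2") %in% labels)) {
      labels <- setdiff(labels, c("M1", "M2"))
      X <- X[labels, , drop = FALSE]
    }
    X <- sweep(X, 2, colMeans(X))
  }
  eeg_recording(X, rec$srate, labels, rec$montage)
}

#' Cut a recording into stage-labelled, artifact-screened epochs
#'
#' Epoch k (0-based) covers samples `[k*L, (k+1)*L)`. An epoch is excluded
#' iff its arousal fraction strictly exceeds `arousal_threshold` ("more
#' than" the threshold share of the scored epoch); epochs overlapping the
#' first or last `edge_samples` samples (filter transients) are also
#' dropped. Exclusion counts are recorded per stage.
#'
#' @param rec an [eeg_recording]
#' @param hyp a [hypnogram]; the recording must cover all its epochs
#'   (one-epoch tolerance at the end)
#' @param arousal_threshold fraction above which an epoch is rejected
#' @param edge_samples number of edge samples to protect (e.g. the filter
#'   order)
#' @param demean subtract each epoch's per-channel mean
#' @param detrend remove a per-channel linear trend per epoch
#' @return object of class `epoch_set`: list with `stages` (stage ->
#'   list of channels x L matrices), `epoch_ids`, `excluded` (per-stage
#'   counts), `provenance`
#' @export
segment_epochs <- function(rec, hyp, arousal_threshold = 0.15,
                           edge_samples = 0, demean = FALSE,
                           detrend = FALSE) {
  L <- as.integer(attr(hyp, "epoch_length") * rec$srate)
  n_ep <- nrow(hyp)
  if (n_ep * L > n_samples(rec) + L)
    stop("hypnogram longer than the recording")
  stages <- unique(hyp$stage)
  out <- stats::setNames(lapply(stages, function(s) list()), stages)
  ids <- stats::setNames(lapply(stages, function(s) integer(0)), stages)
  excluded <- stats::setNames(rep(0L, length(stages)), stages)
  for (e in seq_len(n_ep)) {
    a <- (e - 1L) * L + 1L
    b <- e * L
    if (b > n_samples(rec)) break
    s <- hyp$stage[e]
    if (hyp$arousal_fraction[e] > arousal_threshold ||
        a <= edge_samples || b > n_samples(rec) - edge_samples) {
      excluded[s] <- excluded[s] + 1L
      next
    }
    M <- rec$data[, a:b, drop = FALSE]
    if (demean) M <- M - rowMeans(M)
    if (detrend) {
      tt <- seq_len(L) - (L + 1) / 2
      beta <- (M %*% tt) / sum(tt^2)
      M <- M - tcrossprod(beta, tt)
    }
    out[[s]] <- c(out[[s]], list(M))
    ids[[s]] <- c(ids[[s]], e - 1L)
  }
  structure(list(stages = out, epoch_ids = ids, excluded = excluded,
                 srate = rec$srate, labels = rec$labels,
                 provenance = list(filter = attr(rec, "filter"),
                                   arousal_threshold = arousal_threshold,
                                   edge_samples = edge_samples)),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cnt <- vapply(x$stages, length, 0L)
  cat("<epoch_set>",
      paste(names(cnt), cnt, sep = ":", collapse = " "),
      sprintf("(excluded: %d)\n", sum(x$excluded)))
  invisible(x)
}
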