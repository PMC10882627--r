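#' EEG recording container
#'
#' @param data numeric matrix, channels x samples, in microvolts
#' @param srate sampling rate in Hz
#' @param labels channel labels (length = nrow(data))
#' @param montage a [montage] covering at least the scalp channels, or NULL
#' @return object of class `eeg_recording`
#' @export
eeg_recording <- function(data, srate, labels, montage = NULL) {
  data <- as.matrix(data)
  if (!is.numeric(data) || anyNA(data) || any(!is.finite(data)))
    stop("data must be a finite numeric matrix")
  if (length(labels) != nrow(data))
    stop("channel count (", nrow(data), ") != label count (",
         length(labels), ")")
  if (!is.numeric(srate) || srate <= 0) stop("sampling_rate must be > 0")
  rownames(data) <- labels
  structure(list(data = data, srate = srate, labels = as.character(labels),
                 montage = montage),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d ch x %d samples @ %g Hz (%.1f min)\n",
              nrow(x$data), ncol(x$data), x$srate,
              ncol(x$data) / x$srate / 60))
  invisible(x)
}

n_samples <- function(rec) ncol(rec$data)

#' Hypnogram container
#'
#' Ordered 30-s (by default) sleep-stage epochs with per-epoch arousal
#' fractions. Stages use the fixed vocabulary W, N1, N2, N3, REM.
#'
#' @param stages character vector of stage labels
#' @param arousal_fraction numeric in \[0, 1\], same length (default 0)
#' @param epoch_length epoch length in seconds
#' @return object of class `hypnogram`: data.frame with columns
#'   `epoch_index` (0-based), `stage`, `arousal_fraction`
#' @export
hypnogram <- function(stages, arousal_fraction = 0, epoch_length = 30) {
  stages <- as.character(stages)
  bad <- setdiff(unique(stages), c("W", "N1", "N2", "N3", "REM"))
  if (length(bad)) stop("unknown stages: ", paste(bad, collapse = ", "))
  af <- rep_len(arousal_fraction, length(stages))
  if (any(af < 0 | af > 1)) stop("arousal_fraction must lie in [0, 1]")
  out <- data.frame(epoch_index = seq_along(stages) - 1L, stage = stages,
                    arousal_fraction = af)
  attr(out, "epoch_length") <- epoch_length
  class(out) <- c("hypnogram", "data.frame")
  out
}

#' @export
print.hypnogram <- function(x, ...) {
  tb <- table(x$stage)
  cat(sprintf("<hypnogram> %d x %gs epochs (%s)\n", nrow(x),
              attr(x, "epoch_length"),
              paste(names(tb), tb, sep = ":", collapse = " ")))
  invisible(x)
}

#' Write / read a hypnogram as CSV
#'
#' Columns: `epoch_index`, `stage`, `arousal_fraction`.
#' @param hyp a [hypnogram]
#' @param path file path
#' @param epoch_length epoch length (s) used when reading
#' @export
write_hypnogram <- function(hyp, path) {
  utils::write.csv(as.data.frame(hyp)[c("epoch_index", "stage",
                                        "arousal_fraction")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hypnogram
#' @export
read_hypnogram <- function(path, epoch_length = 30) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  hypnogram(df$stage, df$arousal_fraction, epoch_length)
}
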