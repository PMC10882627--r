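# Minimal EDF (European Data Format) reader/writer.
#
# Supports the continuous-recording subset used here: identical sampling
# rate on every signal, 16-bit samples, 1-s data records. This is not a
# general-purpose EDF library; it exists because the pipeline's on-disk
# interchange format for recordings is EDF and no reader is otherwise
# available to the package.

edf_pad <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = width, flag = "-")
}

#' Write a recording to an EDF file
#'
#' Voltages are scaled per channel to the full signed 16-bit range; the
#' physical extrema are stored in the header, so the round-trip error is at
#' most half a quantization step. The recording is truncated to a whole
#' number of 1-second data records.
#'
#' @param rec an [eeg_recording]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$srate
  if (fs != round(fs)) stop("write_edf requires an integer sampling rate")
  ns <- nrow(rec$data)
  nrec <- floor(ncol(rec$data) / fs)
  if (nrec < 1) stop("recording shorter than one data record")
  X <- rec$data[, seq_len(nrec * fs), drop = FALSE]
  pmin_ <- apply(X, 1, min)
  pmax_ <- apply(X, 1, max)
  span <- pmax_ - pmin_
  pmin_[span == 0] <- pmin_[span == 0] - 1
  pmax_[span == 0] <- pmax_[span == 0] + 1
  dmin <- -32768; dmax <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, w) writeChar(paste0(edf_pad(s, w), collapse = ""), con,
                                 eos = NULL)
  wr("0", 8)                                   # version
  wr("X X X X", 80)                            # patient id (anonymous)
  wr("Startdate X X X X", 80)                  # recording id
  wr("01.01.00", 8); wr("00.00.00", 8)         # date, time
  wr(as.character(256 * (ns + 1)), 8)          # header bytes
  wr("", 44)                                   # reserved
  wr(as.character(nrec), 8)
  wr("1", 8)                                   # record duration (s)
  wr(as.character(ns), 4)
  for (l in rec$labels) wr(l, 16)
  for (i in seq_len(ns)) wr("", 80)            # transducer
  for (i in seq_len(ns)) wr("uV", 8)
  for (v in pmin_) wr(formatC(v, format = "g", digits = 7), 8)
  for (v in pmax_) wr(formatC(v, format = "g", digits = 7), 8)
  for (i in seq_len(ns)) wr(as.character(dmin), 8)
  for (i in seq_len(ns)) wr(as.character(dmax), 8)
  for (i in seq_len(ns)) wr("", 80)            # prefiltering
  for (i in seq_len(ns)) wr(as.character(fs), 8)
  for (i in seq_len(ns)) wr("", 32)            # reserved
  gain <- (pmax_ - pmin_) / (dmax - dmin)
  for (r in seq_len(nrec)) {
    sel <- ((r - 1) * fs + 1):(r * fs)
    for (i in seq_len(ns)) {
      dig <- round((X[i, sel] - pmin_[i]) / gain[i] + dmin)
      writeBin(as.integer(pmin(pmax(dig, dmin), dmax)), con, size = 2,
               endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF recording
#'
#' Reads the continuous 16-bit EDF subset written by [write_edf] (equal
#' sampling rates across signals). Channel labels are matched against the
#' standard 10-20 montage; unknown labels are an error unless a `montage`
#' covering them is supplied.
#'
#' @param path EDF file path
#' @param montage optional [montage] overriding the 10-20 lookup
#' @return an [eeg_recording]
#' @export
read_edf <- function(path, montage = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  ver <- rd(8)
  if (!identical(ver, "0")) stop("unreadable EDF header (version '", ver, "')")
  rd(80); rd(80); rd(8); rd(8)
  hdr_bytes <- as.integer(rd(8))
  rd(44)
  nrec <- as.integer(rd(8))
  dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1) stop("EDF file contains no signals")
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(80)
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(32)
  if (length(unique(spr)) != 1)
    stop("mixed sampling rates are not supported")
  fs <- spr[1] / dur
  seek(con, hdr_bytes)
  gain <- (pmax_ - pmin_) / (dmax - dmin)
  X <- matrix(0, ns, nrec * spr[1])
  for (r in seq_len(nrec)) {
    block <- readBin(con, "integer", n = ns * spr[1], size = 2,
                     endian = "little")
    sel <- ((r - 1) * spr[1] + 1):(r * spr[1])
    X[, sel] <- matrix(block, nrow = spr[1])[, seq_len(ns)] |> t()
    # block is stored signal-major: spr samples of signal 1, then signal 2...
  }
  X <- X * gain + (pmin_ - dmin * gain)
  if (is.null(montage)) {
    std <- montage_1020(include_mastoids = TRUE)
    unknown <- setdiff(labels, std$labels)
    if (length(unknown))
      stop("unknown channel label(s) ", paste(unknown, collapse = ", "),
           " and no montage supplied")
    montage <- std
  } else {
    unknown <- setdiff(labels, montage$labels)
    if (length(unknown))
      stop("montage does not position ", paste(unknown, collapse = ", "))
  }
  eeg_recording(X, fs, labels, montage)
}

#' @rdname read_edf
#' @export
read_recording <- read_edf
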