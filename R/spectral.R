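# Multitaper (DPSS) power spectral density, band powers, and subject-level
# relative power tables per sleep stage.

.dpss_cache <- new.env(parent = emptyenv())

#' DPSS (Slepian) tapers and their spectral concentrations
#'
#' Computes the `K` most concentrated discrete prolate spheroidal sequences
#' of length `n` for time-half-bandwidth product `nw`, together with each
#' taper's in-band energy concentration lambda (used as averaging weights).
#' Results are cached per `(n, nw, K)`.
#'
#' @param n taper length in samples
#' @param nw time-half-bandwidth product (W = nw/n cycles per sample)
#' @param K number of tapers (default `2*nw - 1`)
#' @return list with `tapers` (n x K, orthonormal columns) and
#'   `eigenvalues` (concentrations in \[0, 1\])
#' @export
dpss_tapers <- function(n, nw, K = max(1, floor(2 * nw) - 1)) {
  if (K < 1) stop("need at least one taper (increase the half-bandwidth)")
  key <- sprintf("%d_%g_%d", n, nw, K)
  hit <- .dpss_cache[[key]]
  if (!is.null(hit)) return(hit)
  V <- dpss_cpp(as.integer(n), nw, as.integer(K))
  # concentration lambda_k = v' S v with S the sinc kernel matrix,
  # evaluated exactly via FFT convolution
  W <- nw / n
  m <- seq_len(n - 1)
  kern <- c(2 * W, sin(2 * pi * W * m) / (pi * m))
  # S v for the symmetric Toeplitz sinc matrix via circulant embedding
  mfft <- stats::nextn(2 * n - 1, 2)
  kfull <- numeric(mfft)
  kfull[1:n] <- kern
  kfull[mfft - seq_len(n - 1) + 1] <- kern[-1]
  Kf <- stats::fft(kfull)
  lam <- vapply(seq_len(K), function(k) {
    v <- V[, k]
    sv <- Re(stats::fft(stats::fft(c(v, numeric(mfft - n))) * Kf,
                        inverse = TRUE)) / mfft
    sum(v * sv[1:n])
  }, 0)
  out <- list(tapers = V, eigenvalues = pmin(pmax(lam, 0), 1))
  .dpss_cache[[key]] <- out
  out
}

#' Multitaper power spectral density of one epoch
#'
#' Eigenvalue-weighted average of DPSS tapered periodograms, scaled as a
#' one-sided density (uV^2/Hz) whose integral over frequency equals the
#' signal variance.
#'
#' @param epoch channels x samples matrix
#' @param srate sampling rate in Hz
#' @param half_bandwidth spectral half-bandwidth in Hz (default 0.5,
#'   resolving the 0.5 Hz delta edge on 30-s epochs)
#' @return object of class `power_spectrum`: list with `frequencies` (Hz),
#'   `power` (channels x frequencies density matrix), `taper_count`
#' @export
multitaper_psd <- function(epoch, srate, half_bandwidth = 0.5) {
  epoch <- as.matrix(epoch)
  n <- ncol(epoch)
  if (n < 2 * srate) stop("epoch must be at least 2 s long")
  nw <- half_bandwidth * n / srate
  K <- max(1, floor(2 * nw) - 1)
  if (K < 1) stop("half_bandwidth too small for this epoch length")
  dp <- dpss_tapers(n, nw, K)
  w <- dp$eigenvalues / sum(dp$eigenvalues)
  P <- mtm_power_cpp(t(epoch), dp$tapers, w)      # (n/2+1) x channels
  # density scaling: two-sided |X|^2/(fs) folded one-sided
  P <- P / srate
  nf <- nrow(P)
  dbl <- rep(2, nf)
  dbl[1] <- 1
  if (n %% 2 == 0) dbl[nf] <- 1
  P <- P * dbl
  freqs <- seq(0, srate / 2, length.out = nf)
  structure(list(frequencies = freqs, power = t(P), taper_count = K,
                 srate = srate),
            class = "power_spectrum")
}

#' Band power from a power spectrum
#'
#' Trapezoidal integral of the one-sided density over `[low, high]`, with
#' linear interpolation at band edges that fall between grid points;
#' adjacent bands are exactly additive.
#'
#' @param ps a `power_spectrum`
#' @param low,high band edges in Hz (within the spectrum's range)
#' @return named numeric vector, one power value per channel (uV^2)
#' @export
band_power <- function(ps, low, high) {
  f <- ps$frequencies
  if (low < f[1] - 1e-9 || high > f[length(f)] + 1e-9 || low >= high)
    stop("band outside the spectrum's frequency range")
  grid <- sort(unique(c(low, high, f[f > low & f < high])))
  P <- apply(ps$power, 1, function(p) {
    y <- stats::approx(f, p, xout = grid)$y
    sum(diff(grid) * (head(y, -1) + tail(y, -1)) / 2)
  })
  P
}

#' Relative band powers for one epoch spectrum
#'
#' Divides each band's power by the total power over the analysed range
#' (default 0.5-30 Hz, the spectral-arm filter band), giving the share of
#' power per band in \[0, 1\].
#'
#' @param ps a `power_spectrum`
#' @param bands named list of `c(low, high)` band edges
#' @param total_range range over which the normalizing total power is taken
#' @return list with `relative` and `absolute` (band x channel matrices);
#'   channels with zero total power are flagged via the `dropped` attribute
#' @export
relative_power <- function(ps, bands = spectral_bands(),
                           total_range = c(0.5, 30)) {
  abs_p <- do.call(rbind, lapply(bands, function(b)
    band_power(ps, b[1], b[2])))
  rownames(abs_p) <- names(bands)
  total <- band_power(ps, total_range[1], total_range[2])
  bad <- total <= 0
  total[bad] <- NA_real_
  rel <- sweep(abs_p, 2, total, "/")
  out <- list(relative = rel, absolute = abs_p, total = total)
  attr(out, "dropped") <- which(bad)
  out
}

#' Standard sleep band definitions
#'
#' delta 0.5-4 Hz, theta 4-8 Hz, alpha 8-12 Hz. Beta is deliberately not
#' analysed.
#' @return named list of `c(low, high)` pairs
#' @export
spectral_bands <- function() {
  list(delta = c(0.5, 4), theta = c(4, 8), alpha = c(8, 12))
}

#' Subject-level band-power table for a set of epoched subjects
#'
#' For every subject, stage, channel and band: the unweighted mean over the
#' subject's retained epochs of per-epoch relative (and absolute) band
#' power. Returns a tidy data.frame plus per-(stage, band) channel-wise
#' group difference maps (mean patients minus mean controls).
#'
#' @param epoch_sets named list (subject -> `epoch_set`)
#' @param groups named character vector (subject -> "patient"/"control")
#' @param stages sleep stages to evaluate
#' @param bands named band list, see [spectral_bands]
#' @param half_bandwidth multitaper half-bandwidth (Hz)
#' @param total_range normalization range for relative power
#' @return list with `table` (tidy data.frame: subject, group, stage,
#'   channel, band, rel_power, abs_power) and `difference` (stage ->
#'   band -> named channel vector), `n_epochs` bookkeeping
#' @export
stage_group_table <- function(epoch_sets, groups,
                              stages = c("N1", "N2", "N3", "REM"),
                              bands = spectral_bands(),
                              half_bandwidth = 0.5,
                              total_range = c(0.5, 30)) {
  subjects <- names(epoch_sets)
  rows <- list()
  n_epochs <- list()
  for (sid in subjects) {
    es <- epoch_sets[[sid]]
    chans <- setdiff(es$labels, c("M1", "M2"))
    for (st in intersect(stages, names(es$stages))) {
      eps <- es$stages[[st]]
      if (!length(eps)) next
      rel_sum <- abs_sum <- 0
      for (M in eps) {
        ps <- multitaper_psd(M[chans, , drop = FALSE], es$srate,
                             half_bandwidth)
        rp <- relative_power(ps, bands, total_range)
        rel_sum <- rel_sum + rp$relative
        abs_sum <- abs_sum + rp$absolute
      }
      rel <- rel_sum / length(eps)
      abs_ <- abs_sum / length(eps)
      n_epochs[[paste(sid, st)]] <- length(eps)
      for (b in names(bands))
        rows[[length(rows) + 1]] <- data.frame(
          subject = sid, group = unname(groups[sid]), stage = st,
          channel = chans, band = b, rel_power = rel[b, ],
          abs_power = abs_[b, ], row.names = NULL)
    }
  }
  tab <- do.call(rbind, rows)
  diff_maps <- list()
  for (st in stages) {
    diff_maps[[st]] <- list()
    for (b in names(bands)) {
      sub <- tab[tab$stage == st & tab$band == b, ]
      if (!nrow(sub)) { diff_maps[[st]][[b]] <- NULL; next }
      agg <- function(g) {
        s2 <- sub[sub$group == g, ]
        if (!nrow(s2)) return(NULL)
        tapply(s2$rel_power, s2$channel, mean)
      }
      mp <- agg("patient"); mc <- agg("control")
      diff_maps[[st]][[b]] <- if (is.null(mp) || is.null(mc)) NULL
        else mp[names(mc)] - mc
    }
  }
  list(table = tab, difference = diff_maps, n_epochs = n_epochs)
}
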