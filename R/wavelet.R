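# Morlet wavelet band power.

# Complex Morlet coefficients via frequency-domain Gaussian windows.
# n_cycles fixes the mother-wavelet width: sigma_t = n_cycles / (2 pi fc),
# i.e. sigma_f = fc / n_cycles. L2 normalization is immaterial here since
# every downstream use renormalizes; the same constant is applied to all
# center frequencies.
morlet_power_matrix <- function(x, fs, centers, n_cycles = 4) {
  n <- length(x)
  nf <- stats::nextn(n, factors = 2)
  X <- stats::fft(c(x - mean(x), numeric(nf - n)))
  f <- (seq_len(nf) - 1) / nf * fs
  pos <- f <= fs / 2
  out <- matrix(0, n, length(centers))
  for (j in seq_along(centers)) {
    fc <- centers[j]
    sf <- fc / n_cycles
    H <- numeric(nf)
    H[pos] <- 2 * exp(-((f[pos] - fc)^2) / (2 * sf^2))
    w <- stats::fft(X * H, inverse = TRUE)[seq_len(n)] / nf
    out[, j] <- Mod(w)^2
  }
  out
}

#' Band power traces by Morlet wavelet transform
#'
#' Computes, for each requested band, the mean squared Morlet coefficient
#' magnitude across center frequencies spaced 0.5 Hz apart (four-cycle
#' wavelets), down-sampled to `fs_out` (10 Hz) by block averaging. The
#' input is decimated to `work_fs` first, which is transparent for band
#' edges up to 40% of `work_fs`. Normalized traces divide each band by the
#' sum across bands of the band means within NREMS (NREMS and MA epochs),
#' expressing bands as relative contributions.
#'
#' @param rec a `psg_recording` or numeric vector.
#' @param hyp matching [hypnogram()].
#' @param channel channel name.
#' @param bands named list of `c(lo, hi)` bands (default delta, sigma,
#'   beta, low gamma).
#' @param fs_out output rate, Hz.
#' @param work_fs internal analysis rate after decimation, Hz.
#' @param fs sampling rate when `rec` is a plain vector.
#' @param n_cycles Morlet cycles.
#' @return object of class `band_traces`: `t`, `fs`, `raw` and `norm`
#'   (sample x band matrices), `mask` (NREMS or MA).
#' @export
band_power_traces <- function(rec, hyp, channel = "eeg",
                              bands = band_definitions()[c("delta", "sigma",
                                                           "beta",
                                                           "low_gamma")],
                              fs_out = 10, work_fs = 100, fs = NULL,
                              n_cycles = 4) {
  if (inherits(rec, "psg_recording")) {
    if (!channel %in% names(rec$signals)) stop("channel '", channel,
                                               "' absent from recording")
    x <- rec$signals[[channel]]
    fs <- rec$fs
  } else x <- rec
  hi_edge <- max(vapply(bands, max, 1))
  if (work_fs < 2.5 * hi_edge) work_fs <- fs   # no decimation margin
  if (fs < 2 * hi_edge) stop("sampling rate too low for requested bands")
  xd <- if (fs > work_fs) lowpass_decimate(x, fs, work_fs) else x
  fsd <- min(fs, work_fs)

  q <- fsd / fs_out
  n10 <- floor(length(xd) / q)
  raw <- matrix(0, n10, length(bands),
                dimnames = list(NULL, names(bands)))
  for (b in seq_along(bands)) {
    centers <- seq(bands[[b]][1], bands[[b]][2], by = 0.5)
    p <- rowMeans(morlet_power_matrix(xd, fsd, centers, n_cycles))
    raw[, b] <- colMeans(matrix(p[seq_len(n10 * q)], nrow = q))
  }
  mask <- state_at_samples(hyp, fs_out, n10) %in% c("NREMS", "MA")
  nm_means <- colMeans(raw[mask, , drop = FALSE])
  norm <- raw / sum(nm_means)
  structure(list(t = (seq_len(n10) - 1) / fs_out, fs = fs_out,
                 raw = raw, norm = norm, mask = mask),
            class = "band_traces")
}

#' @export
print.band_traces <- function(x, ...) {
  cat("<band_traces> ", nrow(x$raw), " samples @ ", x$fs, " Hz, bands: ",
      paste(colnames(x$raw), collapse = ", "), "\n", sep = "")
  invisible(x)
}
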