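# Internal signal-processing helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Analytic signal via the frequency-domain Hilbert transform
#'
#' Computes the analytic signal x + i*H(x) of a real vector using the FFT
#' one-sided spectrum method, as used for instantaneous-phase extraction.
#'
#' @param x numeric vector.
#' @return complex vector of the same length.
#' @keywords internal
#' @noRd
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# Local extrema with plateau handling: a plateau counts once, at its
# midpoint (earliest sample wins on even plateaus via floor()).
find_extrema <- function(x, type = c("max", "min")) {
  type <- match.arg(type)
  x <- as.vector(x)
  if (type == "min") x <- -x
  r <- rle(x)
  k <- length(r$values)
  if (k < 3L) return(integer(0))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  v <- r$values
  i <- 2:(k - 1L)
  hit <- i[v[i] > v[i - 1L] & v[i] > v[i + 1L]]
  as.integer(floor((starts[hit] + ends[hit]) / 2))
}

# MATLAB findpeaks-style minimum-distance pruning: candidates are kept
# greedily in decreasing height order; anything closer than min_dist
# samples to an already-kept extremum is dropped. Occupancy marking keeps
# this linear in the number of candidates.
prune_min_distance <- function(idx, height, min_dist) {
  if (length(idx) <= 1L) return(idx)
  min_dist <- max(0L, as.integer(min_dist))
  off <- min(idx) - 1L
  blocked <- logical(max(idx) - off + min_dist + 1L)
  keep <- logical(length(idx))
  for (j in order(height, decreasing = TRUE)) {
    pos <- idx[j] - off
    if (!blocked[pos]) {
      keep[j] <- TRUE
      blocked[max(1L, pos - min_dist):(pos + min_dist)] <- TRUE
    }
  }
  sort(idx[keep])
}

# Zero-phase FIR low-pass used for decimation; cutoff in Hz.
lowpass_decimate <- function(x, fs, fs_out) {
  stopifnot(fs %% fs_out == 0)
  q <- fs / fs_out
  if (q == 1) return(x)
  bf <- signal::butter(6, (0.4 * fs_out) / (fs / 2), type = "low")
  y <- signal::filtfilt(bf, x)
  y[seq(1L, length(y), by = q)]
}

# Band-limited Gaussian noise with unit variance, via single-pass IIR
# filtering of white noise (phase is immaterial for noise synthesis).
# Used by the generator and by test fixtures.
band_noise <- function(n, fs, lo, hi, order = 2) {
  # lead-in discarded so the IIR startup transient never reaches the
  # output (essential when synthesizing short segments)
  pad <- if (lo > 0) ceiling(8 * fs / max(lo, 1)) else ceiling(0.5 * fs)
  w <- stats::rnorm(n + pad)
  ny <- fs / 2
  if (lo <= 0) {
    bf <- signal::butter(order, hi / ny, type = "low")
  } else if (hi >= ny) {
    bf <- signal::butter(order, lo / ny, type = "high")
  } else {
    bf <- signal::butter(order, c(lo, hi) / ny, type = "pass")
  }
  v <- stats::filter(w, bf$b, method = "convolution", sides = 1)
  v[is.na(v)] <- 0
  y <- as.numeric(stats::filter(v, -bf$a[-1], method = "recursive"))
  y <- y[(pad + 1):(pad + n)]
  y / stats::sd(y)
}

# Runs of a logical vector as (start, end) index pairs.
logical_runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values])
}

# Brick-wall band-limited unit-variance noise via an FFT mask. Steep
# edges matter for the generator: shallow IIR skirts would leak
# state-dependent theta/beta power into the 10-15 Hz sigma estimate.
fft_band_noise <- function(n, fs, lo, hi) {
  nf <- stats::nextn(n, 2)
  W <- stats::fft(stats::rnorm(nf))
  f <- (seq_len(nf) - 1) / nf * fs
  f <- pmin(f, fs - f)
  W[f < lo | f > hi] <- 0
  y <- Re(stats::fft(W, inverse = TRUE))[seq_len(n)] / nf
  y / stats::sd(y)
}

# Band noise generated at a reduced rate gen_fs and linearly upsampled to
# fs (valid for bands well below gen_fs / 2; spectral images around
# gen_fs are attenuated > 19 dB and land outside the analysis bands).
band_noise_up <- function(n, fs, lo, hi, gen_fs) {
  if (gen_fs >= fs) return(fft_band_noise(n, fs, lo, hi))
  ng <- ceiling(n / fs * gen_fs) + 2L
  yg <- fft_band_noise(ng, gen_fs, lo, hi)
  y <- stats::approx((seq_len(ng) - 1) / gen_fs, yg,
                     xout = (seq_len(n) - 1) / fs)$y
  y / stats::sd(y)
}

# Envelope-stabilized band noise: the instantaneous (analytic) envelope
# is smoothed over ~2 s and divided out, mimicking the continuous,
# amplitude-stable character of NREMS slow-wave activity (plain Gaussian
# band noise has chi-square power fluctuations far larger than real
# ongoing delta oscillations).
stable_band_noise_up <- function(n, fs, lo, hi, gen_fs) {
  # power-of-two length keeps the analytic-signal FFTs fast
  ng <- stats::nextn(ceiling(n / fs * gen_fs) + 2L, 2)
  yg <- fft_band_noise(ng, gen_fs, lo, hi)
  e <- Mod(analytic_signal(yg))
  w <- round(2 * gen_fs)
  es <- as.numeric(stats::filter(e, rep(1 / w, w), sides = 2))
  es[is.na(es)] <- mean(e)
  yg <- yg / pmax(es, 0.1 * mean(e))
  y <- if (gen_fs >= fs) yg[seq_len(n)] else
    stats::approx((seq_len(ng) - 1) / gen_fs, yg,
                  xout = (seq_len(n) - 1) / fs)$y
  y / stats::sd(y)
}

wrap360 <- function(x) ((x %% 360) + 360) %% 360

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi
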