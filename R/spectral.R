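# Epoch FFTs and the wake / sleep spectral normalizations.

#' Per-epoch power spectral density
#'
#' Single-taper periodogram of each scoring epoch after offset correction
#' (subtraction of the epoch mean). Bin width is `1/epoch_s` Hz (0.25 Hz
#' for 4 s epochs). Epochs whose predecessor or successor carries a
#' different state label are flagged transition-adjacent (recording
#' boundaries count as adjacent).
#'
#' @param rec a `psg_recording` (or plain numeric vector with `fs`).
#' @param hyp matching [hypnogram()].
#' @param channel channel name (default `"eeg"`).
#' @param fs sampling rate, only needed when `rec` is a plain vector.
#' @param max_freq highest frequency bin retained, Hz.
#' @return object of class `epoch_spectra`: `freq`, `psd` (freq x epoch,
#'   units^2/Hz, one-sided), `states`, `transition_adjacent`, `epoch_s`.
#' @export
epoch_spectra <- function(rec, hyp, channel = "eeg", fs = NULL,
                          max_freq = 500) {
  if (inherits(rec, "psg_recording")) {
    if (!channel %in% names(rec$signals)) stop("channel '", channel,
                                               "' absent from recording")
    x <- rec$signals[[channel]]
    fs <- rec$fs
  } else x <- rec
  es <- epoch_s_of(hyp)
  nper <- fs * es
  n_ep <- min(nrow(hyp), floor(length(x) / nper))
  m <- matrix(x[seq_len(n_ep * nper)], nrow = nper)
  m <- sweep(m, 2, colMeans(m))
  X <- stats::mvfft(m)
  keep <- seq_len(min(nper %/% 2 + 1, floor(max_freq * es) + 1))
  psd <- (2 / (fs * nper)) * Mod(X[keep, , drop = FALSE])^2
  psd[1, ] <- psd[1, ] / 2                      # DC not doubled
  freq <- (keep - 1) / es

  states <- hyp$state[seq_len(n_ep)]
  adj <- rep(TRUE, n_ep)
  if (n_ep > 2) {
    mid <- 2:(n_ep - 1)
    adj[mid] <- states[mid] != states[mid - 1] | states[mid] != states[mid + 1]
  }
  structure(list(freq = freq, psd = psd, states = states,
                 transition_adjacent = adj, epoch_s = es, fs = fs),
            class = "epoch_spectra")
}

#' @export
print.epoch_spectra <- function(x, ...) {
  cat("<epoch_spectra> ", ncol(x$psd), " epochs x ", length(x$freq),
      " bins (", x$freq[2] - x$freq[1], " Hz)\n", sep = "")
  invisible(x)
}

#' Normalized per-state sleep spectra
#'
#' Median spectrum per vigilance state over epochs non-adjacent to state
#' transitions, divided by a single constant: the average across states of
#' each state's mean power level between 0.75 and 47 Hz. The constant is
#' common to all states so that each state carries the same weight; the
#' result is invariant to a global amplitude gain.
#'
#' @param es an [epoch_spectra()].
#' @param states states to include (defaults to the three main states).
#' @return list with `freq`, `spectra` (freq x state matrix) and
#'   `norm_const`. States without usable epochs are dropped with a
#'   warning.
#' @export
sleep_state_spectrum <- function(es, states = c("Wake", "NREMS", "REMS")) {
  med <- list()
  for (s in states) {
    sel <- es$states == s & !es$transition_adjacent
    if (!any(sel)) {
      warning("no non-transition epochs for state ", s, "; omitted")
      next
    }
    med[[s]] <- apply(es$psd[, sel, drop = FALSE], 1, stats::median)
  }
  if (!length(med)) stop("no usable state spectra")
  spec <- do.call(cbind, med)
  bins <- band_bins(es$freq, c(0.75, 47))
  norm_const <- mean(colMeans(spec[bins, , drop = FALSE]))
  list(freq = es$freq, spectra = spec / norm_const, norm_const = norm_const)
}

#' Normalized quiet / active wakefulness spectra
#'
#' Mean spectrum over each supplied wake-epoch set, each frequency bin
#' divided by the sum of power from 2 to 30 Hz, with theta, beta and
#' low-gamma band summaries (sums of normalized bins).
#'
#' @param es an [epoch_spectra()].
#' @param qw_epochs,aw_epochs integer epoch index sets from
#'   [segment_quiet_active_wake()].
#' @param bands band definitions (see [band_definitions()]).
#' @return list with `freq`, `qw`, `aw` (normalized spectra) and
#'   `summary` (data frame of band sums per set).
#' @export
wake_spectrum <- function(es, qw_epochs, aw_epochs,
                          bands = band_definitions()) {
  one <- function(idx, label) {
    if (!length(idx)) stop("empty ", label, " epoch set")
    sp <- rowMeans(es$psd[, idx, drop = FALSE])
    sp / sum(sp[band_bins(es$freq, c(2, 30))])
  }
  qw <- one(qw_epochs, "QW")
  aw <- one(aw_epochs, "AW")
  summ <- do.call(rbind, lapply(c("theta", "beta", "low_gamma"), function(b) {
    bins <- band_bins(es$freq, bands[[b]])
    data.frame(band = b, qw = sum(qw[bins]), aw = sum(aw[bins]))
  }))
  list(freq = es$freq, qw = qw, aw = aw, summary = summ)
}

#' Segment quiet and active wakefulness from the EMG
#'
#' Per-animal percentile thresholds on the natural logarithm of the mean
#' squared EMG per epoch, over wake epochs only: quiet wakefulness (QW)
#' spans the 10th-25th percentile and requires at least three consecutive
#' qualifying epochs (>12 s); active wakefulness (AW) spans the
#' 50th-99th percentile. Quantiles use linear interpolation.
#'
#' @param emg EMG signal vector.
#' @param fs sampling rate, Hz.
#' @param hyp matching [hypnogram()].
#' @param qw_limits,aw_limits percentile bounds.
#' @param min_run_qw minimum consecutive qualifying epochs for QW.
#' @return list with integer epoch index sets `qw` and `aw` (disjoint).
#' @export
segment_quiet_active_wake <- function(emg, fs, hyp,
                                      qw_limits = c(0.10, 0.25),
                                      aw_limits = c(0.50, 0.99),
                                      min_run_qw = 3) {
  es <- epoch_s_of(hyp)
  n_ep <- min(nrow(hyp), floor(length(emg) / (fs * es)))
  wake <- which(hyp$state[seq_len(n_ep)] == "Wake")
  if (length(wake) < 20) stop("need at least 20 wake epochs")
  msq <- colMeans(matrix(emg[seq_len(n_ep * fs * es)]^2, nrow = fs * es))
  lv <- log(msq[wake])
  q <- stats::quantile(lv, c(qw_limits, aw_limits), type = 7)

  qw_cand <- wake[lv >= q[1] & lv <= q[2]]
  aw <- wake[lv >= q[3] & lv <= q[4]]
  qw <- integer(0)
  if (length(qw_cand)) {
    flag <- seq_len(n_ep) %in% qw_cand
    runs <- logical_runs(flag)
    runs <- runs[runs$end - runs$start + 1L >= min_run_qw, , drop = FALSE]
    qw <- unlist(lapply(seq_len(nrow(runs)),
                        function(i) runs$start[i]:runs$end[i]))
    qw <- as.integer(qw %||% integer(0))
  }
  list(qw = qw, aw = aw)
}

#' High-gamma power ratio between two recordings
#'
#' Per-state ratio (follow-up / baseline) of mean 60-80 Hz power taken
#' from the state-normalized sleep spectra of the two recordings.
#'
#' @param es_baseline,es_followup [epoch_spectra()] of the same subject.
#' @param band gamma band, Hz.
#' @param states states to report.
#' @return named numeric vector of ratios.
#' @export
gamma_ratio <- function(es_baseline, es_followup, band = c(60, 80),
                        states = c("Wake", "NREMS", "REMS")) {
  sb <- sleep_state_spectrum(es_baseline, states)
  sf <- sleep_state_spectrum(es_followup, states)
  common <- intersect(colnames(sb$spectra), colnames(sf$spectra))
  if (!length(common)) stop("no state present in both recordings")
  bins <- band_bins(sb$freq, band)
  vapply(common, function(s) {
    mean(sf$spectra[bins, s]) / mean(sb$spectra[bins, s])
  }, 1)
}

#' Normalized delta-power time course
#'
#' Raw 1-4 Hz power per non-transition NREMS epoch, averaged within
#' periods containing equal amounts of NREMS (12 per light phase, 6 per
#' dark phase by convention), normalized to the mean over a reference
#' window (ZT9-12 by default, when sleep pressure is lowest).
#'
#' @param es an [epoch_spectra()].
#' @param hyp matching [hypnogram()].
#' @param n_periods number of equal-NREMS periods.
#' @param norm_window_s reference window `c(t0, t1)` in seconds.
#' @param band delta band, Hz.
#' @return data frame with `period`, `t_mid_s`, `delta_raw`,
#'   `delta_norm`. Errors if the reference window holds no NREMS epoch.
#' @export
delta_timecourse <- function(es, hyp, n_periods = 12,
                             norm_window_s = c(9, 12) * 3600,
                             band = c(1, 4)) {
  esec <- epoch_s_of(hyp)
  n_ep <- length(es$states)
  sel <- which(es$states == "NREMS" & !es$transition_adjacent)
  if (length(sel) < n_periods) stop("too few NREMS epochs for ", n_periods,
                                    " periods")
  bins <- band_bins(es$freq, band)
  dp <- colMeans(es$psd[bins, sel, drop = FALSE])
  tmid <- (sel - 0.5) * esec

  ref <- dp[tmid >= norm_window_s[1] & tmid <= norm_window_s[2]]
  if (!length(ref))
    stop("no NREMS epochs inside the normalization window; ",
         "normalization failure")
  grp <- ceiling(seq_along(sel) * n_periods / length(sel))
  out <- data.frame(
    period = seq_len(n_periods),
    t_mid_s = as.numeric(tapply(tmid, grp, mean)),
    delta_raw = as.numeric(tapply(dp, grp, mean)))
  out$delta_norm <- out$delta_raw / mean(ref)
  out
}
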