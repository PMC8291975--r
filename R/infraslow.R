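# Core infraslow (0.02 Hz) machinery: sigma trace, spectrum, phase,
# cycles, event-phase coupling, fragility outcomes.

#' Extract the normalized sigma-power trace
#'
#' Sigma (10-15 Hz) power by Morlet wavelet transform (four cycles,
#' 0.5 Hz-spaced center frequencies), down-sampled to 10 Hz, smoothed with
#' a zero-phase windowed-sinc FIR low-pass (cutoff 0.0125 Hz, order 100;
#' the deliberately low order lets the 0.02 Hz component through while
#' removing fast power fluctuations), and normalized by the mean over
#' NREMS and MA samples. The Hilbert phase (see [compute_phase()]) is
#' computed once over the whole smoothed trace and is meaningful on the
#' NREMS/MA mask.
#'
#' @param rec a `psg_recording` or numeric signal vector.
#' @param hyp matching [hypnogram()].
#' @param channel EEG/LFP channel name.
#' @param band sigma band, Hz.
#' @param fs sampling rate when `rec` is a plain vector.
#' @param fs_sigma trace rate, Hz (10).
#' @param fir_order,fir_cutoff_hz smoothing filter parameters.
#' @return object of class `sigma_trace`: `t`, `fs`, `power` (normalized,
#'   unsmoothed), `smooth` (normalized, smoothed), `phase_deg`, `mask`.
#' @export
compute_sigma_trace <- function(rec, hyp, channel = "eeg",
                                band = c(10, 15), fs = NULL,
                                fs_sigma = 10, fir_order = 100,
                                fir_cutoff_hz = 0.0125) {
  bt <- band_power_traces(rec, hyp, channel,
                          bands = list(sigma = band),
                          fs_out = fs_sigma, fs = fs)
  p <- bt$raw[, "sigma"]
  mask <- bt$mask
  if (!any(mask)) stop("no NREMS samples: cannot normalize sigma trace")

  b <- as.numeric(signal::fir1(fir_order, fir_cutoff_hz / (fs_sigma / 2)))
  sm <- signal::filtfilt(b, 1, p)

  p <- p / mean(p[mask])
  sm <- sm / mean(sm[mask])
  ph <- compute_phase_vector(sm, mean_level = 1)

  structure(list(t = bt$t, fs = fs_sigma, power = p, smooth = sm,
                 phase_deg = ph, mask = mask),
            class = "sigma_trace")
}

#' @export
print.sigma_trace <- function(x, ...) {
  cat("<sigma_trace> ", length(x$power), " samples @ ", x$fs, " Hz; ",
      round(100 * mean(x$mask), 1), "% NREMS/MA\n", sep = "")
  invisible(x)
}

# Phase of the mean-subtracted trace via the analytic signal, mapped so
# that a cosine peak sits at 0 deg and the trough at 180 deg, increasing
# through the cycle.
compute_phase_vector <- function(x, mean_level = mean(x)) {
  if (stats::sd(x) == 0) stop("constant trace: phase undefined")
  wrap360(rad2deg(Arg(analytic_signal(x - mean_level))))
}

#' Infraslow phase of a sigma trace
#'
#' Hilbert-transform phase of the smoothed sigma trace (computed over the
#' whole recording, interpreted on the NREMS/MA mask), with peaks at
#' 0 deg and troughs at 180 deg.
#'
#' @param st a [compute_sigma_trace()] result, or a plain numeric trace.
#' @return numeric phase vector, degrees in `[0, 360)`.
#' @export
compute_phase <- function(st) {
  if (inherits(st, "sigma_trace")) return(st$phase_deg)
  compute_phase_vector(st)
}

#' Infraslow spectrum of the sigma trace
#'
#' Per-bout FFT of the mean-subtracted smoothed sigma trace over
#' continuous NREMS bouts (MA epochs do not interrupt a bout), with the
#' 0-0.5 Hz bins linearly interpolated onto a common 201-point grid and
#' averaged across bouts. The peak is searched above 0.005 Hz (two grid
#' bins) to avoid detrending leakage into the lowest bins.
#'
#' @param st a `sigma_trace`.
#' @param hyp matching [hypnogram()].
#' @param min_bout_s shortest bout entering the average, seconds.
#' @return list with `freq` (201 points), `power`, `peak_freq_hz`,
#'   `peak_power`, `n_bouts`. Errors when no bout qualifies.
#' @export
infraslow_spectrum <- function(st, hyp, min_bout_s = 100) {
  b <- hyp_bouts(hyp, merge_ma = TRUE)
  b <- b[b$state == "NREMS" & b$duration_s >= min_bout_s, , drop = FALSE]
  if (nrow(b) == 0) stop("no NREMS bout of at least ", min_bout_s, " s")
  grid <- seq(0, 0.5, length.out = 201)
  acc <- numeric(201)
  used <- 0L
  for (i in seq_len(nrow(b))) {
    i0 <- floor(b$start_s[i] * st$fs) + 1L
    i1 <- min(length(st$smooth), i0 + round(b$duration_s[i] * st$fs) - 1L)
    y <- st$smooth[i0:i1]
    L <- length(y)
    if (L < min_bout_s * st$fs) next
    y <- y - mean(y)
    P <- (2 / L^2) * Mod(stats::fft(y))^2
    f <- (seq_len(L) - 1) / L * st$fs
    keep <- f <= 0.5
    acc <- acc + stats::approx(f[keep], P[keep], xout = grid, rule = 2)$y
    used <- used + 1L
  }
  if (used == 0L) stop("no qualifying bout")
  pw <- acc / used
  search <- which(grid > 0.005)
  pk <- search[which.max(pw[search])]
  list(freq = grid, power = pw, peak_freq_hz = grid[pk],
       peak_power = pw[pk], n_bouts = used)
}

#' Detect individual infraslow cycles
#'
#' Find-peaks style detection on the smoothed normalized sigma trace:
#' peaks must exceed the NREMS/MA mean, troughs must fall below it, and
#' extrema of the same kind must be separated by more than `min_sep_s`
#' (20 s). Cycles are assembled peak-trough-peak; a cycle is retained only
#' when it lies entirely within NREMS (MA epochs permitted). Bouts
#' shorter than 2 x `min_sep_s` cannot hold a cycle and are implicitly
#' skipped.
#'
#' @param st a `sigma_trace`.
#' @param hyp matching [hypnogram()].
#' @param min_sep_s minimum same-kind extremum separation, seconds.
#' @return data frame of class `cycle_set`: sample indices `peak1`,
#'   `trough`, `peak2`, times `start_s`/`trough_s`/`end_s`, `outcome`
#'   (filled by [classify_fragility_outcomes()]), `ai_peak` placeholder.
#' @export
detect_cycles <- function(st, hyp, min_sep_s = 20) {
  s <- st$smooth
  m <- mean(s[st$mask])
  sep <- round(min_sep_s * st$fs)

  pk <- find_extrema(s, "max")
  pk <- pk[s[pk] > m]
  pk <- prune_min_distance(pk, s[pk], sep)
  tr <- find_extrema(s, "min")
  tr <- tr[s[tr] < m]
  tr <- prune_min_distance(tr, -s[tr], sep)

  ext <- rbind(data.frame(i = pk, kind = "peak"),
               data.frame(i = tr, kind = "trough"))
  ext <- ext[order(ext$i), , drop = FALSE]
  # collapse consecutive same-kind extrema, keeping the more extreme one
  keep <- rep(TRUE, nrow(ext))
  if (nrow(ext) > 1) {
    j <- 1L
    for (i in 2:nrow(ext)) {
      if (ext$kind[i] == ext$kind[j]) {
        better <- if (ext$kind[i] == "peak") s[ext$i[i]] > s[ext$i[j]] else
          s[ext$i[i]] < s[ext$i[j]]
        if (better) { keep[j] <- FALSE; j <- i } else keep[i] <- FALSE
      } else j <- i
    }
  }
  ext <- ext[keep, , drop = FALSE]

  cyc <- list()
  if (nrow(ext) >= 3) {
    for (i in seq_len(nrow(ext) - 2)) {
      if (ext$kind[i] == "peak" && ext$kind[i + 1] == "trough" &&
          ext$kind[i + 2] == "peak") {
        span <- ext$i[i]:ext$i[i + 2]
        if (all(st$mask[span])) {
          cyc[[length(cyc) + 1L]] <- data.frame(
            peak1 = ext$i[i], trough = ext$i[i + 1], peak2 = ext$i[i + 2])
        }
      }
    }
  }
  cs <- if (length(cyc)) do.call(rbind, cyc) else
    data.frame(peak1 = integer(0), trough = integer(0), peak2 = integer(0))
  cs$start_s <- st$t[cs$peak1]
  cs$trough_s <- st$t[cs$trough]
  cs$end_s <- st$t[cs$peak2]
  cs$outcome <- rep(NA_character_, nrow(cs))
  cs$ai_peak <- rep(NA, nrow(cs))
  attr(cs, "fs") <- st$fs
  class(cs) <- c("cycle_set", "data.frame")
  cs
}

#' @export
print.cycle_set <- function(x, ...) {
  cat("<cycle_set> ", nrow(x), " cycles\n", sep = "")
  if (nrow(x) && any(!is.na(x$outcome))) print(table(x$outcome))
  invisible(x)
}

#' Infraslow phase at event onsets
#'
#' Samples the phase trace at each event onset and at fixed offsets
#' before it (0, 4, 8, 12 s by default, matching the pre-onset windows of
#' the event-coupling analysis).
#'
#' @param st a `sigma_trace` (or plain phase vector at 10 Hz).
#' @param events event table with `onset_s` (e.g. MA onsets).
#' @param offsets_s offsets subtracted from the onset, seconds.
#' @return matrix (events x offsets) of phases in degrees.
#' @export
phase_at_events <- function(st, events, offsets_s = c(0, 4, 8, 12)) {
  ph <- if (inherits(st, "sigma_trace")) st$phase_deg else st
  fs <- if (inherits(st, "sigma_trace")) st$fs else 10
  onsets <- events$onset_s
  if (any(onsets < 0 | onsets > length(ph) / fs))
    stop("event outside recording")
  out <- sapply(offsets_s, function(off) {
    idx <- pmax(1L, floor((onsets - off) * fs) + 1L)
    ph[idx]
  })
  out <- matrix(out, nrow = length(onsets),
                dimnames = list(NULL, paste0("minus_", offsets_s, "s")))
  out
}

#' Classify fragility-period outcomes
#'
#' Each detected cycle's fragility span (phase 90-270 deg, the
#' peak-to-trough stretch) is labelled `MA` when a microarousal onset
#' falls inside it with extracted phase in 90-270 deg,
#' `REMS-transition` when the state turns to REMS within or immediately
#' after the span, and `NREMS-continuing` otherwise.
#'
#' @param cs a [detect_cycles()] result.
#' @param hyp matching [hypnogram()].
#' @param events event table with MA onsets (`onset_s`, `type` optional).
#' @param st the `sigma_trace` (for onset phases).
#' @return list with `cycles` (outcome column filled) and `proportions`
#'   (named, sums to 1 when cycles exist).
#' @export
classify_fragility_outcomes <- function(cs, hyp, events, st) {
  if (!is.null(events$type)) events <- events[events$type == "MA", ,
                                              drop = FALSE]
  onset_phase <- if (nrow(events))
    phase_at_events(st, events, offsets_s = 0)[, 1] else numeric(0)
  es <- epoch_s_of(hyp)
  out <- character(nrow(cs))
  for (i in seq_len(nrow(cs))) {
    frag0 <- cs$start_s[i]; frag1 <- cs$trough_s[i]
    has_ma <- nrow(events) > 0 &&
      any(events$onset_s >= cs$start_s[i] & events$onset_s < cs$end_s[i] &
            onset_phase >= 90 & onset_phase <= 270)
    if (has_ma) { out[i] <- "MA"; next }
    e0 <- epoch_of_time(hyp, frag0)
    e1 <- min(nrow(hyp), epoch_of_time(hyp, frag1) + 2L)
    out[i] <- if (any(hyp$state[e0:e1] == "REMS")) "REMS-transition" else
      "NREMS-continuing"
  }
  cs$outcome <- out
  lv <- c("MA", "REMS-transition", "NREMS-continuing")
  prop <- as.numeric(table(factor(out, levels = lv))) / max(1L, nrow(cs))
  names(prop) <- lv
  list(cycles = cs, proportions = prop)
}
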