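#' Synthesize EEG and EMG signals for a simulated session
#'
#' Noise-shaping synthesis: each EEG frequency band is unit-variance
#' band-limited Gaussian noise scaled by a state-dependent amplitude. In
#' NREMS the sigma-band (10-15 Hz) power is modulated as
#' `1 + modulation_depth * cos(phase)` with 0 deg at the envelope peak,
#' while delta power runs anti-phase: dipped by `delta_continuity_dip`
#' during continuity and surging by `delta_surge_gain` toward the
#' fragility trough, with plateau-like switching at 60/300 deg (the
#' delta upstroke begins before the 90 deg span edge). The SNI condition
#' multiplies tonic 16-40 Hz power in NREMS and wakefulness by
#' `sni_hf_gain`, blunts the delta surge by `sni_delta_surge_gain`, and
#' inserts AI-peak local-arousal events (3 s delta drop plus 16-40 Hz
#' burst, no EMG burst) in a fraction of MA-free cycles, with a
#' heart-rate transient. The EMG is state-dependent tonic noise plus
#' phasic movement bursts (wakefulness and microarousal onsets) plus an
#' additive R-peak impulse train at the state-dependent heart rate.
#'
#' @param hyp hypnogram (after [place_microarousals()]).
#' @param truth matching `sim_truth`.
#' @param cfg the [sim_config()].
#' @param seed integer or `NULL`.
#' @return list with `recording` (class `psg_recording`: signals `eeg`,
#'   `emg` at `fs_signal`, channel roles and site labels) and the updated
#'   `truth` (R-peak times, AI-peak events).
#' @export
synthesize_signals <- function(hyp, truth, cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fs <- cfg$fs_signal
  dur <- hyp_duration_s(hyp)
  if (abs(dur - cfg$duration_s) > cfg$epoch_s)
    stop("hypnogram and config durations are inconsistent")
  n <- floor(dur * fs)
  t <- (seq_len(n) - 1) / fs
  si <- match(state_at_samples(hyp, fs, n), c("Wake", "NREMS", "REMS", "MA"))
  cosph <- cos(2 * pi * t / cfg$infraslow_period_s)
  sni <- cfg$condition == "sni"
  hf_gain <- if (sni) cfg$sni_hf_gain else 1
  surge <- cfg$delta_surge_gain * (if (sni) cfg$sni_delta_surge_gain else 1)

  # --- AI-peak local-arousal events (drawn for all cycles so that sham and
  # SNI sessions share the RNG stream; eligibility differs only by p).
  cyc <- truth$cycles
  ai_events <- data.frame(onset_s = numeric(0), duration_s = numeric(0))
  if (nrow(cyc)) {
    u <- stats::runif(nrow(cyc))
    ph_e <- stats::runif(nrow(cyc), 120, 240)
    sel <- !cyc$has_ma & u < cfg$p_ai_peak_fragility
    if (any(sel)) {
      onset <- cyc$start_s[sel] + ph_e[sel] / 360 * cfg$infraslow_period_s
      ai_events <- data.frame(onset_s = onset,
                              duration_s = rep(3, length(onset)))
      cyc$ai_event[sel] <- TRUE
    }
  }
  truth$cycles <- cyc
  truth$ai_events <- ai_events

  in_win <- function(times, onsets, durs) {
    f <- logical(length(times))
    for (j in seq_along(onsets)) {
      f <- f | (times >= onsets[j] & times < onsets[j] + durs[j])
    }
    f
  }

  # --- EEG -------------------------------------------------------------
  g <- function(wake, nrems, rems, ma) c(wake, nrems, rems, ma)[si]
  nr <- si == 2L
  ev <- if (nrow(ai_events))
    in_win(t, ai_events$onset_s, ai_events$duration_s) else
    logical(n)

  # Delta runs anti-phase to sigma across the infraslow cycle: low while
  # spindle density is high (continuity), surging toward the fragility
  # trough. SNI blunts the fragility surge but leaves the continuity dip.
  # The fourth-root shaping makes the alternation plateau-like (sharp
  # switching at the 90/270 deg span edges rather than a slow sinusoidal
  # crossing), as in the abrupt delta upstroke entering fragility.
  # Switch points sit at 60/300 deg: the delta upstroke begins before the
  # 90 deg fragility edge and releases after 270 deg, so within 90-270 the
  # delta (and hence the activation index) is on its plateau.
  amp <- g(10, 40, 8, 8)
  sw <- function(x) pmax(0, x / 1.5)^0.25
  u <- 0.5 - cosph[nr]
  denv <- 1 + surge * sw(u) - cfg$delta_continuity_dip * sw(-u)
  amp[nr] <- amp[nr] * sqrt(pmax(0.05, denv))
  amp[ev] <- amp[ev] * 0.4
  eeg <- stable_band_noise_up(n, fs, 1, 4, gen_fs = 100) * amp

  # mouse theta peaks at 6-9 Hz; a sharp upper edge below the sigma
  # band keeps theta from leaking into the 10-15 Hz wavelet estimate
  eeg <- eeg + band_noise_up(n, fs, 5, 9, gen_fs = 100) * g(25, 15, 30, 25)

  # The sigma band follows the infraslow envelope through MA epochs as
  # well: a brief arousal does not reset the underlying fluctuation, and
  # an event-locked sigma artifact would corrupt phase estimates at the
  # very events the analysis phase-references. Desynchronization during
  # MAs is carried by the delta drop and high-frequency content instead.
  amp <- g(8, 25, 6, 25)
  nrma <- nr | si == 4L
  amp[nrma] <- amp[nrma] * sqrt(1 + cfg$modulation_depth * cosph[nrma])
  eeg <- eeg + band_noise_up(n, fs, 10, 15, gen_fs = 100) * amp

  amp <- g(12, 8, 10, 12)
  amp[si <= 2L] <- amp[si <= 2L] * sqrt(hf_gain)
  amp[ev] <- amp[ev] * 2.5
  eeg <- eeg + band_noise_up(n, fs, 16, 40, gen_fs = 200) * amp

  amp <- g(6, 3, 5, 6)
  if (sni) amp[nr] <- amp[nr] * sqrt(1.3)
  amp[ev] <- amp[ev] * 1.3
  eeg <- eeg + band_noise(n, fs, 60, 80) * amp

  eeg <- eeg + band_noise(n, fs, 0, 100) * 5
  eeg <- eeg + band_noise(n, fs, 100, 450) * g(4, 1.5, 2, 4)

  # --- EMG -------------------------------------------------------------
  dur_s <- floor(dur)
  z_raw <- stats::rnorm(dur_s + 60)
  z_sm <- stats::filter(z_raw, rep(1 / 30, 30), sides = 1)
  z_sm <- z_sm[!is.na(z_sm)][seq_len(dur_s)]
  z_slow <- as.numeric(scale(z_sm))
  z_samp <- z_slow[pmin(dur_s, floor(t) + 1L)]

  amp <- g(4, 2, 1, 2)
  wk <- si == 1L
  amp[wk] <- amp[wk] * exp(0.3 * z_samp[wk])
  emg <- stats::rnorm(n) * amp

  bursts <- list()
  add_burst <- function(onset, len, a) {
    bursts[[length(bursts) + 1L]] <<- c(onset, len, a)
  }
  # movement bursts in wakefulness, rate modulated by the slow drive
  sec_state <- si[seq(1L, n, by = fs)]
  for (s in which(sec_state == 1L)) {
    if (stats::runif(1) < min(0.9, 0.25 * exp(1.5 * z_slow[min(s, dur_s)]))) {
      add_burst((s - 1) + stats::runif(1, 0, 0.7), 0.3,
                40 * exp(0.3 * stats::rnorm(1)))
    }
  }
  # guaranteed burst at each wake-bout onset (animals move on waking)
  bouts <- truth$bouts
  for (i in which(bouts$state == "Wake")) {
    add_burst(bouts$start_s[i], 1.5, 40)
  }
  # phasic EMG burst defining each microarousal onset
  if (nrow(truth$ma)) {
    for (i in seq_len(nrow(truth$ma))) {
      add_burst(truth$ma$onset_s[i], min(truth$ma$duration_s[i], 4), 50)
    }
  }
  for (bu in bursts) {
    i0 <- max(1L, floor(bu[1] * fs) + 1L)
    i1 <- min(n, i0 + round(bu[2] * fs) - 1L)
    if (i1 >= i0) emg[i0:i1] <- emg[i0:i1] + stats::rnorm(i1 - i0 + 1L) * bu[3]
  }

  # --- R-peak impulse train --------------------------------------------
  base_rate <- c(cfg$hr_wake_hz, cfg$hr_nrems_hz, cfg$hr_rems_hz,
                 cfg$hr_wake_hz)[sec_state]
  tr_on <- ai_events$onset_s; tr_dur <- rep(4, length(tr_on))
  tr_sec <- integer(0)
  if (length(tr_on)) {
    tr_sec <- unique(unlist(lapply(seq_along(tr_on), function(j) {
      floor(tr_on[j]):floor(tr_on[j] + tr_dur[j])
    }))) + 1L
    tr_sec <- tr_sec[tr_sec >= 1 & tr_sec <= dur_s]
  }
  rate_sec <- base_rate[seq_len(dur_s)]
  rate_sec[tr_sec] <- rate_sec[tr_sec] + cfg$hr_ai_transient_hz
  rpeaks <- numeric(ceiling(dur * (max(rate_sec) + 2)))
  nb <- 0L
  tb <- 0.05
  jit <- stats::rnorm(length(rpeaks), 0, 0.003)
  while (tb < dur - 0.05) {
    nb <- nb + 1L
    rpeaks[nb] <- tb
    tb <- tb + max(0.06, 1 / rate_sec[min(dur_s, floor(tb) + 1L)] + jit[nb])
  }
  rpeaks <- rpeaks[seq_len(nb)]
  idx <- pmin(n, floor(rpeaks * fs) + 1L)
  emg[idx] <- emg[idx] + 120
  truth$rpeaks_s <- rpeaks

  rec <- structure(list(
    signals = list(eeg = eeg, emg = emg),
    fs = fs,
    roles = c(eeg = "EEG", emg = "EMG"),
    sites = c(eeg = "S1HL", emg = "neck")
  ), class = "psg_recording")
  list(recording = rec, truth = truth)
}

#' @export
print.psg_recording <- function(x, ...) {
  n <- length(x$signals[[1]])
  cat("<psg_recording> ", length(x$signals), " channel(s) @ ", x$fs,
      " Hz, ", round(n / x$fs, 1), " s\n", sep = "")
  for (nm in names(x$signals)) {
    cat("  ", nm, " [", x$roles[[nm]], "]\n", sep = "")
  }
  invisible(x)
}

#' Simulate a complete ground-truthed polysomnography session
#'
#' Convenience wrapper chaining [simulate_hypnogram()],
#' [place_microarousals()] and [synthesize_signals()] under a single seed.
#' Identical config and seed give bit-identical output.
#'
#' @param cfg a [sim_config()]; `cfg$seed` drives all randomness.
#' @return list of class `sim_session` with `recording`, `hypnogram`,
#'   `events` (MA event table), `truth` and `cfg`.
#' @examples
#' \donttest{
#' ses <- simulate_recording(sim_config(duration_s = 600))
#' ses$hypnogram
#' }
#' @export
simulate_recording <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  hg <- simulate_hypnogram(cfg, seed = NULL)
  pm <- place_microarousals(hg$hypnogram, hg$truth, cfg, seed = NULL)
  sg <- synthesize_signals(pm$hypnogram, pm$truth, cfg, seed = NULL)
  structure(list(recording = sg$recording, hypnogram = pm$hypnogram,
                 events = pm$events, truth = sg$truth, cfg = cfg),
            class = "sim_session")
}

#' @export
print.sim_session <- function(x, ...) {
  cat("<sim_session> condition =", x$cfg$condition,
      "seed =", x$cfg$seed, "\n")
  print(x$recording)
  print(x$hypnogram)
  invisible(x)
}
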