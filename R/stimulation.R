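# Simulated closed-loop vibration experiment and the automatic
# wake-up / sleep-through trial scorer.

#' Run a simulated closed-loop stimulation session
#'
#' Walks the session second by second using the online state machine and
#' the period classifier. When the target period is detected during
#' likely NREMS, the controller waits 4 s, re-assesses, and if the target
#' persists launches a 3 s vibration with probability 0.25. The
#' generator's response model then decides a wake-up with probability
#' `p_wakeup_fragility` or `p_wakeup_continuity` according to the *true*
#' period at stimulus time; wake-ups imprint 5 s of desynchronized EEG
#' and an EMG burst on the signals (so the automatic scorer sees them),
#' sleep-throughs leave the signals untouched.
#'
#' @param ses a `sim_session` from [simulate_recording()].
#' @param clf trained [train_period_classifier()].
#' @param target `"fragility"` or `"continuity"`.
#' @param thr state-machine thresholds (default calibrated on the
#'   session).
#' @param detection optional precomputed [online_period_detection()]
#'   result for this session (avoids recomputing features and classifier
#'   predictions when several targets are run on one session).
#' @param p_stim stimulation probability at a passed gate (0.25).
#' @param stim_dur_s vibration duration, seconds.
#' @param gate_delay_s re-assessment delay, seconds (4).
#' @param refractory_s pause after each stimulus before re-arming.
#' @param seed RNG seed for the stimulus lottery and response model.
#' @return list with `stimuli` (onset_s, duration_s, type, channel,
#'   true_period, woke), the modified `recording`, `n_gate_passes`, and
#'   the per-second `online` table (state and period call).
#' @export
closed_loop_session <- function(ses, clf, target = c("fragility",
                                                     "continuity"),
                                thr = NULL, p_stim = 0.25, stim_dur_s = 3,
                                gate_delay_s = 4, refractory_s = 15,
                                seed = 1, detection = NULL) {
  target <- match.arg(target)
  if (!inherits(clf, "period_classifier")) stop("untrained classifier")
  od <- detection %||% online_period_detection(ses$recording,
                                               ses$hypnogram, clf = clf,
                                               thr = thr)
  sec_lookup <- stats::setNames(od$table$period, od$table$second)

  set.seed(seed)
  rec <- ses$recording
  fs <- rec$fs
  dur <- floor(length(rec$signals$eeg) / fs)
  cfg <- ses$cfg
  stim <- list()
  n_gate <- 0L
  s <- min(od$table$second)
  last_end <- -Inf
  while (s <= dur - gate_delay_s - stim_dur_s - 5) {
    call_now <- sec_lookup[as.character(s)]
    if (!is.na(call_now) && call_now == target && s >= last_end) {
      call_later <- sec_lookup[as.character(s + gate_delay_s)]
      if (!is.na(call_later) && call_later == target) {
        n_gate <- n_gate + 1L
        if (stats::runif(1) < p_stim) {
          onset <- s + gate_delay_s
          true_phase <- truth_phase_at(ses$truth, onset)
          ep <- epoch_of_time(ses$hypnogram, onset)
          in_nrems <- ses$hypnogram$state[ep] %in% c("NREMS", "MA")
          true_period <- if (!in_nrems) "none" else
            if (true_phase >= 90 & true_phase <= 270) "fragility" else
              "continuity"
          p_wake <- switch(true_period,
                           fragility = cfg$p_wakeup_fragility,
                           continuity = cfg$p_wakeup_continuity,
                           0.9)
          woke <- stats::runif(1) < p_wake
          if (woke) {
            i0 <- floor(onset * fs) + 1L
            i1 <- min(length(rec$signals$eeg), i0 + 5 * fs - 1L)
            nn <- i1 - i0 + 1L
            rec$signals$eeg[i0:i1] <-
              band_noise(nn, fs, 5, 10) * 25 +
              band_noise(nn, fs, 1, 4) * 10 +
              band_noise(nn, fs, 16, 40) * 12 +
              band_noise(nn, fs, 100, 450) * 4 +
              band_noise(nn, fs, 0, 100) * 5
            rec$signals$emg[i0:i1] <- stats::rnorm(nn) * 4
            ib <- i0:(min(i1, i0 + 2 * fs))
            rec$signals$emg[ib] <- rec$signals$emg[ib] +
              stats::rnorm(length(ib)) * 40
          }
          stim[[length(stim) + 1L]] <- data.frame(
            onset_s = onset, duration_s = stim_dur_s, type = "stimulus",
            channel = "motor", true_period = true_period, woke = woke)
          last_end <- onset + stim_dur_s + refractory_s
          s <- ceiling(last_end)
          next
        }
        last_end <- s + gate_delay_s + 1
      }
    }
    s <- s + 1
  }
  stimuli <- if (length(stim)) do.call(rbind, stim) else
    data.frame(onset_s = numeric(0), duration_s = numeric(0),
               type = character(0), channel = character(0),
               true_period = character(0), woke = logical(0))
  list(stimuli = stimuli, recording = rec, n_gate_passes = n_gate,
       online = od$table)
}

#' Automatic scoring of vibration trials
#'
#' For each stimulus, EEG and EMG are analysed in the 5 s before and
#' after. Rejection rules first: theta/delta ratio > 1 before stimulation
#' (REMS-like) or squared EMG larger before than after (wake-like). A
#' wake-up is scored when the low/high-frequency ratio (1-4 Hz over
#' 100-500 Hz) drops markedly after stimulation together with EMG
#' activation, or - the escape clause - when either channel alone changes
#' very strongly while the other at least does not oppose it. Everything
#' else is a sleep-through.
#'
#' @param rec the (possibly stimulus-modified) `psg_recording`; sampling
#'   rate must be at least 1000 Hz unless the high band is reconfigured.
#' @param stimuli stimulus event table (`onset_s`, `duration_s`).
#' @param thresholds list: `drop` (ln pre/post low-high ratio), `emg`
#'   (post/pre squared-EMG ratio), `drop_strong`, `emg_strong`.
#' @param window_s analysis window, seconds.
#' @param high_band high-frequency band, Hz.
#' @return data frame of class `trial_scores`: per trial the three
#'   metrics and the verdict (`rejected`, `wake_up`, `sleep_through`).
#'   Trials without full margins are dropped with a warning.
#' @export
autoscore_trials <- function(rec, stimuli,
                             thresholds = list(drop = 0.75, emg = 1.5,
                                               drop_strong = 2.5,
                                               emg_strong = 6),
                             window_s = 5, high_band = c(100, 500)) {
  fs <- rec$fs
  if (fs < 2 * high_band[2])
    stop("sampling rate too low for the ", high_band[1], "-", high_band[2],
         " Hz band; reconfigure high_band")
  n <- length(rec$signals$eeg)
  bands <- band_definitions()
  bp <- function(x) {
    P <- Mod(stats::fft(x - mean(x))[seq_len(length(x) %/% 2 + 1)])^2
    f <- (seq_len(length(x) %/% 2 + 1) - 1) / window_s
    list(P = P, f = f)
  }
  res <- list()
  for (i in seq_len(nrow(stimuli))) {
    t0 <- stimuli$onset_s[i]
    i_pre <- (floor((t0 - window_s) * fs) + 1):floor(t0 * fs)
    i_post <- (floor(t0 * fs) + 1):floor((t0 + window_s) * fs)
    if (i_pre[1] < 1 || i_post[length(i_post)] > n) {
      warning("trial at ", t0, " s too close to recording edge; dropped")
      next
    }
    pre <- bp(rec$signals$eeg[i_pre]); post <- bp(rec$signals$eeg[i_post])
    mb <- function(sp, b) mean(sp$P[band_bins(sp$f, b)])
    theta_delta_pre <- mb(pre, bands$theta) / mb(pre, bands$delta)
    lh_pre <- mb(pre, bands$delta) / mb(pre, high_band)
    lh_post <- mb(post, bands$delta) / mb(post, high_band)
    lh_drop <- log(lh_pre / lh_post)
    emg_ratio <- mean(rec$signals$emg[i_post]^2) /
      mean(rec$signals$emg[i_pre]^2)

    verdict <- if (theta_delta_pre > 1 || emg_ratio < 1) "rejected"
    else if ((lh_drop > thresholds$drop && emg_ratio > thresholds$emg) ||
             (lh_drop > thresholds$drop_strong && emg_ratio > 1) ||
             (emg_ratio > thresholds$emg_strong && lh_drop > 0)) "wake_up"
    else "sleep_through"

    res[[length(res) + 1L]] <- data.frame(
      onset_s = t0, theta_delta_pre = theta_delta_pre,
      lowhigh_drop = lh_drop, emg_ratio = emg_ratio, verdict = verdict,
      true_period = stimuli$true_period[i] %||% NA_character_,
      woke = stimuli$woke[i] %||% NA)
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(onset_s = numeric(0), theta_delta_pre = numeric(0),
               lowhigh_drop = numeric(0), emg_ratio = numeric(0),
               verdict = character(0), true_period = character(0),
               woke = logical(0))
  class(out) <- c("trial_scores", "data.frame")
  out
}

#' Calibrate autoscoring thresholds at the equal-error point
#'
#' Given scored trials with known ground-truth responses (from the
#' generator's response model), chooses the `drop` and `emg` thresholds
#' minimizing the difference between false-positive and false-negative
#' rates over candidate midpoints.
#'
#' @param trials an [autoscore_trials()] table with a logical `woke`
#'   column.
#' @return thresholds list as taken by [autoscore_trials()].
#' @export
calibrate_autoscore_thresholds <- function(trials) {
  tr <- trials[trials$verdict != "rejected" & !is.na(trials$woke), ]
  if (nrow(tr) < 4 || length(unique(tr$woke)) < 2)
    stop("need scored exemplars of both outcomes")
  eq_err <- function(metric, truth) {
    cand <- sort(unique(metric))
    cand <- (cand[-1] + cand[-length(cand)]) / 2
    err <- vapply(cand, function(th) {
      abs(mean(metric[!truth] > th) - mean(metric[truth] <= th))
    }, 1)
    cand[which.min(err)]
  }
  drop_th <- eq_err(tr$lowhigh_drop, tr$woke)
  emg_th <- eq_err(tr$emg_ratio, tr$woke)
  list(drop = drop_th, emg = emg_th,
       drop_strong = 2 * drop_th, emg_strong = 4 * emg_th)
}

#' Wake-up probability by period and time of day
#'
#' `wake_up / (wake_up + sleep_through)` per online period type and per
#' ZT bin; rejected trials are excluded. Empty cells are `NA`.
#'
#' @param scores an [autoscore_trials()] table.
#' @param period_labels per-trial period labels (defaults to the
#'   `true_period` column).
#' @param zt_bin_s ZT bin width in seconds; `Inf` pools all times.
#' @return data frame `period`, `zt_bin`, `n_trials`, `p_wakeup`.
#' @export
wakeup_probability <- function(scores, period_labels = scores$true_period,
                               zt_bin_s = Inf) {
  sc <- scores[scores$verdict != "rejected", , drop = FALSE]
  period_labels <- period_labels[scores$verdict != "rejected"]
  bin <- if (is.infinite(zt_bin_s)) rep(0, nrow(sc)) else
    floor(sc$onset_s / zt_bin_s)
  cells <- unique(data.frame(period = period_labels, zt_bin = bin))
  cells <- cells[order(cells$period, cells$zt_bin), , drop = FALSE]
  out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sel <- period_labels == cells$period[i] & bin == cells$zt_bin[i]
    v <- sc$verdict[sel]
    n <- sum(v %in% c("wake_up", "sleep_through"))
    data.frame(period = cells$period[i], zt_bin = cells$zt_bin[i],
               n_trials = n,
               p_wakeup = if (n > 0) sum(v == "wake_up") / n else NA_real_)
  }))
  rownames(out) <- NULL
  out
}
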