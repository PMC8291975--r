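# Closed-loop session, automatic trial scoring, wake-up probabilities.

# Build a tiny recording with known pre/post stimulus windows.
mk_trial_rec <- function(kind, fs = 1000) {
  n <- 20 * fs
  set.seed(77)
  eeg <- infraslow:::band_noise(n, fs, 1, 4) * 40 +
    infraslow:::band_noise(n, fs, 100, 450) * 1.5 +
    infraslow:::band_noise(n, fs, 0, 100) * 5
  emg <- rnorm(n) * 2
  post <- (10 * fs + 1):(15 * fs)
  if (kind == "wake") {
    eeg[post] <- infraslow:::band_noise(length(post), fs, 5, 10) * 25 +
      infraslow:::band_noise(length(post), fs, 100, 450) * 5 +
      infraslow:::band_noise(length(post), fs, 1, 4) * 8
    emg[post] <- rnorm(length(post)) * 25
  } else if (kind == "rems_pre") {
    pre <- (5 * fs + 1):(10 * fs)
    eeg[pre] <- infraslow:::band_noise(length(pre), fs, 5, 10) * 40 +
      infraslow:::band_noise(length(pre), fs, 1, 4) * 8
    emg[post] <- rnorm(length(post)) * 2.2
  } else {
    emg[post] <- rnorm(length(post)) * 2.2   # slight rise avoids rejection
  }
  structure(list(signals = list(eeg = eeg, emg = emg), fs = fs,
                 roles = c(eeg = "EEG", emg = "EMG")),
            class = "psg_recording")
}

stim_at_10 <- data.frame(onset_s = 10, duration_s = 3, type = "stimulus",
                         channel = "motor", true_period = "fragility",
                         woke = NA)

test_that("autoscoring verdicts on constructed trials", {
  expect_equal(autoscore_trials(mk_trial_rec("wake"),
                                stim_at_10)$verdict, "wake_up")
  expect_equal(autoscore_trials(mk_trial_rec("sleep"),
                                stim_at_10)$verdict, "sleep_through")
  expect_equal(autoscore_trials(mk_trial_rec("rems_pre"),
                                stim_at_10)$verdict, "rejected")
  # margins: a stimulus at the very edge is dropped with a warning
  expect_warning(sc <- autoscore_trials(mk_trial_rec("sleep"),
                                        data.frame(onset_s = 2,
                                                   duration_s = 3,
                                                   true_period = "x",
                                                   woke = NA)),
                 "edge")
  expect_equal(nrow(sc), 0)
  # 100-500 Hz band needs 1 kHz sampling
  lowfs <- mk_trial_rec("sleep"); lowfs$fs <- 500
  expect_error(autoscore_trials(lowfs, stim_at_10), "sampling rate")
})

test_that("trial order never changes verdicts", {
  rec <- mk_trial_rec("sleep")
  st2 <- rbind(stim_at_10, transform(stim_at_10, onset_s = 12))
  a <- autoscore_trials(rec, st2)
  b <- autoscore_trials(rec, st2[2:1, ])
  expect_setequal(paste(a$onset_s, a$verdict), paste(b$onset_s, b$verdict))
})

test_that("wake-up probability table behaves", {
  sc <- data.frame(onset_s = c(10, 20, 30, 40),
                   verdict = c("wake_up", "wake_up", "sleep_through",
                               "rejected"),
                   true_period = c("fragility", "fragility", "fragility",
                                   "continuity"))
  wp <- wakeup_probability(sc)
  frag <- wp[wp$period == "fragility", ]
  expect_equal(frag$p_wakeup, 2 / 3)
  expect_equal(frag$n_trials, 3)
  expect_true(all(wp$p_wakeup >= 0 & wp$p_wakeup <= 1, na.rm = TRUE))
  # all wake-ups -> probability one
  sc$verdict <- "wake_up"
  expect_true(all(wakeup_probability(sc)$p_wakeup == 1))
})

test_that("closed loop: gating, stimulation probability and determinism", {
  ses <- default_session()
  od <- online_period_detection(ses$recording, ses$hypnogram,
                                maxit = 120, seed = 1)
  cl1 <- closed_loop_session(ses, od$clf, "fragility", thr = od$thr,
                             seed = 5)
  cl2 <- closed_loop_session(ses, od$clf, "fragility", thr = od$thr,
                             seed = 5)
  expect_identical(cl1$stimuli$onset_s, cl2$stimuli$onset_s)
  expect_gt(cl1$n_gate_passes, 0)
  # stimulus count is binomial(n_gate_passes, 0.25); allow 4 sd
  p_hat <- nrow(cl1$stimuli) / cl1$n_gate_passes
  expect_lt(abs(p_hat - 0.25),
            4 * sqrt(0.25 * 0.75 / cl1$n_gate_passes))
  # an untrained classifier is refused
  expect_error(closed_loop_session(ses, list(), "fragility"),
               "untrained")

  # wake-up probability ordering: fragility above continuity under the
  # generator's response model (pooled trials from both targets)
  cl_c <- closed_loop_session(ses, od$clf, "continuity", thr = od$thr,
                              seed = 6)
  sc <- rbind(autoscore_trials(cl1$recording, cl1$stimuli),
              autoscore_trials(cl_c$recording, cl_c$stimuli))
  sc <- sc[sc$true_period %in% c("continuity", "fragility"), ]
  wp <- wakeup_probability(sc)
  if (all(c("fragility", "continuity") %in% wp$period)) {
    expect_gt(wp$p_wakeup[wp$period == "fragility"],
              wp$p_wakeup[wp$period == "continuity"])
  }
})

test_that("threshold calibration at the equal-error point", {
  set.seed(12)
  n <- 60
  woke <- rep(c(TRUE, FALSE), each = n / 2)
  trials <- data.frame(
    onset_s = seq_len(n) * 20,
    lowhigh_drop = ifelse(woke, rnorm(n, 2, 0.3), rnorm(n, 0, 0.3)),
    emg_ratio = ifelse(woke, rlnorm(n, log(6), 0.3),
                       rlnorm(n, log(1.1), 0.2)),
    verdict = "scored", true_period = "fragility", woke = woke)
  th <- calibrate_autoscore_thresholds(trials)
  expect_gt(th$drop, 0.5); expect_lt(th$drop, 1.6)
  expect_gt(th$emg, 1.2); expect_lt(th$emg, 4)
  expect_error(calibrate_autoscore_thresholds(trials[woke, ]),
               "both outcomes")
})
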