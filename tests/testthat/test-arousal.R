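# Activation index, AI-peak detection, phase-binned power, heart rate.

fake_band_traces <- function(delta, beta, low_gamma, fs = 10) {
  n <- length(delta)
  raw <- cbind(delta = delta, sigma = rep(1, n), beta = beta,
               low_gamma = low_gamma)
  structure(list(t = (seq_len(n) - 1) / fs, fs = fs, raw = raw,
                 norm = raw / sum(colMeans(raw)),
                 mask = rep(TRUE, n)),
            class = "band_traces")
}

test_that("activation index identities", {
  bt <- fake_band_traces(delta = c(2, 2, 4), beta = c(1, 1, 1),
                         low_gamma = c(1, 1, 1))
  ai <- activation_index(bt)
  expect_equal(ai$ai[1], 0)                       # (1+1)/2 -> ln 1
  expect_equal(ai$ai[3], -log(2))                 # delta doubled
  bt$raw[2, "delta"] <- 0
  expect_true(is.na(activation_index(bt)$ai[2]))
})

test_that("AI is invariant to a global signal gain", {
  ses <- short_session()
  bt <- band_power_traces(ses$recording, ses$hypnogram)
  rec2 <- ses$recording
  rec2$signals$eeg <- rec2$signals$eeg * 7
  bt2 <- band_power_traces(rec2, ses$hypnogram)
  expect_equal(activation_index(bt2)$ai, activation_index(bt)$ai,
               tolerance = 1e-9)
})

test_that("AI peak detection flags injected transients only", {
  # clean sigma oscillation, constant AI with one transient per flagged
  # cycle
  st <- synthetic_sigma_trace(duration_s = 1200)
  h <- all_nrems_hypnogram(1200)
  cs <- detect_cycles(st, h)
  n <- length(st$t)
  ai_const <- structure(list(t = st$t, fs = st$fs, ai = rep(0.5, n)),
                        class = "ai_trace")
  flags0 <- detect_ai_peaks(ai_const, cs, st)
  expect_false(any(flags0$ai_peak))

  ai_vec <- rep(0.5, n)
  # inject a 3 s transient in the fragility span of cycles 3 and 7
  for (i in c(3, 7)) {
    t0 <- cs$trough_s[i] - 5
    ai_vec[(t0 * 10):(t0 * 10 + 30)] <- 3
  }
  ai_t <- structure(list(t = st$t, fs = st$fs, ai = ai_vec),
                    class = "ai_trace")
  flags <- detect_ai_peaks(ai_t, cs, st, smooth_s = 1)
  expect_setequal(which(flags$ai_peak), c(3, 7))
  expect_equal(flags$ai_peak_t[3], cs$trough_s[3] - 5 + 1.5,
               tolerance = 1.5)
})

test_that("phase-binned profiles: constant band is flat, sigma peaks at
           the cycle peak", {
  ses <- default_session()
  st <- cached_sigma_trace("default", ses)
  cs <- detect_cycles(st, ses$hypnogram)
  cl <- classify_fragility_outcomes(cs, ses$hypnogram, ses$events, st)
  bt <- band_power_traces(ses$recording, ses$hypnogram)
  pb <- phase_binned_power(bt, st, cl$cycles)
  prof <- pb$`NREMS-continuing`$profile
  # sigma maximal in the bins adjacent to 0 deg (first or last bin)
  expect_true(which.max(prof[, "sigma"]) %in% c(1, 2, 17, 18))
  # delta higher in fragility than continuity for sham
  expect_gt(pb$`NREMS-continuing`$fragility_mean["delta"],
            pb$`NREMS-continuing`$continuity_mean["delta"])

  bt_flat <- fake_band_traces(delta = rep(2, length(st$t)),
                              beta = rep(1, length(st$t)),
                              low_gamma = rep(1, length(st$t)))
  st_c <- synthetic_sigma_trace(duration_s = length(st$t) / 10)
  cs_c <- detect_cycles(st_c, all_nrems_hypnogram(length(st$t) / 10))
  cs_c$outcome <- "NREMS-continuing"
  pb_flat <- phase_binned_power(bt_flat, st_c, cs_c)
  prof_flat <- pb_flat$`NREMS-continuing`$profile
  expect_lt(diff(range(prof_flat[, "delta"])), 1e-9)
})

test_that("R-peak detection: rate, scale invariance and refractory", {
  fs <- 1000
  set.seed(9)
  n <- 120 * fs
  emg <- rnorm(n) * 2
  beats <- seq(0.5, 119.5, by = 0.1)            # 10 Hz
  emg[round(beats * fs)] <- emg[round(beats * fs)] + 120
  hr <- heart_rate_from_emg(emg, fs)
  expect_equal(length(hr$rpeaks_s), length(beats), tolerance = 2)
  expect_equal(median(hr$rate_bpm), 600, tolerance = 2)

  hr2 <- heart_rate_from_emg(emg * 2, fs)
  expect_identical(hr2$rpeaks_s, hr$rpeaks_s)   # gain invariance

  # two impulses 30 ms apart: the second is inside the refractory window
  emg3 <- rnorm(2 * fs) * 0.5
  emg3[c(1000, 1030)] <- 150
  hr3 <- heart_rate_from_emg(emg3, fs)
  # only one of the two impulses survives the 50 ms refractory window
  expect_equal(sum(hr3$rpeaks_s > 0.99 & hr3$rpeaks_s < 1.04), 1)
})

test_that("state-wise heart rate recovers the generator's rates", {
  ses <- default_session()
  hr <- heart_rate_from_emg(ses$recording$signals$emg,
                            ses$recording$fs)
  rates <- heart_rate_by_state(hr, ses$hypnogram)
  expect_equal(rates[["NREMS"]], ses$cfg$hr_nrems_hz * 60,
               tolerance = 0.02 * ses$cfg$hr_nrems_hz * 60)
  expect_equal(rates[["Wake"]], ses$cfg$hr_wake_hz * 60,
               tolerance = 0.02 * ses$cfg$hr_wake_hz * 60)
  expect_equal(rates[["REMS"]], ses$cfg$hr_rems_hz * 60,
               tolerance = 0.02 * ses$cfg$hr_rems_hz * 60)
})

test_that("heart-rate cycle profiles and AI-peak breakdown bookkeeping", {
  ses <- default_session()
  st <- cached_sigma_trace("default", ses)
  cs <- detect_cycles(st, ses$hypnogram)
  cl <- classify_fragility_outcomes(cs, ses$hypnogram, ses$events, st)
  bt <- band_power_traces(ses$recording, ses$hypnogram)
  cs2 <- detect_ai_peaks(activation_index(bt), cl$cycles, st)
  hr <- heart_rate_from_emg(ses$recording$signals$emg,
                            ses$recording$fs)
  hbc <- heart_rate_by_cycle(hr, cs2, st)
  expect_equal(sum(hbc$n_cycles),
               sum(cs2$outcome == "NREMS-continuing"))

  ad <- ai_peak_density(cs2, ses$hypnogram)
  expect_equal(sum(ad$breakdown), 1, tolerance = 1e-12)
  # a cycle set with no flags gives an all-zero density
  cs3 <- cs2; cs3$ai_peak <- FALSE
  expect_true(all(ai_peak_density(cs3,
                                  ses$hypnogram)$density$peaks == 0))
})
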