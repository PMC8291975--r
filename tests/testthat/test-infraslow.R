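# Core infraslow machinery: phase convention, sigma trace, spectrum,
# cycle detection, event-phase sampling, outcome classification.

test_that("phase convention: peak at 0, trough at 180, quadrature at 90", {
  t <- (0:5999) / 10
  x <- cos(2 * pi * t / 50)
  ph <- compute_phase(x)
  expect_equal(ph[t == 25], 180, tolerance = 1e-6)
  p0 <- ph[t == 50][1]
  expect_lt(min(p0, 360 - p0), 1e-4)
  expect_equal(ph[t == 12.5], 90, tolerance = 1e-6)
  # strictly increasing modulo 360 on a pure sinusoid
  d <- diff(ph) %% 360
  expect_true(all(d[d < 180] > 0))
  expect_error(compute_phase(rep(1, 100)), "constant")
})

test_that("sigma trace: normalization identity and scale invariance", {
  ses <- short_session()
  st <- cached_sigma_trace("short", ses)
  expect_equal(mean(st$power[st$mask]), 1, tolerance = 1e-9)
  expect_equal(mean(st$smooth[st$mask]), 1, tolerance = 1e-9)

  rec3 <- ses$recording
  rec3$signals$eeg <- rec3$signals$eeg * 3
  st3 <- compute_sigma_trace(rec3, ses$hypnogram)
  expect_equal(st3$power, st$power, tolerance = 1e-9)
  expect_equal(st3$phase_deg, st$phase_deg, tolerance = 1e-6)
})

test_that("amplitude-modulated carrier yields a 0.02 Hz sigma trace", {
  # oracle: rectified band-pass envelope of the same signal
  fs <- 1000
  dur <- 1000
  t <- (seq_len(fs * dur) - 1) / fs
  env_pow <- 1 + 0.9 * cos(2 * pi * t / 50)
  x <- sqrt(env_pow) * sin(2 * pi * 12 * t)
  h <- all_nrems_hypnogram(dur)
  st <- compute_sigma_trace(x, h, fs = fs)
  # the smoothed trace oscillates at 0.02 Hz with the injected depth
  sp <- infraslow_spectrum(st, h)
  expect_equal(sp$peak_freq_hz, 0.02, tolerance = 0.0026)
  # oracle comparison: normalized envelope power on the same time base
  env10 <- env_pow[seq(1, length(t), by = 100)]
  env10 <- env10 / mean(env10)
  keep <- 200:(length(st$smooth) - 200)       # away from filter edges
  expect_gt(cor(st$smooth[keep], env10[keep]), 0.99)
})

test_that("unmodulated sigma shows no infraslow peak where a modulated
           one does", {
  set.seed(8)
  fs <- 10; dur <- 2000
  tt <- (seq_len(dur * fs) - 1) / fs
  b <- as.numeric(signal::fir1(100, 0.0125 / 5))
  mk <- function(p) {
    sm <- signal::filtfilt(b, 1, p)
    structure(list(t = tt, fs = fs, power = p, smooth = sm / mean(sm),
                   phase_deg = NULL, mask = rep(TRUE, length(p))),
              class = "sigma_trace")
  }
  h <- all_nrems_hypnogram(dur)
  flat <- mk(1 + 0.05 * rnorm(dur * fs))
  mod <- mk((1 + 0.9 * cos(2 * pi * tt / 50)) *
              (1 + 0.05 * rnorm(dur * fs)))
  sp_flat <- infraslow_spectrum(flat, h)
  sp_mod <- infraslow_spectrum(mod, h)
  # the modulated trace concentrates power at 0.02 Hz; the flat one has
  # no comparable peak anywhere
  expect_gt(sp_mod$peak_power, 20 * sp_flat$peak_power)
  expect_lt(abs(sp_mod$peak_freq_hz - 0.02), 0.0025 + 1e-9)
})

test_that("cycle detection: exact count and extrema on a clean envelope", {
  # 21 peaks -> 20 peak-to-peak cycles
  st <- synthetic_sigma_trace(duration_s = 21 * 50 + 10)
  h <- all_nrems_hypnogram(21 * 50 + 12)
  cs <- detect_cycles(st, h)
  expect_equal(nrow(cs), 20)
  # analytic positions: peaks at multiples of 50 s, troughs at +25 s
  expect_true(all(abs((cs$start_s %% 50)) <= 0.1 |
                    abs((cs$start_s %% 50) - 50) <= 0.1))
  expect_true(all(abs(cs$trough_s - cs$start_s - 25) <= 0.1))
  # phase/extrema consistency
  expect_true(all(abs(st$phase_deg[cs$trough] - 180) < 10))
  pk_ph <- st$phase_deg[cs$peak1]
  expect_true(all(pmin(pk_ph, 360 - pk_ph) < 10))
})

test_that("cycle detection separation and amplitude rules reject
           candidates", {
  fs <- 10
  t <- (0:20000) / fs
  # 15 s period: raw extrema are 15 s apart, under the separation rule;
  # whatever survives pruning must keep same-kind extrema > 20 s apart
  st_fast <- synthetic_sigma_trace(duration_s = 2000, period_s = 15)
  cs_f <- detect_cycles(st_fast, all_nrems_hypnogram(2000))
  if (nrow(cs_f) > 1) {
    expect_gt(min(diff(cs_f$start_s)), 20)
    expect_gt(min(diff(cs_f$trough_s)), 20)
  }
  expect_true(all(cs_f$trough_s - cs_f$start_s > 20 - 1e-9 |
                    nrow(cs_f) == 0))
  # sub-mean local maxima must not count as peaks
  p <- 1 + 0.9 * cos(2 * pi * t / 50)
  dip <- 0.3 * exp(-((t - 500) %% 50 - 25)^2 / 4)
  p2 <- p - pmax(0, 0.95 - p) * 0 - dip      # wiggle below the mean
  st2 <- structure(list(t = t, fs = fs, power = p2, smooth = p2,
                        phase_deg = compute_phase(p2),
                        mask = rep(TRUE, length(t))),
                   class = "sigma_trace")
  cs2 <- detect_cycles(st2, all_nrems_hypnogram(2001))
  expect_true(all(st2$smooth[cs2$peak1] > 1))
  expect_true(all(st2$smooth[cs2$trough] < 1))
})

test_that("phase at events: trough sampling and 4 s offsets", {
  st <- synthetic_sigma_trace(duration_s = 600)
  ev <- data.frame(onset_s = c(125, 275))     # exact troughs
  ph <- phase_at_events(st, ev)
  expect_equal(unname(ph[, 1]), c(180, 180), tolerance = 1)
  # 4 s = 28.8 deg at 0.02 Hz
  expect_equal(unname(ph[, 2]), c(180, 180) - 28.8, tolerance = 1.5)
  expect_equal(unname(ph[, 3]), c(180, 180) - 57.6, tolerance = 1.5)
  expect_equal(unname(ph[, 4]), c(180, 180) - 86.4, tolerance = 1.5)
  expect_error(phase_at_events(st, data.frame(onset_s = 1e5)),
               "outside")
})

test_that("fragility outcomes partition to one and degenerate cases", {
  ses <- default_session()
  st <- cached_sigma_trace("default", ses)
  cs <- detect_cycles(st, ses$hypnogram)
  cl <- classify_fragility_outcomes(cs, ses$hypnogram, ses$events, st)
  expect_equal(sum(cl$proportions), 1, tolerance = 1e-12)
  expect_true(all(cl$cycles$outcome %in%
                    c("MA", "REMS-transition", "NREMS-continuing")))

  no_ev <- data.frame(onset_s = numeric(0))
  h <- all_nrems_hypnogram(1200)
  st0 <- synthetic_sigma_trace(1200)
  cs0 <- detect_cycles(st0, h)
  cl0 <- classify_fragility_outcomes(cs0, h, no_ev, st0)
  expect_equal(unname(cl0$proportions["NREMS-continuing"]), 1)
})
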