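# Epoch FFTs, wake and sleep normalizations, QW/AW segmentation, gamma
# and delta summaries.

flat_hyp <- function(n_ep, state = "Wake") hypnogram(rep(state, n_ep))

test_that("periodogram fundamentals: sinusoid peak, constant epoch,
           Parseval-style band power", {
  fs <- 200
  t <- (0:(4 * fs - 1)) / fs
  x <- c(sin(2 * pi * 10 * t), rep(1, 4 * fs))
  es <- epoch_spectra(x, flat_hyp(2), fs = fs, max_freq = 100)
  expect_equal(es$freq[which.max(es$psd[, 1])], 10)
  expect_equal(max(es$psd[, 2]), 0, tolerance = 1e-20)

  # band power integrates back to the time-domain variance
  set.seed(1)
  y <- infraslow:::band_noise(fs * 40, fs, 8, 12) * 3
  esy <- epoch_spectra(y, flat_hyp(10), fs = fs, max_freq = 100)
  bp <- sum(rowMeans(esy$psd)) * 0.25
  expect_equal(bp, var(y), tolerance = 0.1 * var(y))
})

test_that("white-noise epochs give a flat mean spectrum", {
  set.seed(2)
  fs <- 250
  x <- rnorm(fs * 4 * 200)
  es <- epoch_spectra(x, flat_hyp(200), fs = fs, max_freq = 120)
  m <- rowMeans(es$psd)[-1]
  expect_lt(sd(m) / mean(m), 0.12)
})

test_that("sleep spectra: transition exclusion, symmetry and scale
           invariance", {
  ses <- default_session()
  es <- epoch_spectra(ses$recording, ses$hypnogram)
  ss <- sleep_state_spectrum(es)
  # NREMS peaks in delta, REMS in theta (excluding the DC bin)
  bands <- band_definitions()
  peak_f <- function(s) ss$freq[-1][which.max(ss$spectra[-1, s])]
  expect_true(peak_f("NREMS") >= 1 & peak_f("NREMS") <= 4)
  expect_true(peak_f("REMS") >= 5 & peak_f("REMS") <= 10)

  # doubling the gain leaves normalized spectra untouched
  rec2 <- ses$recording
  rec2$signals$eeg <- rec2$signals$eeg * 2
  ss2 <- sleep_state_spectrum(epoch_spectra(rec2, ses$hypnogram))
  expect_equal(ss2$spectra, ss$spectra, tolerance = 1e-10)

  # identical spectra across states normalize to unit mean level
  set.seed(3)
  x <- rnorm(200 * 4 * 90)
  h <- hypnogram(rep(c("Wake", "NREMS", "REMS"), each = 30))
  one <- sleep_state_spectrum(epoch_spectra(x, h, fs = 200,
                                            max_freq = 90))
  lv <- colMeans(one$spectra[band_bins(one$freq, c(0.75, 47)), ])
  expect_equal(mean(lv), 1, tolerance = 1e-9)
  expect_equal(unname(lv["Wake"]), 1, tolerance = 0.05)
})

test_that("wake spectra normalize to unit 2-30 Hz sum", {
  ses <- default_session()
  es <- epoch_spectra(ses$recording, ses$hypnogram)
  qa <- segment_quiet_active_wake(ses$recording$signals$emg,
                                  ses$recording$fs, ses$hypnogram)
  ws <- wake_spectrum(es, qa$qw, qa$aw)
  bins <- band_bins(ws$freq, c(2, 30))
  expect_equal(sum(ws$qw[bins]), 1, tolerance = 1e-12)
  expect_equal(sum(ws$aw[bins]), 1, tolerance = 1e-12)
  expect_error(wake_spectrum(es, integer(0), qa$aw), "empty")
})

test_that("QW/AW segmentation: percentile oracle on a monotone ramp", {
  # 100 wake epochs with EMG variance increasing monotonically: the
  # rank-based oracle says QW are epochs ranked in (10, 25]% and AW in
  # (50, 99]%.
  fs <- 100
  n_ep <- 100
  set.seed(4)
  amp <- seq(1, 20, length.out = n_ep)
  emg <- unlist(lapply(amp, function(a) rnorm(4 * fs) * a))
  h <- flat_hyp(n_ep)
  seg <- segment_quiet_active_wake(emg, fs, h)
  lv <- log(colMeans(matrix(emg^2, nrow = 4 * fs)))
  q <- quantile(lv, c(0.10, 0.25, 0.50, 0.99), type = 7)
  oracle_qw <- which(lv >= q[1] & lv <= q[2])
  oracle_aw <- which(lv >= q[3] & lv <= q[4])
  # monotone ramp makes qualifying epochs consecutive, so the run rule
  # keeps them all
  expect_setequal(seg$qw, oracle_qw)
  expect_setequal(seg$aw, oracle_aw)
  expect_length(intersect(seg$qw, seg$aw), 0)
})

test_that("QW requires at least three consecutive qualifying epochs", {
  fs <- 100
  set.seed(5)
  # low-EMG epochs isolated in pairs: never 3 in a row
  amp <- rep(c(1, 1, 10, 10, 10), 20)
  emg <- unlist(lapply(amp, function(a) rnorm(4 * fs) * a))
  seg <- segment_quiet_active_wake(emg, fs, flat_hyp(100))
  expect_length(seg$qw, 0)
})

test_that("gamma ratio is 1 for identical recordings and tracks a
           doubled 60-80 Hz content", {
  ses <- short_session()
  es <- epoch_spectra(ses$recording, ses$hypnogram)
  r <- gamma_ratio(es, es)
  expect_equal(unname(r), rep(1, length(r)), tolerance = 1e-12)

  rec2 <- ses$recording
  extra <- infraslow:::band_noise(length(rec2$signals$eeg),
                                  rec2$fs, 60, 80)
  # add an independent component equal in power to the existing one,
  # state by state, so 60-80 Hz power roughly doubles
  g <- c(Wake = 6, NREMS = 3, REMS = 5, MA = 6)
  st <- infraslow:::state_at_samples(ses$hypnogram, rec2$fs,
                                     length(extra))
  rec2$signals$eeg <- rec2$signals$eeg + extra * g[st]
  r2 <- gamma_ratio(es, epoch_spectra(rec2, ses$hypnogram))
  expect_true(all(r2 > 1.5 & r2 < 2.6))
})

test_that("delta time course is flat at one for stationary delta and
           splits periods evenly", {
  ses <- default_session()
  es <- epoch_spectra(ses$recording, ses$hypnogram)
  dt <- delta_timecourse(es, ses$hypnogram, n_periods = 6,
                         norm_window_s = c(0, 3600))
  expect_equal(nrow(dt), 6)
  expect_equal(mean(dt$delta_norm), 1, tolerance = 0.05)
  # equal epoch counts (+-1)
  sel <- which(es$states == "NREMS" & !es$transition_adjacent)
  counts <- table(ceiling(seq_along(sel) * 6 / length(sel)))
  expect_lte(diff(range(counts)), 1)
  expect_error(delta_timecourse(es, ses$hypnogram, n_periods = 6,
                                norm_window_s = c(30000, 40000)),
               "normalization")
})
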