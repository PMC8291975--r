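# Phase-binned band dynamics, activation index, local (AI-peak) arousals,
# EMG-derived heart rate.

phase_bin_index <- function(phase_deg, n_bins = 18) {
  pmin(n_bins, floor(wrap360(phase_deg) / (360 / n_bins)) + 1L)
}

#' Phase-binned band power profiles
#'
#' Mean normalized band power in 18 bins of 20 deg of infraslow phase,
#' averaged across cycles, separately for MA-containing and
#' NREMS-continuing cycles, plus summary means over the continuity
#' (270-90 deg) and fragility (90-270 deg) spans.
#'
#' @param bt a [band_power_traces()] result.
#' @param st the matching `sigma_trace` (phase source).
#' @param cs a classified [detect_cycles()] result (`outcome` filled).
#' @param n_bins number of phase bins (18).
#' @return list per cycle class (`MA`, `NREMS-continuing`): `profile`
#'   (bins x bands), `continuity_mean`, `fragility_mean` (named by band),
#'   `n_cycles`.
#' @export
phase_binned_power <- function(bt, st, cs, n_bins = 18) {
  stopifnot(nrow(bt$raw) == length(st$phase_deg))
  classes <- list(`MA` = which(cs$outcome == "MA"),
                  `NREMS-continuing` = which(cs$outcome == "NREMS-continuing"))
  res <- list()
  for (cl in names(classes)) {
    rows <- classes[[cl]]
    if (!length(rows)) next
    idx <- unlist(lapply(rows, function(i) cs$peak1[i]:cs$peak2[i]))
    ph <- st$phase_deg[idx]
    bin <- phase_bin_index(ph, n_bins)
    prof <- apply(bt$norm[idx, , drop = FALSE], 2, function(v) {
      as.numeric(tapply(v, factor(bin, levels = seq_len(n_bins)), mean,
                        na.rm = TRUE))
    })
    frag <- ph >= 90 & ph <= 270
    res[[cl]] <- list(
      profile = prof,
      continuity_mean = colMeans(bt$norm[idx[!frag], , drop = FALSE],
                                 na.rm = TRUE),
      fragility_mean = colMeans(bt$norm[idx[frag], , drop = FALSE],
                                na.rm = TRUE),
      n_cycles = length(rows))
  }
  res
}

#' Activation index
#'
#' Pointwise natural logarithm of (beta + low-gamma) power over delta
#' power on the common 10 Hz base. Samples with non-positive band power
#' are masked (`NA`). Invariant to a global signal gain.
#'
#' @param bt a [band_power_traces()] with `delta`, `beta` and `low_gamma`
#'   bands.
#' @return object of class `ai_trace`: `t`, `fs`, `ai`.
#' @export
activation_index <- function(bt) {
  need <- c("delta", "beta", "low_gamma")
  if (!all(need %in% colnames(bt$raw)))
    stop("band traces must include ", paste(need, collapse = ", "))
  num <- bt$raw[, "beta"] + bt$raw[, "low_gamma"]
  den <- bt$raw[, "delta"]
  ai <- ifelse(num > 0 & den > 0, log(num / den), NA_real_)
  structure(list(t = bt$t, fs = bt$fs, ai = ai), class = "ai_trace")
}

#' @export
print.ai_trace <- function(x, ...) {
  cat("<ai_trace> ", length(x$ai), " samples @ ", x$fs, " Hz\n", sep = "")
  invisible(x)
}

#' Detect intermittent AI peaks within fragility spans
#'
#' Within each cycle, local maxima of the activation index are searched at
#' phase values 90-270 deg; maxima exceeding that cycle's mean AI flag the
#' cycle as carrying an intermittent peak (a local-arousal candidate when
#' the cycle continues into NREMS). A peak counts when its maximum lies
#' inside the span.
#'
#' @param ai an [activation_index()] result.
#' @param cs a `cycle_set`.
#' @param st the matching `sigma_trace`.
#' @param smooth_s moving-average width applied to the AI trace before
#'   peak search, seconds (default 5). Smoothing suppresses
#'   sample-to-sample estimator noise so that only sustained activation
#'   transients cross the cycle-mean threshold; an intermittent peak is a
#'   seconds-long event, not a single noisy sample.
#' @return the `cycle_set` with `ai_peak` (logical) and `ai_peak_t`
#'   (time of the highest qualifying peak, `NA` if none).
#' @export
detect_ai_peaks <- function(ai, cs, st, smooth_s = 5) {
  stopifnot(length(ai$ai) == length(st$phase_deg))
  a <- ai$ai
  w <- max(1L, round(smooth_s * ai$fs))
  if (w > 1) {
    a_f <- a
    a_f[is.na(a_f)] <- stats::median(a, na.rm = TRUE)
    a <- as.numeric(stats::filter(a_f, rep(1 / w, w), sides = 2))
    a[is.na(a)] <- a_f[is.na(a)]
  }
  cs$ai_peak <- rep(FALSE, nrow(cs))
  cs$ai_peak_t <- rep(NA_real_, nrow(cs))
  for (i in seq_len(nrow(cs))) {
    span <- cs$peak1[i]:cs$peak2[i]
    vals <- a[span]
    mu <- mean(vals, na.rm = TRUE)
    frag <- span[st$phase_deg[span] >= 90 & st$phase_deg[span] <= 270]
    if (length(frag) < 3) next
    seg <- a[frag]
    seg[is.na(seg)] <- -Inf
    pk <- find_extrema(seg, "max")
    pk <- pk[seg[pk] > mu]
    if (length(pk)) {
      cs$ai_peak[i] <- TRUE
      cs$ai_peak_t[i] <- st$t[frag[pk[which.max(seg[pk])]]]
    }
  }
  cs
}

#' Heart rate from the EMG signal
#'
#' The EMG is high-pass filtered above 25 Hz and squared; R peaks of the
#' electrocardiographic artifact are detected as local maxima of the
#' squared trace after division by its rolling local median (0.5 s
#' window; this keeps the detection scale-invariant and robust to phasic
#' EMG bursts), thresholded at median + k * MAD with a refractory
#' constraint.
#'
#' @param emg EMG vector.
#' @param fs sampling rate, Hz (>= 200).
#' @param k_mad threshold multiplier (default 8).
#' @param refractory_s minimum inter-beat interval, seconds (default
#'   0.05).
#' @return object of class `heart_rate`: `rpeaks_s`, `ibi_s`, `rate_t`
#'   (inter-beat midpoints) and `rate_bpm`. Empty with a warning when no
#'   peak is found.
#' @export
heart_rate_from_emg <- function(emg, fs, k_mad = 8, refractory_s = 0.05) {
  if (fs < 200) stop("need fs >= 200 Hz for R-peak detection")
  hp <- signal::butter(4, 25 / (fs / 2), type = "high")
  sq <- signal::filtfilt(hp, emg)^2
  win <- 2 * floor(0.25 * fs) + 1
  base <- stats::runmed(sq, win)
  z <- sq / pmax(base, .Machine$double.eps)
  thr <- stats::median(z) + k_mad * stats::mad(z)
  pk <- find_extrema(z, "max")
  pk <- pk[z[pk] > thr]
  pk <- prune_min_distance(pk, z[pk], round(refractory_s * fs))
  if (!length(pk)) {
    warning("no R peaks detected")
    return(structure(list(rpeaks_s = numeric(0), ibi_s = numeric(0),
                          rate_t = numeric(0), rate_bpm = numeric(0)),
                     class = "heart_rate"))
  }
  tp <- (pk - 1) / fs
  ibi <- diff(tp)
  structure(list(rpeaks_s = tp, ibi_s = ibi,
                 rate_t = tp[-1] - ibi / 2, rate_bpm = 60 / ibi),
            class = "heart_rate")
}

#' @export
print.heart_rate <- function(x, ...) {
  cat("<heart_rate> ", length(x$rpeaks_s), " beats",
      if (length(x$rate_bpm)) paste0(", median ",
                                     round(stats::median(x$rate_bpm)),
                                     " bpm"), "\n", sep = "")
  invisible(x)
}

#' Mean heart rate per vigilance state
#'
#' Beats counted within each state's epochs divided by the state's total
#' time.
#'
#' @param hr a [heart_rate_from_emg()] result.
#' @param hyp matching [hypnogram()].
#' @return named numeric vector, beats per minute.
#' @export
heart_rate_by_state <- function(hr, hyp) {
  es <- epoch_s_of(hyp)
  st_at <- hyp$state[epoch_of_time(hyp, hr$rpeaks_s)]
  lv <- c("Wake", "NREMS", "REMS", "MA")
  counts <- table(factor(st_at, levels = lv))
  secs <- table(factor(hyp$state, levels = lv)) * es
  out <- 60 * as.numeric(counts) / as.numeric(secs)
  names(out) <- lv
  out
}

#' Heart-rate dynamics across infraslow cycles
#'
#' Instantaneous rate (constant between beats) sampled on the sigma-trace
#' time base, averaged per 20 deg phase bin and per continuity/fragility
#' span, split by the cycle's AI-peak flag. Applied to NREMS-continuing
#' cycles.
#'
#' @param hr a `heart_rate`.
#' @param cs a `cycle_set` with `ai_peak` filled ([detect_ai_peaks()]).
#' @param st the matching `sigma_trace`.
#' @param n_bins phase bins (18).
#' @return list with `profiles` (bins x class matrix, classes `peak` and
#'   `no_peak`), `span_means` (data frame class x span) and `n_cycles`.
#' @export
heart_rate_by_cycle <- function(hr, cs, st, n_bins = 18) {
  if (length(hr$rate_bpm) < 2) stop("heart-rate trace too short")
  rate10 <- stats::approx(hr$rate_t, hr$rate_bpm, xout = st$t,
                          method = "constant", rule = 2)$y
  keep <- which(cs$outcome == "NREMS-continuing")
  classes <- list(peak = keep[cs$ai_peak[keep] %in% TRUE],
                  no_peak = keep[cs$ai_peak[keep] %in% FALSE])
  profiles <- matrix(NA_real_, n_bins, 2,
                     dimnames = list(NULL, names(classes)))
  span_means <- list()
  for (cl in names(classes)) {
    rows <- classes[[cl]]
    if (!length(rows)) next
    idx <- unlist(lapply(rows, function(i) cs$peak1[i]:cs$peak2[i]))
    ph <- st$phase_deg[idx]
    bin <- phase_bin_index(ph, n_bins)
    profiles[, cl] <- as.numeric(
      tapply(rate10[idx], factor(bin, levels = seq_len(n_bins)), mean))
    frag <- ph >= 90 & ph <= 270
    span_means[[cl]] <- data.frame(
      class = cl,
      continuity = mean(rate10[idx[!frag]]),
      fragility = mean(rate10[idx[frag]]))
  }
  list(profiles = profiles,
       span_means = do.call(rbind, span_means),
       n_cycles = vapply(classes, length, 1L))
}

#' Density of AI-peak fragility periods and outcome breakdown
#'
#' Hourly-binned count of NREMS-continuing cycles flagged with an
#' intermittent AI peak per hour of NREMS, plus the two-level breakdown
#' of all cycles into MA vs continuing (peak / no peak).
#'
#' @param cs a classified `cycle_set` with `ai_peak`.
#' @param hyp matching [hypnogram()].
#' @param bin_s ZT bin width, seconds (3600).
#' @return list with `density` (data frame zt_bin, nrems_h, peaks,
#'   per_h_nrems) and `breakdown` (named proportions summing to 1).
#' @export
ai_peak_density <- function(cs, hyp, bin_s = 3600) {
  es <- epoch_s_of(hyp)
  total_s <- nrow(hyp) * es
  edges <- seq(0, total_s, by = bin_s)
  if (edges[length(edges)] < total_s) edges <- c(edges, total_s)
  cont <- cs$outcome == "NREMS-continuing"
  flag_t <- cs$trough_s[cont & cs$ai_peak %in% TRUE]
  ep_t <- (hyp$epoch - 0.5) * es
  dens <- data.frame(zt_bin = edges[-length(edges)] / 3600)
  dens$nrems_h <- vapply(seq_len(nrow(dens)), function(i) {
    sum(hyp$state == "NREMS" &
          ep_t >= edges[i] & ep_t < edges[i + 1]) * es / 3600
  }, 1)
  dens$peaks <- vapply(seq_len(nrow(dens)), function(i) {
    sum(flag_t >= edges[i] & flag_t < edges[i + 1])
  }, 1)
  dens$per_h_nrems <- ifelse(dens$nrems_h > 0, dens$peaks / dens$nrems_h,
                             NA_real_)
  n <- max(1L, nrow(cs))
  breakdown <- c(
    ma = sum(cs$outcome == "MA") / n,
    continuing_peak = sum(cont & cs$ai_peak %in% TRUE) / n,
    continuing_no_peak = sum(cont & cs$ai_peak %in% FALSE) / n,
    rems_transition = sum(cs$outcome == "REMS-transition") / n)
  list(density = dens, breakdown = breakdown)
}
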