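# Streaming vigilance-state machine, online sigma estimate,
# continuity/fragility classifier and shuffle validation.

#' Per-second online features
#'
#' For every second (from second 4 on), the FFT of the mean-centered last
#' 4 s of EEG gives the delta (1-4 Hz) / theta (5-10 Hz) power ratio and
#' the sigma (10-15 Hz) band power; the EMG feature is the median of the
#' squared EMG over the last second (the median is robust to the
#' electrocardiographic spikes riding on a mouse neck EMG).
#'
#' @param rec a `psg_recording` with `eeg` and `emg` channels.
#' @param work_fs EEG analysis rate after decimation, Hz.
#' @return data frame with `second` (window end, s), `ratio`, `sigma`,
#'   `emg`.
#' @export
online_features <- function(rec, work_fs = 100) {
  fs <- rec$fs
  eeg <- lowpass_decimate(rec$signals$eeg, fs, work_fs)
  emg <- rec$signals$emg
  dur <- floor(length(eeg) / work_fs)
  bands <- band_definitions()
  nwin <- 4 * work_fs
  f <- (seq_len(nwin %/% 2 + 1) - 1) / 4
  bd <- band_bins(f, bands$delta)
  bt <- band_bins(f, bands$theta)
  bs <- band_bins(f, bands$sigma)
  out <- data.frame(second = 4:dur, ratio = NA_real_, sigma = NA_real_,
                    emg = NA_real_)
  for (r in seq_len(nrow(out))) {
    s <- out$second[r]
    w <- eeg[((s - 4) * work_fs + 1):(s * work_fs)]
    P <- Mod(stats::fft(w - mean(w))[seq_len(nwin %/% 2 + 1)])^2
    out$ratio[r] <- mean(P[bd]) / mean(P[bt])
    out$sigma[r] <- mean(P[bs])
    e <- emg[((s - 1) * fs + 1):(s * fs)]
    out$emg[r] <- stats::median(e^2)
  }
  out
}

#' Calibrate state-machine thresholds from a labelled stretch
#'
#' The transition rules need four heuristically set thresholds. They are
#' calibrated per recording from a labelled calibration window (default
#' the first 10 min; automatically extended to the whole recording when a
#' state is missing from the window): the high EMG threshold is the 75th
#' percentile of wake EMG power, the low EMG threshold the 10th
#' percentile of NREMS EMG power, and the ratio thresholds the geometric
#' midpoints between the wake/NREMS and REMS/NREMS median delta/theta
#' ratios.
#'
#' @param feats [online_features()] output.
#' @param hyp reference [hypnogram()] (MA counts as Wake).
#' @param window_s calibration window length, seconds.
#' @return list with `emg_high`, `emg_low`, `ratio_high`, `ratio_low`.
#' @export
calibrate_online_thresholds <- function(feats, hyp, window_s = 600) {
  lab <- hyp$state[epoch_of_time(hyp, feats$second - 0.5)]
  lab[lab == "MA"] <- "Wake"
  win <- feats$second <= window_s
  if (!all(c("Wake", "NREMS") %in% lab[win])) win <- rep(TRUE, length(lab))
  l <- lab[win]; f <- feats[win, ]
  emg_high <- stats::quantile(f$emg[l == "Wake"], 0.75, names = FALSE)
  emg_low <- stats::quantile(f$emg[l == "NREMS"], 0.10, names = FALSE)
  r_wake <- stats::median(f$ratio[l == "Wake"])
  r_nrems <- stats::median(f$ratio[l == "NREMS"])
  ratio_high <- sqrt(r_wake * r_nrems)
  ratio_low <- if (any(l == "REMS")) {
    sqrt(stats::median(f$ratio[l == "REMS"]) * r_nrems)
  } else ratio_high / 4
  list(emg_high = emg_high, emg_low = emg_low,
       ratio_high = ratio_high, ratio_low = ratio_low)
}

#' One step of the online vigilance-state machine
#'
#' Applies the seven transition rules given the current likely state and
#' the last five seconds of delta/theta ratio and EMG power (index 5 =
#' most recent). Out of Wake: to NREMS when the last 3 s of EMG are below
#' the high threshold and at least two of the last three ratio values are
#' above the high threshold; to REMS when all 5 s of EMG are below the
#' low threshold and all five ratio values are above the high threshold.
#' Out of NREMS: to Wake when the last second of EMG is above the high
#' threshold; to REMS when the last 5 s of EMG are below the low
#' threshold, at least four of five ratio values are below the low
#' threshold and all five below the high threshold. Out of REMS: to Wake
#' when the last second of EMG is above the high threshold; to NREMS when
#' the ratio is above the high threshold for at least four of five
#' seconds.
#'
#' @param state current state, one of `"Wake"`, `"NREMS"`, `"REMS"`.
#' @param ratio5,emg5 numeric length-5 histories.
#' @param thr thresholds from [calibrate_online_thresholds()].
#' @return next state label.
#' @export
online_state_step <- function(state, ratio5, emg5, thr) {
  if (is.null(thr$emg_high) || is.null(thr$ratio_high))
    stop("unconfigured thresholds")
  r <- ratio5; e <- emg5
  if (state == "Wake") {
    if (all(e[3:5] < thr$emg_high) && sum(r[3:5] > thr$ratio_high) >= 2)
      return("NREMS")
    if (all(e < thr$emg_low) && all(r > thr$ratio_high)) return("REMS")
  } else if (state == "NREMS") {
    if (e[5] > thr$emg_high) return("Wake")
    if (all(e < thr$emg_low) && sum(r < thr$ratio_low) >= 4 &&
        all(r < thr$ratio_high)) return("REMS")
  } else if (state == "REMS") {
    if (e[5] > thr$emg_high) return("Wake")
    if (sum(r > thr$ratio_high) >= 4) return("NREMS")
  } else stop("unknown state ", state)
  state
}

#' Run the state machine over a whole recording
#'
#' Equivalent to iterating [online_state_step()] second by second; there
#' is no hidden state beyond the five-second feature buffers.
#'
#' @param feats [online_features()] output.
#' @param thr thresholds.
#' @param init initial state.
#' @return character vector of per-second likely states, aligned with
#'   `feats$second`.
#' @export
online_state_machine <- function(feats, thr, init = "Wake") {
  n <- nrow(feats)
  lab <- character(n)
  state <- init
  for (i in seq_len(n)) {
    if (i >= 5) {
      state <- online_state_step(state, feats$ratio[(i - 4):i],
                                 feats$emg[(i - 4):i], thr)
    }
    lab[i] <- state
  }
  lab
}

# Orthonormal basis for degree-9 polynomial fitting on a fixed 200-point
# grid; cached per session.
poly_basis_200 <- local({
  cache <- NULL
  function(n = 200, degree = 9) {
    if (is.null(cache)) {
      b <- cbind(1, stats::poly(seq_len(n), degree))
      cache <<- qr.Q(qr(b))
    }
    cache
  }
})

#' Online sigma-curve estimate
#'
#' Least-squares degree-9 polynomial fit to the last 200 s of normalized
#' sigma power (1 Hz), the online approximation of the 0.02 Hz
#' fluctuation. A constant buffer returns a flat curve.
#'
#' @param sigma_buffer numeric vector; the last 200 values are used.
#' @param degree polynomial degree.
#' @return fitted curve (length 200).
#' @export
online_sigma_estimate <- function(sigma_buffer, degree = 9) {
  n <- length(sigma_buffer)
  if (n < 200) stop("need at least 200 s of buffered sigma power")
  y <- sigma_buffer[(n - 199):n]
  if (stats::sd(y) == 0) return(rep(y[1], 200))
  Q <- poly_basis_200(200, degree)
  as.numeric(Q %*% crossprod(Q, y))
}

#' Build the labelled training set for the period classifier
#'
#' Emulates the online pipeline over a recording: per-second sigma power
#' normalized by the running NREMS mean (updated only in likely-NREMS
#' seconds), a 200 s rolling buffer fitted with the degree-9 polynomial,
#' and the label of the final second taken from offline cycle detection
#' (continuity = trough to peak, fragility = peak to trough, `none`
#' outside detected cycles). Each feature vector is the 200-point fitted
#' curve plus the current delta/theta ratio and EMG power.
#'
#' @param feats [online_features()] output.
#' @param online_states per-second likely states
#'   ([online_state_machine()]).
#' @param cs offline [detect_cycles()] result for the same recording.
#' @param st the offline `sigma_trace` (time alignment).
#' @return list with `x` (chunks x 202 matrix), `y` (factor
#'   continuity/fragility/none), `second`.
#' @export
make_training_set <- function(feats, online_states, cs, st) {
  n <- nrow(feats)
  if (length(online_states) != n) stop("misaligned online state labels")
  # per-second normalized sigma with running NREMS mean
  norm_sigma <- numeric(n)
  run_mean <- NA_real_
  run_n <- 0
  for (i in seq_len(n)) {
    if (online_states[i] == "NREMS") {
      run_n <- run_n + 1
      run_mean <- if (run_n == 1) feats$sigma[i] else
        run_mean + (feats$sigma[i] - run_mean) / run_n
    }
    norm_sigma[i] <- feats$sigma[i] / if (is.na(run_mean) || run_mean <= 0)
      mean(feats$sigma[seq_len(i)]) else run_mean
  }
  # per-second offline labels
  lab <- rep("none", n)
  for (i in seq_len(nrow(cs))) {
    sec <- feats$second
    lab[sec >= cs$start_s[i] & sec < cs$trough_s[i]] <- "fragility"
    lab[sec >= cs$trough_s[i] & sec < cs$end_s[i]] <- "continuity"
  }
  usable <- which(seq_len(n) >= 200)
  Q <- poly_basis_200()
  x <- matrix(NA_real_, length(usable), 202)
  for (k in seq_along(usable)) {
    i <- usable[k]
    y <- norm_sigma[(i - 199):i]
    fit <- if (stats::sd(y) == 0) rep(y[1], 200) else
      as.numeric(Q %*% crossprod(Q, y))
    x[k, ] <- c(fit, feats$ratio[i], feats$emg[i])
  }
  list(x = x, y = factor(lab[usable],
                         levels = c("continuity", "fragility", "none")),
       second = feats$second[usable])
}

#' Train the continuity/fragility period classifier
#'
#' Feed-forward network with one hidden layer of 10 units and a 3-class
#' softmax output, trained on a 70/15/15 train/validation/test split
#' under a fixed seed. Features are standardized with the training-set
#' statistics.
#'
#' @param ts training set from [make_training_set()] (or a list with
#'   `x`, `y`).
#' @param seed integer split/initialization seed.
#' @param size hidden units.
#' @param maxit optimizer iterations.
#' @return object of class `period_classifier` with the fitted net,
#'   scaling, split indices, held-out `confusion` matrix and `accuracy`.
#' @export
train_period_classifier <- function(ts, seed = 1, size = 10, maxit = 200) {
  y <- droplevels(ts$y)
  if (nlevels(y) < 3)
    stop("all three labels (continuity, fragility, none) must be present")
  set.seed(seed)
  n <- nrow(ts$x)
  idx <- sample.int(n)
  n_tr <- floor(0.70 * n); n_va <- floor(0.15 * n)
  split <- list(train = idx[seq_len(n_tr)],
                valid = idx[n_tr + seq_len(n_va)],
                test = idx[(n_tr + n_va + 1):n])
  ctr <- colMeans(ts$x[split$train, , drop = FALSE])
  scl <- apply(ts$x[split$train, , drop = FALSE], 2, stats::sd)
  scl[scl == 0] <- 1
  xs <- sweep(sweep(ts$x, 2, ctr), 2, scl, "/")
  net <- nnet::nnet(xs[split$train, ], nnet::class.ind(y[split$train]),
                    size = size, softmax = TRUE, maxit = maxit,
                    MaxNWts = 10000, trace = FALSE)
  pred_lab <- function(rows) {
    p <- stats::predict(net, xs[rows, , drop = FALSE])
    factor(levels(y)[max.col(p)], levels = levels(y))
  }
  test_pred <- pred_lab(split$test)
  confusion <- table(truth = y[split$test], predicted = test_pred)
  structure(list(net = net, center = ctr, scale = scl, levels = levels(y),
                 split = split,
                 confusion = confusion,
                 accuracy = mean(test_pred == y[split$test]),
                 valid_accuracy = mean(pred_lab(split$valid) ==
                                         y[split$valid])),
            class = "period_classifier")
}

#' @export
print.period_classifier <- function(x, ...) {
  cat("<period_classifier> 10-unit single-hidden-layer network\n",
      "held-out accuracy: ", round(x$accuracy, 3), "\n", sep = "")
  print(x$confusion)
  invisible(x)
}

#' @param object a `period_classifier`.
#' @param newx feature matrix as produced by [make_training_set()].
#' @param ... unused.
#' @return factor of predicted period labels.
#' @rdname train_period_classifier
#' @export
predict.period_classifier <- function(object, newx, ...) {
  xs <- sweep(sweep(newx, 2, object$center), 2, object$scale, "/")
  p <- stats::predict(object$net, xs)
  factor(object$levels[max.col(p)], levels = object$levels)
}

#' End-to-end online period detection over a session
#'
#' Convenience wrapper running the full online path on one recording:
#' per-second features, threshold calibration, the vigilance-state
#' machine, the offline sigma trace and cycle detection (for labels),
#' training-chunk construction, classifier training (unless one is
#' supplied) and per-second period calls. Seconds whose likely state is
#' not NREMS are called `none`.
#'
#' @param rec a `psg_recording`.
#' @param hyp matching [hypnogram()].
#' @param clf optional pre-trained [train_period_classifier()].
#' @param thr optional thresholds; calibrated from `hyp` when `NULL`.
#' @param seed training seed.
#' @param maxit optimizer iterations for training.
#' @return list with `clf`, `thr`, `table` (second, state, offline label,
#'   period call), `st`, `cs`, `feats`.
#' @export
online_period_detection <- function(rec, hyp, clf = NULL, thr = NULL,
                                    seed = 1, maxit = 150) {
  feats <- online_features(rec)
  if (is.null(thr)) thr <- calibrate_online_thresholds(feats, hyp)
  states <- online_state_machine(feats, thr)
  st <- compute_sigma_trace(rec, hyp)
  cs <- detect_cycles(st, hyp)
  ts <- make_training_set(feats, states, cs, st)
  if (is.null(clf)) clf <- train_period_classifier(ts, seed = seed,
                                                   maxit = maxit)
  pred <- as.character(predict(clf, ts$x))
  st_at <- states[match(ts$second, feats$second)]
  pred[st_at != "NREMS"] <- "none"
  list(clf = clf, thr = thr,
       table = data.frame(second = ts$second, state = st_at,
                          offline = as.character(ts$y), period = pred,
                          stringsAsFactors = FALSE),
       st = st, cs = cs, feats = feats)
}

#' Shuffle validation of online period detection
#'
#' Proportion of scored microarousals whose onset second falls in
#' online-detected fragility (and continuity) seconds, compared with a
#' null distribution obtained by repositioning the detected points
#' uniformly at random within the recording's NREMS seconds (preserving
#' their number). Reports the percentile of the observed proportion in
#' the null.
#'
#' @param period_labels per-second factor/character of online period
#'   calls (`continuity`/`fragility`/`none`).
#' @param seconds the second stamps aligned with `period_labels`.
#' @param ma_onsets_s scored MA onset times, seconds.
#' @param nrems_seconds integer seconds scored NREMS (shuffle support).
#' @param n_shuffles number of shuffles.
#' @param seed RNG seed.
#' @return list with `proportions` (fragility, continuity, neither; sums
#'   to 1), `percentile` (fragility, continuity) and the null matrices.
#' @export
validate_online_detection <- function(period_labels, seconds, ma_onsets_s,
                                      nrems_seconds, n_shuffles = 1000,
                                      seed = 1) {
  if (!length(ma_onsets_s)) stop("no microarousals to validate against")
  ma_sec <- floor(ma_onsets_s)
  lab <- as.character(period_labels)
  sec_of <- function(which_lab) seconds[lab == which_lab]
  frag <- sec_of("fragility"); cont <- sec_of("continuity")
  prop <- c(fragility = mean(ma_sec %in% frag),
            continuity = mean(ma_sec %in% cont))
  prop["neither"] <- 1 - sum(prop)

  set.seed(seed)
  null <- matrix(NA_real_, n_shuffles, 2,
                 dimnames = list(NULL, c("fragility", "continuity")))
  for (b in seq_len(n_shuffles)) {
    sf <- sample(nrems_seconds, length(frag),
                 replace = length(frag) > length(nrems_seconds))
    sc <- sample(nrems_seconds, length(cont),
                 replace = length(cont) > length(nrems_seconds))
    null[b, 1] <- mean(ma_sec %in% sf)
    null[b, 2] <- mean(ma_sec %in% sc)
  }
  pct <- c(fragility = 100 * mean(null[, 1] < prop["fragility"]),
           continuity = 100 * mean(null[, 2] < prop["continuity"]))
  list(proportions = prop, percentile = pct, null = null)
}
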