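#' Simulate a mouse hypnogram with ground truth
#'
#' Draws a semi-Markov sequence of vigilance-state bouts
#' (Wake -> NREMS -> \{Wake | REMS\} -> ...) with bout durations chosen so
#' that NREMS bouts carry several uninterrupted infraslow cycles, quantizes
#' it to scoring epochs, and lays the true infraslow phase over the
#' recording. The true phase advances continuously at 360/T degrees per
#' second with 0 deg at the sigma-power envelope maximum (so the trough is
#' at 180 deg, matching the analysis convention).
#'
#' @param cfg a [sim_config()].
#' @param seed integer seed; `NULL` leaves the RNG stream untouched
#'   (used when called from [simulate_recording()]).
#' @return list with `hypnogram` (a [hypnogram()], without microarousals
#'   yet) and `truth` (class `sim_truth`): bout table, true phase at the
#'   sigma-trace rate, and the candidate infraslow cycle table (complete
#'   peak-to-peak cycles lying inside NREMS bouts).
#' @export
simulate_hypnogram <- function(cfg, seed = cfg$seed) {
  if (!is.null(seed)) set.seed(seed)
  es <- cfg$epoch_s
  total_ep <- floor(cfg$duration_s / es)
  if (total_ep < 1) stop("duration too short for a single epoch")

  draw_ep <- function(meanlog, sdlog, lo, hi) {
    d <- min(max(stats::rlnorm(1, meanlog, sdlog), lo), hi)
    max(1L, round(d / es))
  }

  if (cfg$nrems_only) {
    states <- rep("NREMS", total_ep)
  } else {
    states <- character(0)
    cur <- "Wake"
    first <- TRUE
    while (length(states) < total_ep) {
      n_ep <- switch(cur,
        Wake  = if (first) draw_ep(log(120), 0.3, 60, 300)
                else draw_ep(log(150), 0.5, 40, 600),
        NREMS = draw_ep(log(480), 0.35, 200, 1200),
        REMS  = draw_ep(log(80), 0.3, 40, 160))
      states <- c(states, rep(cur, n_ep))
      nxt <- switch(cur,
        Wake  = "NREMS",
        NREMS = if (stats::runif(1) < 0.35) "REMS" else "Wake",
        REMS  = if (stats::runif(1) < 0.8) "Wake" else "NREMS")
      cur <- nxt
      first <- FALSE
    }
    states <- states[seq_len(total_ep)]
  }
  hyp <- hypnogram(states, epoch_s = es)

  Tis <- cfg$infraslow_period_s
  n10 <- floor(hyp_duration_s(hyp) * cfg$fs_sigma)
  t10 <- (seq_len(n10) - 1) / cfg$fs_sigma
  phase10 <- wrap360(360 * t10 / Tis)

  bouts <- hyp_bouts(hyp)
  nb <- bouts[bouts$state == "NREMS", , drop = FALSE]
  cyc <- list()
  for (i in seq_len(nrow(nb))) {
    b0 <- nb$start_s[i]; b1 <- nb$start_s[i] + nb$duration_s[i]
    ks <- seq(ceiling(b0 / Tis), floor(b1 / Tis) - 1)
    if (length(ks) == 0 || ks[1] > ks[length(ks)]) next
    cyc[[length(cyc) + 1L]] <- data.frame(
      start_s = ks * Tis, end_s = (ks + 1) * Tis,
      frag_start_s = ks * Tis + Tis / 4,
      frag_end_s = ks * Tis + 3 * Tis / 4)
  }
  cycles <- if (length(cyc)) do.call(rbind, cyc) else
    data.frame(start_s = numeric(0), end_s = numeric(0),
               frag_start_s = numeric(0), frag_end_s = numeric(0))
  cycles$has_ma <- FALSE
  cycles$ai_event <- FALSE

  truth <- list(
    cfg = cfg,
    bouts = bouts,
    phase_deg = phase10,
    fs_phase = cfg$fs_sigma,
    cycles = cycles,
    ma = data.frame(onset_s = numeric(0), duration_s = numeric(0),
                    true_phase_deg = numeric(0)),
    ai_events = data.frame(onset_s = numeric(0), duration_s = numeric(0)),
    rpeaks_s = numeric(0)
  )
  class(truth) <- "sim_truth"
  list(hypnogram = hyp, truth = truth)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("<sim_truth> ", nrow(x$bouts), " bouts, ", nrow(x$cycles),
      " infraslow cycles, ", nrow(x$ma), " MAs, ",
      nrow(x$ai_events), " AI-peak events, ",
      length(x$rpeaks_s), " R peaks\n", sep = "")
  invisible(x)
}

# True phase (degrees) at arbitrary times.
truth_phase_at <- function(truth, t_s) {
  wrap360(360 * t_s / truth$cfg$infraslow_period_s)
}
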