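#' Place phase-locked microarousals into a simulated hypnogram
#'
#' For each complete infraslow cycle lying inside a NREMS bout, a
#' microarousal is placed with per-cycle probability
#' `p_ma_per_fragility / P_vM(90-270 deg)`, so that the expected
#' proportion of fragility periods containing an in-window MA equals
#' `p_ma_per_fragility` while MA onset phases keep the configured von
#' Mises distribution (mean 151.6 deg, 89\% of mass between 90 and 270
#' deg). The onset phase is drawn von Mises(mu, kappa), mapped to time
#' within the cycle; the duration is uniform on 4-16 s; epochs covered by
#' the MA (at most four) are relabelled `MA`.
#'
#' @param hyp hypnogram from [simulate_hypnogram()].
#' @param truth matching `sim_truth`.
#' @param cfg the [sim_config()].
#' @param seed integer or `NULL`.
#' @return list with the relabelled `hypnogram`, updated `truth`, and
#'   `events`: a data frame (onset_s, duration_s, type, channel,
#'   true_phase_deg).
#' @export
place_microarousals <- function(hyp, truth, cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cyc <- truth$cycles
  es <- epoch_s_of(hyp)
  n_ep <- nrow(hyp)
  states <- hyp$state
  Tis <- cfg$infraslow_period_s

  in_range <- vonmises_arc_mass(90, 270, cfg$ma_phase_mu_deg,
                                cfg$ma_phase_kappa)
  p_place <- min(1, cfg$p_ma_per_fragility / in_range)

  ma <- list()
  if (nrow(cyc)) {
    u <- stats::runif(nrow(cyc))
    place <- u < p_place
    phis <- rvonmises_deg(nrow(cyc), cfg$ma_phase_mu_deg,
                          cfg$ma_phase_kappa)
    durs <- stats::runif(nrow(cyc), 4, 16)
    for (i in which(place)) {
      onset <- cyc$start_s[i] + phis[i] / 360 * Tis
      dur <- durs[i]
      e1 <- floor(onset / es) + 1L
      e2 <- min(floor((onset + dur - 1e-9) / es) + 1L, e1 + 3L, n_ep)
      if (e1 > n_ep) next
      ok <- states[e1:e2] %in% c("NREMS", "MA")
      if (!ok[1]) next
      if (!all(ok)) e2 <- e1 + sum(cumprod(ok)) - 1L  # clip at bout edge
      states[e1:e2] <- "MA"
      cyc$has_ma[i] <- TRUE
      ma[[length(ma) + 1L]] <- data.frame(
        onset_s = onset, duration_s = dur, true_phase_deg = phis[i])
    }
  }
  ma <- if (length(ma)) do.call(rbind, ma) else
    data.frame(onset_s = numeric(0), duration_s = numeric(0),
               true_phase_deg = numeric(0))
  truth$cycles <- cyc
  truth$ma <- ma

  events <- data.frame(
    onset_s = ma$onset_s, duration_s = ma$duration_s,
    type = rep("MA", nrow(ma)), channel = rep("emg", nrow(ma)),
    true_phase_deg = ma$true_phase_deg, stringsAsFactors = FALSE)

  list(hypnogram = hypnogram(states, epoch_s = es, zt0 = attr(hyp, "zt0")),
       truth = truth, events = events)
}
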