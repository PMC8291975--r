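#' Configuration for the synthetic polysomnography generator
#'
#' Builds a validated configuration for [simulate_recording()] and friends.
#' Defaults encode the study conditions the analysis stack is calibrated
#' against: a ~50 s (0.02 Hz) infraslow modulation of NREMS sigma power,
#' microarousal onsets phase-locked at a preferred phase of 151.6 deg with
#' 89% of onsets falling in the 90-270 deg fragility window, and one third
#' (33.6%) of fragility periods containing a microarousal.
#'
#' @param ... named overrides of the fields below. Unknown names and
#'   invariant violations raise errors.
#'
#' @section Fields:
#' \describe{
#'   \item{duration_s}{session length, seconds (default 3600; full 12 h
#'     sessions by override).}
#'   \item{fs_signal}{signal sampling rate, Hz (default 1000).}
#'   \item{fs_sigma}{sigma-trace rate, Hz (10).}
#'   \item{epoch_s}{scoring epoch, seconds (4).}
#'   \item{infraslow_period_s}{infraslow period T, seconds (50; must be
#'     > 40 so the cycle-detection separation rule is satisfiable).}
#'   \item{modulation_depth}{depth d of the sigma *power* modulation
#'     1 + d cos(phase), in `[0, 1]` (default 0.9).}
#'   \item{ma_phase_mu_deg}{preferred microarousal onset phase (151.6).}
#'   \item{ma_phase_kappa}{von Mises concentration of onset phases;
#'     `NULL` (default) solves for the value putting 89% of the mass on
#'     90-270 deg, i.e. kappa = 2.015.}
#'   \item{p_ma_per_fragility}{target proportion of fragility periods
#'     containing an in-window microarousal (0.336). The per-cycle
#'     placement probability is this divided by the von Mises mass on
#'     90-270 deg, so that both the 89% clustering and the 33.6%
#'     fragility-MA proportion hold jointly.}
#'   \item{condition}{`"sham"` or `"sni"` (spared nerve injury).}
#'   \item{sni_hf_gain}{tonic multiplier on NREMS beta/low-gamma power in
#'     the SNI condition (default 2).}
#'   \item{delta_surge_gain}{fractional delta-power surge during fragility
#'     periods in NREMS (default 0.5).}
#'   \item{delta_continuity_dip}{fractional delta-power dip during
#'     continuity periods (default 0.35): delta runs anti-phase to sigma
#'     across the cycle, as in sensory cortex.}
#'   \item{sni_delta_surge_gain}{multiplier applied to the surge under SNI
#'     (default 0.2, i.e. the surge is blunted).}
#'   \item{p_ai_peak_fragility}{probability that a NREMS-continuing cycle
#'     carries a local-arousal (AI-peak) event; default 0.15 for sham,
#'     0.35 for SNI.}
#'   \item{hr_nrems_hz, hr_rems_hz, hr_wake_hz}{heart rate per state,
#'     beats/s (defaults 10, 11, 12.5).}
#'   \item{hr_ai_transient_hz}{heart-rate increment during an AI-peak
#'     event, beats/s (default 2).}
#'   \item{p_wakeup_continuity, p_wakeup_fragility}{probability that a
#'     vibration delivered in a true continuity / fragility period wakes
#'     the animal; defaults 0.25/0.55 (sham) and 0.40/0.75 (SNI).}
#'   \item{nrems_only}{if `TRUE` the hypnogram is a single NREMS bout.}
#'   \item{seed}{integer seed recorded in the config (default 1).}
#' }
#' @return list of class `sim_config`.
#' @examples
#' cfg <- sim_config()
#' cfg$infraslow_period_s
#' @export
sim_config <- function(...) {
  cfg <- list(
    duration_s = 3600,
    fs_signal = 1000,
    fs_sigma = 10,
    epoch_s = 4,
    infraslow_period_s = 50,
    modulation_depth = 0.9,
    ma_phase_mu_deg = 151.6,
    ma_phase_kappa = NULL,
    p_ma_per_fragility = 0.336,
    condition = "sham",
    sni_hf_gain = 2,
    delta_surge_gain = 0.5,
    delta_continuity_dip = 0.35,
    sni_delta_surge_gain = 0.2,
    p_ai_peak_fragility = NULL,
    hr_nrems_hz = 10,
    hr_rems_hz = 11,
    hr_wake_hz = 12.5,
    hr_ai_transient_hz = 2,
    p_wakeup_continuity = NULL,
    p_wakeup_fragility = NULL,
    nrems_only = FALSE,
    seed = 1L
  )
  ov <- list(...)
  if (length(ov) == 1L && is.list(ov[[1]]) && is.null(names(ov))) ov <- ov[[1]]
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown)) stop("unknown sim_config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(ov)] <- ov

  cfg$condition <- match.arg(cfg$condition, c("sham", "sni"))
  sni <- cfg$condition == "sni"
  if (is.null(cfg$p_ai_peak_fragility))
    cfg$p_ai_peak_fragility <- if (sni) 0.35 else 0.15
  if (is.null(cfg$p_wakeup_continuity))
    cfg$p_wakeup_continuity <- if (sni) 0.40 else 0.25
  if (is.null(cfg$p_wakeup_fragility))
    cfg$p_wakeup_fragility <- if (sni) 0.75 else 0.55
  if (is.null(cfg$ma_phase_kappa))
    cfg$ma_phase_kappa <- solve_kappa_for_mass(0.89, 90, 270,
                                               cfg$ma_phase_mu_deg)

  probs <- c("p_ma_per_fragility", "p_ai_peak_fragility",
             "p_wakeup_continuity", "p_wakeup_fragility",
             "modulation_depth")
  for (p in probs) {
    v <- cfg[[p]]
    if (!is.numeric(v) || v < 0 || v > 1)
      stop(p, " must lie in [0, 1], got ", v)
  }
  if (cfg$infraslow_period_s <= 40)
    stop("infraslow_period_s must exceed 40 s (cycle-detection separation rule)")
  if (cfg$fs_signal < 2 * 500)
    stop("fs_signal must be at least 1000 Hz (twice the 500 Hz EMG band edge)")
  if (cfg$duration_s < 3 * cfg$infraslow_period_s)
    stop("duration_s too short: need at least 3 infraslow periods")
  if (cfg$ma_phase_kappa < 0) stop("ma_phase_kappa must be >= 0")
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", x$duration_s, " s @ ", x$fs_signal, " Hz, condition = ",
      x$condition, "\n  infraslow T = ", x$infraslow_period_s,
      " s, modulation depth = ", x$modulation_depth,
      "\n  MA phase: mu = ", x$ma_phase_mu_deg, " deg, kappa = ",
      round(x$ma_phase_kappa, 3),
      ", p(MA | fragility) = ", x$p_ma_per_fragility, "\n", sep = "")
  invisible(x)
}
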