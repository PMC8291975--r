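# Shared simulated sessions, built lazily and cached for the whole suite.

.session_cache <- new.env(parent = emptyenv())

cached_session <- function(key, ...) {
  if (is.null(.session_cache[[key]])) {
    .session_cache[[key]] <- simulate_recording(sim_config(...))
  }
  .session_cache[[key]]
}

# Default desk-scale animal used by several files (full hour).
default_session <- function() cached_session("default", seed = 11)

# Shorter session for cheap structural tests.
short_session <- function() cached_session("short", seed = 5,
                                           duration_s = 900)

cached_sigma_trace <- function(key, ses) {
  k <- paste0("st_", key)
  if (is.null(.session_cache[[k]])) {
    .session_cache[[k]] <- compute_sigma_trace(ses$recording,
                                               ses$hypnogram)
  }
  .session_cache[[k]]
}

# A noise-free sigma_trace-like object carrying a pure 50 s power
# oscillation, plus an all-NREMS hypnogram; used as cycle/spectrum oracle
# input without running the signal pipeline.
synthetic_sigma_trace <- function(duration_s = 1200, period_s = 50,
                                  depth = 0.9, fs = 10) {
  t <- (seq_len(duration_s * fs) - 1) / fs
  p <- 1 + depth * cos(2 * pi * t / period_s)
  structure(list(t = t, fs = fs, power = p, smooth = p,
                 phase_deg = compute_phase(p),
                 mask = rep(TRUE, length(t))),
            class = "sigma_trace")
}

all_nrems_hypnogram <- function(duration_s = 1200, epoch_s = 4) {
  hypnogram(rep("NREMS", duration_s / epoch_s), epoch_s = epoch_s)
}
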