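#' Standard EEG/EMG frequency-band definitions
#'
#' Returns the band edges (Hz) used throughout the package: delta 1-4,
#' theta 5-10, sigma (spindle) 10-15, beta 16-25, low gamma 26-40, high
#' gamma 60-80, and the high-frequency EMG band 100-500. Individual bands
#' can be overridden.
#'
#' @param ... named overrides, each a numeric `c(lo, hi)` in Hz.
#' @return named list of numeric length-2 vectors.
#' @examples
#' band_definitions()$sigma
#' band_definitions(sigma = c(9, 16))$sigma
#' @export
band_definitions <- function(...) {
  bands <- list(
    delta      = c(1, 4),
    theta      = c(5, 10),
    sigma      = c(10, 15),
    beta       = c(16, 25),
    low_gamma  = c(26, 40),
    high_gamma = c(60, 80),
    emg_high   = c(100, 500)
  )
  ov <- list(...)
  for (nm in names(ov)) {
    b <- ov[[nm]]
    if (!is.numeric(b) || length(b) != 2 || b[1] >= b[2])
      stop("band '", nm, "' must be c(lo, hi) with lo < hi")
    bands[[nm]] <- b
  }
  bands
}

# Frequency-bin selector for a band on a frequency axis (inclusive edges).
band_bins <- function(freq, band) which(freq >= band[1] & freq <= band[2])
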