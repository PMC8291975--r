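# Circular statistics for event-phase analyses.

#' Circular mean with confidence interval
#'
#' Computes the circular (resultant-vector) mean of a sample of angles,
#' the mean resultant length \eqn{\bar R}, and the dispersion-based
#' confidence half-width of the mean direction (the standard chi-square
#' construction used in circular-statistics toolboxes).
#'
#' @param angles_deg numeric vector of angles in degrees; wrapped to
#'   `[0, 360)` internally.
#' @param confidence confidence level for the interval (default 0.95).
#' @return list with `mean_deg`, `ci_halfwidth_deg` (NA when the sample is
#'   too dispersed for the interval to exist), `R_bar` and `n`.
#' @examples
#' circ_mean_ci(c(150, 152, 154))
#' @export
circ_mean_ci <- function(angles_deg, confidence = 0.95) {
  th <- deg2rad(wrap360(angles_deg))
  n <- length(th)
  if (n < 1) stop("need at least one angle")
  C <- sum(cos(th)); S <- sum(sin(th))
  R <- sqrt(C^2 + S^2)
  r <- R / n
  mu <- wrap360(rad2deg(atan2(S, C)))
  ci <- NA_real_
  if (n >= 2 && r > 0) {
    c2 <- stats::qchisq(confidence, df = 1)
    t <- if (r < 0.9 && r > sqrt(c2 / (2 * n))) {
      sqrt((2 * n * (2 * R^2 - n * c2)) / (4 * n - c2))
    } else if (r >= 0.9) {
      sqrt(n^2 - (n^2 - R^2) * exp(c2 / n))
    } else NA_real_
    if (is.finite(t) && t <= R) ci <- rad2deg(acos(t / R))
  }
  list(mean_deg = mu, ci_halfwidth_deg = ci, R_bar = r, n = n)
}

#' Rayleigh test of circular uniformity
#'
#' Tests the null hypothesis that angles are uniformly distributed on the
#' circle against a unimodal alternative. The statistic is
#' \eqn{z = n \bar R^2}; the p value uses the standard large-sample series
#' approximation.
#'
#' @param angles_deg numeric vector of angles in degrees.
#' @return list with `z`, `p_value`, `R_bar` and `n`.
#' @export
rayleigh_test <- function(angles_deg) {
  th <- deg2rad(wrap360(angles_deg))
  n <- length(th)
  if (n < 10) warning("Rayleigh test with n < 10 is unreliable")
  r <- sqrt(sum(cos(th))^2 + sum(sin(th))^2) / n
  R <- n * r
  z <- n * r^2
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - R^2)) - (1 + 2 * n))
  list(z = z, p_value = min(1, p), R_bar = r, n = n)
}

#' von Mises random angles
#'
#' Best-Fisher (1979) rejection sampler; degrees in, degrees out. With
#' `kappa = Inf` all draws equal `mu_deg`; with `kappa = 0` the draws are
#' uniform.
#'
#' @param n number of draws.
#' @param mu_deg mean direction, degrees.
#' @param kappa concentration parameter (>= 0).
#' @return numeric vector of angles in `[0, 360)`.
#' @export
rvonmises_deg <- function(n, mu_deg, kappa) {
  if (kappa < 0) stop("kappa must be >= 0")
  if (is.infinite(kappa)) return(rep(wrap360(mu_deg), n))
  if (kappa == 0) return(stats::runif(n, 0, 360))
  mu <- deg2rad(mu_deg)
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r0 <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u <- stats::runif(3)
      z <- cos(pi * u[1])
      f <- (1 + r0 * z) / (r0 + z)
      c0 <- kappa * (r0 - f)
      if (c0 * (2 - c0) - u[2] > 0 || log(c0 / u[2]) + 1 - c0 >= 0) {
        out[i] <- mu + sign(u[3] - 0.5) * acos(f)
        break
      }
    }
  }
  wrap360(rad2deg(out))
}

# Probability mass of vonMises(mu, kappa) on the arc [lo, hi] (degrees).
vonmises_arc_mass <- function(lo_deg, hi_deg, mu_deg, kappa) {
  if (is.infinite(kappa) || kappa > 300) {
    # degenerate: all mass at mu (besselI overflows long before this)
    mu <- wrap360(mu_deg)
    return(as.numeric(mu >= lo_deg & mu <= hi_deg))
  }
  dens <- function(th) exp(kappa * cos(th - deg2rad(mu_deg))) /
    (2 * pi * besselI(kappa, 0))
  stats::integrate(dens, deg2rad(lo_deg), deg2rad(hi_deg))$value
}

# Solve for kappa giving a target arc mass; used for the generator default.
solve_kappa_for_mass <- function(target, lo_deg = 90, hi_deg = 270,
                                 mu_deg = 151.6) {
  stats::uniroot(function(k) vonmises_arc_mass(lo_deg, hi_deg, mu_deg, k) -
                   target, c(1e-3, 50))$root
}
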