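#' Drift schedule for the phase-response-curve offset
#'
#' Generates the per-step PRC offset delta_theta_k that drives the
#' non-stationarity of the objective:
#' \describe{
#'   \item{none}{all offsets 0 (stationary objective).}
#'   \item{gradual}{linear ramp from 0 to -amplitude over the run,
#'     emulating disease progression.}
#'   \item{periodic}{raised-cosine swing 0 -> -amplitude -> 0 every
#'     `period_steps`, emulating a circadian/medication cycle.}
#'   \item{superimposed}{elementwise sum of the two.}
#' }
#' Optional Gaussian jitter of std `noise_std` is added per step (seeded),
#' for robustness scenarios with a noisy optimum trajectory.
#'
#' @param kind one of `"none"`, `"gradual"`, `"periodic"`, `"superimposed"`.
#' @param n_steps number of optimization steps.
#' @param period_steps period of the periodic component, in steps.
#' @param amplitude peak offset magnitude in radians (default pi).
#' @param noise_std std of per-step Gaussian jitter in radians.
#' @param seed seed for the jitter draws.
#' @return an object of class `drift_schedule` with the derived `offsets`
#'   sequence (length `n_steps`).
#' @examples
#' d <- make_drift("periodic", n_steps = 200, period_steps = 100)
#' range(d$offsets)
#' @export
make_drift <- function(kind = c("none", "gradual", "periodic", "superimposed"),
                       n_steps = 3000, period_steps = 100, amplitude = pi,
                       noise_std = 0, seed = 1) {
  kind <- match.arg(kind)
  check_scalar(n_steps, "n_steps", lower = 1)
  check_scalar(period_steps, "period_steps", lower = 1)
  check_scalar(amplitude, "amplitude")
  check_scalar(noise_std, "noise_std", lower = 0)
  n_steps <- as.integer(n_steps)
  k <- seq_len(n_steps) - 1L   # steps counted from 0
  gradual <- if (n_steps > 1L) -amplitude * k / (n_steps - 1L) else 0 * k
  periodic <- -amplitude * sin(pi * k / period_steps)^2
  offsets <- switch(kind,
    none = 0 * k,
    gradual = gradual,
    periodic = periodic,
    superimposed = gradual + periodic)
  if (noise_std > 0) {
    set.seed(seed)
    offsets <- offsets + stats::rnorm(n_steps, 0, noise_std)
  }
  structure(list(kind = kind, n_steps = n_steps, period_steps = period_steps,
                 amplitude = amplitude, noise_std = noise_std, seed = seed,
                 offsets = offsets),
            class = "drift_schedule")
}

#' @export
print.drift_schedule <- function(x, ...) {
  cat(sprintf("Drift schedule: %s, %d steps", x$kind, x$n_steps))
  if (x$kind %in% c("periodic", "superimposed"))
    cat(sprintf(", period %g steps", x$period_steps))
  cat(sprintf(", amplitude %g rad", x$amplitude))
  if (x$noise_std > 0) cat(sprintf(", jitter sd %g rad", x$noise_std))
  cat("\n")
  invisible(x)
}

#' True optimal stimulation phase under a PRC offset
#'
#' Adding an offset delta_theta to the phase response curve translates the
#' amplitude response curve, so the optimum shifts from its baseline
#' location: psi*_k = wrap(psi*_0 - delta_theta_k). The baseline optimum
#' psi*_0 = -pi is the empirical ARC minimum of the unshifted model.
#'
#' @param prc_offset PRC offset(s) delta_theta in radians (vectorized).
#' @param psi_star0 baseline optimum (default -pi, the empirically
#'   identified ARC minimum at zero offset).
#' @return optimal phase(s) wrapped to \[-pi, pi) (the candidate-grid
#'   convention, under which the baseline optimum is represented as -pi).
#' @export
true_optimum <- function(prc_offset, psi_star0 = -pi) {
  (psi_star0 - prc_offset + pi) %% (2 * pi) - pi
}

#' Analytic toy objective with a drifting optimum
#'
#' Fast stand-in for the oscillator model in optimizer tests:
#' y = -A cos(x - psi*_k) + Gaussian noise, a periodic objective whose
#' global minimum -A tracks the drift schedule's true optimum psi*_k.
#'
#' @param drift a [make_drift()] schedule.
#' @param amplitude A, the objective amplitude.
#' @param noise_std_y observation noise std.
#' @param psi_star0 baseline optimum phase.
#' @param seed seed for the observation noise.
#' @return a function `(x, k) -> y` suitable for [run_bayesopt()].
#' @export
toy_objective <- function(drift, amplitude = 1, noise_std_y = 0,
                          psi_star0 = -pi, seed = 1) {
  force(drift); force(amplitude); force(noise_std_y)
  set.seed(seed)
  function(x, k) {
    opt <- true_optimum(drift$offsets[k], psi_star0)
    -amplitude * cos(x - opt) +
      if (noise_std_y > 0) stats::rnorm(1, 0, noise_std_y) else 0
  }
}
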