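#' Kuramoto population model parameters
#'
#' Parameters of the coupled phase-oscillator population used as the model of
#' a synchronous disease biomarker. Defaults are the reference parameter set:
#' 50 oscillators about 8 Hz (Essential-Tremor band), relative frequency
#' spread 0.0075, coupling 0.8, stimulation intensity 30.
#'
#' @param n_oscillators number of oscillators N.
#' @param f0 natural frequency of the population in Hz.
#' @param sigma spread of oscillator frequencies about `f0`. Interpreted as a
#'   fraction of `f0` when `sigma_mode = "relative"` (default; std in Hz is
#'   `sigma * f0`), or as an absolute std in Hz when `"absolute"`.
#' @param gamma coupling strength between oscillators.
#' @param intensity stimulation intensity I.
#' @param dt integration step in seconds (explicit Euler).
#' @param freq_clip maximum deviation of a drawn frequency from `f0`, in Hz;
#'   draws beyond it are redrawn. `NULL` disables clipping.
#' @param sigma_mode `"relative"` or `"absolute"`, see `sigma`.
#' @return an object of class `kuramoto_params`.
#' @examples
#' kuramoto_params()                 # reference parameter set
#' kuramoto_params(f0 = 23)          # beta-band variant
#' @export
kuramoto_params <- function(n_oscillators = 50L, f0 = 8, sigma = 0.0075,
                            gamma = 0.8, intensity = 30, dt = 1e-3,
                            freq_clip = 0.15,
                            sigma_mode = c("relative", "absolute")) {
  sigma_mode <- match.arg(sigma_mode)
  check_scalar(n_oscillators, "n_oscillators", lower = 1)
  check_scalar(f0, "f0", lower = 0, strict_lower = TRUE)
  check_scalar(sigma, "sigma", lower = 0)
  check_scalar(gamma, "gamma", lower = 0)
  check_scalar(intensity, "intensity", lower = 0)
  check_scalar(dt, "dt", lower = 0, strict_lower = TRUE)
  if (!is.null(freq_clip)) check_scalar(freq_clip, "freq_clip", lower = 0)
  structure(list(n_oscillators = as.integer(n_oscillators), f0 = f0,
                 sigma = sigma, gamma = gamma, intensity = intensity,
                 dt = dt, freq_clip = freq_clip, sigma_mode = sigma_mode),
            class = "kuramoto_params")
}

#' @export
print.kuramoto_params <- function(x, ...) {
  cat("Kuramoto population parameters\n")
  cat(sprintf("  N = %d oscillators, f0 = %g Hz (sigma = %g, %s",
              x$n_oscillators, x$f0, x$sigma, x$sigma_mode))
  if (!is.null(x$freq_clip)) cat(sprintf(", clip +/- %g Hz", x$freq_clip))
  cat(")\n")
  cat(sprintf("  coupling gamma = %g, stimulation intensity I = %g, dt = %g s\n",
              x$gamma, x$intensity, x$dt))
  invisible(x)
}

#' Phase response curve specification
#'
#' Type-II phase response curve Z(theta) = -sin(theta + offset). The offset
#' is the handle through which drift scenarios translate the amplitude
#' response curve over time.
#'
#' @param offset phase offset in radians (any real; interpreted mod 2*pi).
#' @return an object of class `prc_spec`.
#' @export
prc_spec <- function(offset = 0) {
  check_scalar(offset, "offset")
  structure(list(offset = offset), class = "prc_spec")
}

#' Stimulation trial protocol
#'
#' Timing of one optimization step: a settle period, a baseline averaging
#' window, then a trailing window of phase-locked stimulation. Defaults are
#' the full-scale protocol (58 s steps, last 8 s stimulated, 25 s baseline);
#' `scaled_protocol()` gives a shortened 12 s variant for fast closed-loop
#' experiments.
#'
#' @param step_duration_s total simulated time per optimization step (s).
#' @param stim_window_s trailing stimulation window (s).
#' @param baseline_window_s pre-stimulation averaging window (s).
#' @param pulse_width_s duration of each rectangular stimulation pulse (s).
#' @param refractory minimum fraction of a mean oscillation cycle between
#'   consecutive pulse onsets.
#' @return an object of class `stim_protocol`.
#' @export
stim_protocol <- function(step_duration_s = 58, stim_window_s = 8,
                          baseline_window_s = 25, pulse_width_s = 0.002,
                          refractory = 0.5) {
  check_scalar(step_duration_s, "step_duration_s", lower = 0, strict_lower = TRUE)
  check_scalar(stim_window_s, "stim_window_s", lower = 0, strict_lower = TRUE)
  check_scalar(baseline_window_s, "baseline_window_s", lower = 0,
               strict_lower = TRUE)
  check_scalar(pulse_width_s, "pulse_width_s", lower = 0, strict_lower = TRUE)
  check_scalar(refractory, "refractory", lower = 0)
  if (stim_window_s + baseline_window_s > step_duration_s)
    stop_tvbo("stim_window_s + baseline_window_s exceeds step_duration_s",
              "tvbo_invalid_parameter")
  structure(list(step_duration_s = step_duration_s,
                 stim_window_s = stim_window_s,
                 baseline_window_s = baseline_window_s,
                 pulse_width_s = pulse_width_s,
                 refractory = refractory),
            class = "stim_protocol")
}

#' @rdname stim_protocol
#' @export
scaled_protocol <- function() {
  stim_protocol(step_duration_s = 12, stim_window_s = 4, baseline_window_s = 5)
}

#' Initialize an oscillator population
#'
#' Phases are drawn i.i.d. uniform on \[0, 2*pi) and wrapped to (-pi, pi];
#' natural frequencies are Gaussian about `f0` with the spread given by the
#' parameter set, redrawn until within `f0 +/- freq_clip` when clipping is
#' enabled (redraw rather than clamping, to avoid probability mass at the
#' boundary).
#'
#' @param params a [kuramoto_params()] object.
#' @param seed integer seed for reproducible draws.
#' @return an object of class `population_state` with elements `phases`
#'   (radians, wrapped to (-pi, pi]), `omegas` (rad/s, fixed thereafter) and
#'   `time_s` (elapsed simulated time).
#' @export
init_population <- function(params, seed = NULL) {
  stopifnot(inherits(params, "kuramoto_params"))
  if (!is.null(seed)) set.seed(seed)
  n <- params$n_oscillators
  phases <- wrap_angle(stats::runif(n, 0, 2 * pi))
  sd_hz <- if (params$sigma_mode == "relative") params$sigma * params$f0
           else params$sigma
  freqs <- stats::rnorm(n, params$f0, sd_hz)
  if (!is.null(params$freq_clip) && sd_hz > 0) {
    lo <- params$f0 - params$freq_clip
    hi <- params$f0 + params$freq_clip
    bad <- which(freqs < lo | freqs > hi)
    while (length(bad)) {
      freqs[bad] <- stats::rnorm(length(bad), params$f0, sd_hz)
      bad <- bad[freqs[bad] < lo | freqs[bad] > hi]
    }
  }
  structure(list(phases = phases, omegas = 2 * pi * freqs, time_s = 0),
            class = "population_state")
}

#' Population order parameter
#'
#' Magnitude and angle of the population-mean unit phasor:
#' rho * exp(i*psi) = mean(exp(i*theta_j)). `rho` in \[0, 1\] is the mean
#' phase-coherence (the synchrony biomarker); `psi` the mean phase.
#'
#' @param state a `population_state` (or any list with a `phases` element).
#' @return list with elements `rho` and `psi` (psi wrapped to (-pi, pi]).
#' @examples
#' s <- list(phases = c(0, pi / 2))
#' order_parameter(s)   # rho = sqrt(2)/2, psi = pi/4
#' @export
order_parameter <- function(state) {
  th <- state$phases
  if (length(th) < 1L)
    stop_tvbo("empty phase vector", "tvbo_invalid_state")
  z <- mean(exp(1i * th))
  list(rho = Mod(z), psi = wrap_angle(Arg(z)))
}

#' Advance the population by one integration step
#'
#' One explicit-Euler step of
#' dtheta_i/dt = omega_i + (gamma/N) sum_j sin(theta_j - theta_i)
#'             + I X(t) Z(theta_i),
#' with Z(theta) = -sin(theta + offset). The mean-field form
#' gamma * rho * sin(psi - theta_i) is arithmetically identical to the
#' pairwise sum and is the default; `method = "pairwise"` forces the O(N^2)
#' sum (used in equivalence tests).
#'
#' This is the reference single-step implementation; long simulations use the
#' compiled integrator behind [simulate_population()].
#'
#' @param state a `population_state`.
#' @param params a [kuramoto_params()] object.
#' @param prc a [prc_spec()] object.
#' @param stim_active logical; whether the stimulation term is applied.
#' @param method `"meanfield"` or `"pairwise"`.
#' @param wrap wrap resulting phases to (-pi, pi] (the drift depends only on
#'   phase differences, so this does not affect trajectories of rho).
#' @return the advanced `population_state`.
#' @export
step_population <- function(state, params, prc = prc_spec(),
                            stim_active = FALSE,
                            method = c("meanfield", "pairwise"),
                            wrap = TRUE) {
  method <- match.arg(method)
  th <- state$phases
  if (length(th) < 1L) stop_tvbo("empty phase vector", "tvbo_invalid_state")
  if (method == "meanfield") {
    op <- order_parameter(state)
    drift <- state$omegas + params$gamma * op$rho * sin(op$psi - th)
  } else {
    drift <- state$omegas +
      (params$gamma / length(th)) * colSums(sin(outer(th, th, "-")))
  }
  if (isTRUE(stim_active))
    drift <- drift + params$intensity * (-sin(th + prc$offset))
  th2 <- th + drift * params$dt
  if (wrap) th2 <- wrap_angle(th2)
  structure(list(phases = th2, omegas = state$omegas,
                 time_s = state$time_s + params$dt),
            class = "population_state")
}

#' Integrate the population for a span of simulated time
#'
#' Runs the compiled explicit-Euler integrator for `duration_s` seconds,
#' optionally with phase-locked stimulation: a rectangular pulse of
#' `protocol$pulse_width_s` is delivered each time the population mean phase
#' crosses `psi_target` in the direction of phase advance, with a refractory
#' of `protocol$refractory` mean cycles between pulse onsets.
#'
#' @inheritParams step_population
#' @param duration_s simulated time to integrate (s).
#' @param psi_target target mean phase for pulse triggering (radians); `NULL`
#'   for no stimulation.
#' @param protocol a [stim_protocol()] (pulse morphology; timing windows are
#'   not used here).
#' @param record_psi also return the per-step mean phase trace.
#' @return list with the advanced `state`, the per-step `rho` trace, the
#'   number of pulses delivered, and optionally `psi`.
#' @export
simulate_population <- function(state, params, duration_s,
                                psi_target = NULL, prc = prc_spec(),
                                protocol = stim_protocol(),
                                record_psi = FALSE) {
  n_steps <- as.integer(round(duration_s / params$dt))
  if (n_steps < 1L) stop_tvbo("duration shorter than dt", "tvbo_invalid_parameter")
  stim_on <- !is.null(psi_target)
  # trigger half a pulse early (in mean-phase advance) so the delivered
  # pulse is centered on the target phase rather than starting there
  trigger <- if (stim_on)
    wrap_angle(psi_target - pi * params$f0 * protocol$pulse_width_s) else 0
  res <- kuramoto_integrate_cpp(
    state$phases, state$omegas, params$dt, params$gamma, params$intensity,
    prc$offset, n_steps,
    stim_on, trigger,
    max(1L, as.integer(round(protocol$pulse_width_s / params$dt))),
    as.integer(round(protocol$refractory / params$f0 / params$dt)),
    FALSE, record_psi)
  out <- list(state = structure(list(phases = res$phases,
                                     omegas = state$omegas,
                                     time_s = state$time_s + n_steps * params$dt),
                                class = "population_state"),
              rho = res$rho, n_pulses = res$n_pulses)
  if (record_psi) out$psi <- res$psi
  out
}

#' Burn the population in to its steady state
#'
#' @inheritParams simulate_population
#' @param duration_s burn-in length in seconds (200 s reaches the
#'   high-synchrony plateau under the reference parameters).
#' @return the burned-in `population_state`.
#' @export
burn_in <- function(state, params, duration_s = 200) {
  simulate_population(state, params, duration_s)$state
}

#' Run one phase-locked stimulation trial
#'
#' Simulates one optimization step of the closed-loop protocol: the first
#' `step_duration_s - stim_window_s` seconds are unstimulated (the trailing
#' `baseline_window_s` of which forms the baseline), then phase-locked
#' stimulation at `psi_target` is applied for `stim_window_s`. The outcome is
#' the normalized change in mean phase-coherence
#' delta_rho = (mean rho_stim - mean rho_baseline) / mean rho_baseline,
#' negative when stimulation desynchronizes the population.
#'
#' @inheritParams simulate_population
#' @param psi_target stimulation target phase in (-pi, pi].
#' @return list with `rho_baseline`, `rho_stim`, `delta_rho`, `n_pulses`, and
#'   the evolved `state` (carried into the next optimization step).
#' @export
run_stimulation_trial <- function(state, params, prc = prc_spec(),
                                  protocol = stim_protocol(), psi_target) {
  pre_s <- protocol$step_duration_s - protocol$stim_window_s
  pre <- simulate_population(state, params, pre_s, prc = prc,
                             protocol = protocol)
  n_base <- as.integer(round(protocol$baseline_window_s / params$dt))
  rho_pre <- pre$rho
  rho_baseline <- mean(rho_pre[(length(rho_pre) - n_base + 1L):length(rho_pre)])
  if (rho_baseline < 1e-12)
    stop_tvbo("degenerate baseline: mean phase-coherence is zero",
              "tvbo_degenerate_baseline")
  stim <- simulate_population(pre$state, params, protocol$stim_window_s,
                              psi_target = psi_target, prc = prc,
                              protocol = protocol)
  rho_stim <- mean(stim$rho)
  list(rho_baseline = rho_baseline, rho_stim = rho_stim,
       delta_rho = (rho_stim - rho_baseline) / rho_baseline,
       n_pulses = stim$n_pulses, state = stim$state)
}

#' Empirical amplitude response curve (ARC) scan
#'
#' Runs one stimulation trial per grid phase, each starting from the same
#' burned-in population snapshot, and returns the empirical ARC: the change
#' in synchrony delta_rho as a function of the stimulation target phase. The
#' ARC is the objective function the optimizer works on; with the unshifted
#' phase response curve its minimum (strongest desynchronization) sits at
#' psi = -pi.
#'
#' @inheritParams run_stimulation_trial
#' @param phase_grid stimulation target phases to scan (radians).
#' @param seed seed for the population initialization.
#' @param burn_in_s burn-in time before the scan (s).
#' @param state optional pre-burned `population_state`; when supplied the
#'   initialization and burn-in are skipped.
#' @return data.frame of class `arc_scan` with columns `psi_target` and
#'   `delta_rho`.
#' @export
arc_scan <- function(params = kuramoto_params(), prc = prc_spec(),
                     protocol = stim_protocol(),
                     phase_grid = burn_in_schedule(12), seed = 1,
                     burn_in_s = 200, state = NULL) {
  if (length(phase_grid) < 1L)
    stop_tvbo("empty phase grid", "tvbo_invalid_parameter")
  if (is.null(state)) {
    state <- init_population(params, seed)
    state <- burn_in(state, params, burn_in_s)
  }
  dr <- vapply(phase_grid, function(p) {
    run_stimulation_trial(state, params, prc, protocol, p)$delta_rho
  }, numeric(1))
  structure(data.frame(psi_target = phase_grid, delta_rho = dr),
            class = c("arc_scan", "data.frame"), state = state)
}

#' Closed-loop Kuramoto objective for the optimizer
#'
#' Wraps the oscillator model as an objective function for [run_bayesopt()]:
#' calling the returned function with `(psi_target, step)` runs one
#' stimulation trial under the drift schedule's phase-response-curve offset
#' for that step, carrying the population state across steps (one continuous
#' simulation, no re-randomization).
#'
#' @inheritParams arc_scan
#' @param drift a [make_drift()] schedule supplying the PRC offset per step.
#' @return a function `(psi_target, step) -> delta_rho` with the burned-in
#'   starting state captured in its environment. Its `"probe"` attribute is a
#'   companion function with the same signature that measures the objective
#'   from a snapshot of the current state *without* advancing it -- the
#'   counterfactual measurement used to evaluate the objective at the true
#'   optimum for regret (call the probe before the advancing call within a
#'   step so both start from the same state).
#' @export
kuramoto_objective <- function(drift, params = kuramoto_params(),
                               protocol = stim_protocol(), seed = 1,
                               burn_in_s = 200) {
  state <- init_population(params, seed)
  state <- burn_in(state, params, burn_in_s)
  force(drift)
  # the unstimulated settle + baseline segment of a step is shared between
  # the tested trial and the counterfactual probe (both start from the same
  # state and baseline), so it is simulated once per step and cached
  cache <- list(step = NA_integer_)
  pre_for <- function(step) {
    if (!identical(cache$step, step)) {
      off <- drift$offsets[step]
      pre_s <- protocol$step_duration_s - protocol$stim_window_s
      pre <- simulate_population(state, params, pre_s,
                                 prc = prc_spec(off), protocol = protocol)
      n_base <- as.integer(round(protocol$baseline_window_s / params$dt))
      rho_base <- mean(pre$rho[(length(pre$rho) - n_base + 1L):
                                 length(pre$rho)])
      if (rho_base < 1e-12)
        stop_tvbo("degenerate baseline: mean phase-coherence is zero",
                  "tvbo_degenerate_baseline")
      cache <<- list(step = step, state = pre$state, rho_baseline = rho_base,
                     off = off)
    }
    cache
  }
  stim_branch <- function(psi_target, pre) {
    stim <- simulate_population(pre$state, params, protocol$stim_window_s,
                                psi_target = psi_target,
                                prc = prc_spec(pre$off), protocol = protocol)
    list(delta_rho = (mean(stim$rho) - pre$rho_baseline) / pre$rho_baseline,
         state = stim$state)
  }
  fn <- function(psi_target, step) {
    res <- stim_branch(psi_target, pre_for(step))
    state <<- res$state
    res$delta_rho
  }
  attr(fn, "probe") <- function(psi_target, step) {
    stim_branch(psi_target, pre_for(step))$delta_rho
  }
  fn
}
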