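#' Run the closed-loop (time-varying) Bayesian optimization controller
#'
#' Executes the full controller loop against an objective: `n_init`
#' equally-spaced burn-in phases first, then at every step the GP surrogate
#' is refit to the sample history, the GP-LCB acquisition is evaluated on
#' the candidate grid at the current step index, its minimizer is tested,
#' and the outcome appended. `kernel_kind = "static"` in `hp` reproduces
#' time-invariant BayesOpt; the forgetting / periodic / forgetting-periodic
#' kernels give the time-varying controller.
#'
#' Sample taken at loop step k carries temporal index t = k - 1, so burn-in
#' samples occupy indices 0..n_init-1 and age like any other sample under
#' the temporal kernels.
#'
#' @param objective function `(psi_target, step) -> y` (observed delta_rho);
#'   typically [kuramoto_objective()] or [toy_objective()].
#' @param drift the [make_drift()] schedule driving the objective, used to
#'   log the true optimum per step.
#' @param hp a [gp_hyperparams()] object (surrogate kernel).
#' @param spec an [acquisition_spec()].
#' @param n_steps total optimization steps (including burn-in).
#' @param n_init number of burn-in samples (default 12).
#' @param f_true objective value at the true optimum, for regret: a scalar
#'   (exact for the analytic toy objective, whose minimum value is constant
#'   under offset drift), a function of the step index, the string
#'   `"probe"` to measure it per step through the objective's `"probe"`
#'   attribute (a counterfactual trial from the same state as the tested
#'   phase; see [kuramoto_objective()]), or `NULL` to skip regret.
#' @param psi_star0 baseline optimum phase (default -pi).
#' @param seed seed set before the loop (covers any stochastic objective).
#' @param mode label recorded in the trace (defaults to `"static"` for the
#'   static kernel and `"tv"` otherwise).
#' @param verbose emit a progress message every 100 steps.
#' @return an object of class `tvbo_run`: list with `trace` (data.frame of
#'   per-step records), `regret` (a [cumulative_regret()] series, when
#'   `f_true` is given), and the run configuration.
#' @examples
#' d <- make_drift("none", n_steps = 40)
#' run <- run_bayesopt(toy_objective(d), d,
#'                     hp = gp_hyperparams(), n_steps = 40, f_true = -1)
#' summary(run)
#' @export
run_bayesopt <- function(objective, drift, hp = gp_hyperparams(),
                         spec = acquisition_spec(), n_steps = drift$n_steps,
                         n_init = 12, f_true = NULL, psi_star0 = -pi,
                         seed = NULL, mode = NULL, verbose = FALSE) {
  check_scalar(n_steps, "n_steps", lower = 1)
  n_steps <- as.integer(n_steps)
  if (n_steps > drift$n_steps)
    stop_tvbo("n_steps exceeds the drift schedule length",
              "tvbo_invalid_parameter")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(mode))
    mode <- if (hp$kernel_kind == "static") "static" else "tv"
  init_phases <- burn_in_schedule(min(n_init, n_steps))
  grid <- candidate_grid(spec$grid_size)

  probe_mode <- identical(f_true, "probe")
  probe <- attr(objective, "probe")
  if (probe_mode && is.null(probe))
    stop_tvbo("f_true = \"probe\" requires an objective with a probe attribute",
              "tvbo_invalid_parameter")
  history <- data.frame(x = numeric(n_steps), t = numeric(n_steps),
                        y = numeric(n_steps))
  psi_true <- true_optimum(drift$offsets[seq_len(n_steps)], psi_star0)
  ft_probe <- numeric(n_steps)
  for (k in seq_len(n_steps)) {
    if (k <= length(init_phases)) {
      psi_k <- init_phases[k]
    } else {
      fit <- tv_gp(history[seq_len(k - 1L), ], hp)
      post <- predict(fit, x = grid, t = k - 1L)
      psi_k <- select_next(lcb(post, spec), grid, spec)
    }
    if (probe_mode) ft_probe[k] <- probe(psi_true[k], k)
    y_k <- tryCatch(objective(psi_k, k), error = function(e)
      stop_tvbo(sprintf("objective failed at step %d: %s", k,
                        conditionMessage(e)), "tvbo_objective_error"))
    history$x[k] <- psi_k
    history$t[k] <- k - 1L
    history$y[k] <- y_k
    if (verbose && k %% 100L == 0L)
      message(sprintf("step %d/%d: tested %.3f rad, y = %.4f",
                      k, n_steps, psi_k, y_k))
  }
  if (probe_mode) f_true <- ft_probe

  trace <- data.frame(step = seq_len(n_steps), t = history$t,
                      delta_theta = drift$offsets[seq_len(n_steps)],
                      psi_true = psi_true, psi_target = history$x,
                      y = history$y)
  reg <- NULL
  if (!is.null(f_true)) {
    ft <- if (is.function(f_true)) vapply(seq_len(n_steps), f_true, numeric(1))
          else rep_len(f_true, n_steps)
    trace$f_true <- ft
    trace$regret <- regret(ft, trace$y)
    reg <- cumulative_regret(trace$regret)
    trace$cum_regret <- reg$cum_regret
  }
  structure(list(trace = trace, regret = reg, mode = mode, hp = hp,
                 spec = spec, drift = drift[c("kind", "n_steps",
                                              "period_steps", "amplitude",
                                              "noise_std")],
                 n_init = n_init, seed = seed),
            class = "tvbo_run")
}

#' Run the fixed scheduler baseline
#'
#' A non-learning controller that replays a fixed per-time-of-cycle phase
#' schedule: at step k it stimulates at `schedule[(k - 1) mod P + 1]` where
#' P is the schedule length (the anticipated period). Use
#' [oracle_schedule()] to build the schedule that replays the true optimum
#' trajectory of the anticipated drift.
#'
#' @inheritParams run_bayesopt
#' @param schedule vector of phases covering one anticipated period.
#' @return a `tvbo_run` object with `mode = "scheduler"`.
#' @export
run_scheduler <- function(objective, drift, schedule,
                          n_steps = drift$n_steps, f_true = NULL,
                          psi_star0 = -pi, seed = NULL) {
  check_scalar(n_steps, "n_steps", lower = 1)
  if (length(schedule) < 1L)
    stop_tvbo("empty schedule", "tvbo_invalid_parameter")
  n_steps <- as.integer(n_steps)
  if (!is.null(seed)) set.seed(seed)
  psi_true <- true_optimum(drift$offsets[seq_len(n_steps)], psi_star0)
  psi_target <- schedule[(seq_len(n_steps) - 1L) %% length(schedule) + 1L]
  probe_mode <- identical(f_true, "probe")
  probe <- attr(objective, "probe")
  if (probe_mode && is.null(probe))
    stop_tvbo("f_true = \"probe\" requires an objective with a probe attribute",
              "tvbo_invalid_parameter")
  ft_probe <- numeric(n_steps)
  y <- vapply(seq_len(n_steps), function(k) {
    if (probe_mode) ft_probe[k] <<- probe(psi_true[k], k)
    objective(psi_target[k], k)
  }, numeric(1))
  if (probe_mode) f_true <- ft_probe
  trace <- data.frame(step = seq_len(n_steps), t = seq_len(n_steps) - 1L,
                      delta_theta = drift$offsets[seq_len(n_steps)],
                      psi_true = psi_true, psi_target = psi_target, y = y)
  reg <- NULL
  if (!is.null(f_true)) {
    ft <- if (is.function(f_true)) vapply(seq_len(n_steps), f_true, numeric(1))
          else rep_len(f_true, n_steps)
    trace$f_true <- ft
    trace$regret <- regret(ft, trace$y)
    reg <- cumulative_regret(trace$regret)
    trace$cum_regret <- reg$cum_regret
  }
  structure(list(trace = trace, regret = reg, mode = "scheduler",
                 hp = NULL, spec = NULL,
                 drift = drift[c("kind", "n_steps", "period_steps",
                                 "amplitude", "noise_std")],
                 n_init = 0L, seed = seed),
            class = "tvbo_run")
}

#' Oracle schedule over one anticipated period
#'
#' The true-optimum trajectory of a periodic drift with the *anticipated*
#' period: psi_k = wrap(psi_star0 + amplitude * sin^2(pi k / P)),
#' k = 0..P-1. Replaying it with [run_scheduler()] is a perfect controller
#' when the anticipated period matches the true one, and degrades as they
#' diverge.
#'
#' @param period_steps anticipated period P in steps.
#' @param amplitude drift amplitude in radians.
#' @param psi_star0 baseline optimum phase.
#' @return vector of P phases.
#' @export
oracle_schedule <- function(period_steps, amplitude = pi, psi_star0 = -pi) {
  check_scalar(period_steps, "period_steps", lower = 1)
  k <- seq_len(as.integer(period_steps)) - 1L
  offsets <- -amplitude * sin(pi * k / period_steps)^2
  wrap_angle(psi_star0 - offsets)
}

#' @export
print.tvbo_run <- function(x, ...) {
  cat(sprintf("Closed-loop optimization run (%s controller)\n", x$mode))
  cat(sprintf("  %d steps, drift: %s", nrow(x$trace), x$drift$kind))
  if (!is.null(x$hp)) cat(sprintf(", kernel: %s", x$hp$kernel_kind))
  cat("\n")
  if (!is.null(x$regret))
    cat(sprintf("  final cumulative regret %.4f, regret AUC %.4f\n",
                x$regret$cum_regret[length(x$regret$cum_regret)],
                x$regret$auc))
  invisible(x)
}

#' @export
summary.tvbo_run <- function(object, ...) {
  tr <- object$trace
  err <- abs(angle_diff(tr$psi_target, tr$psi_true))
  late <- tr$step > 0.75 * nrow(tr)
  out <- list(mode = object$mode, n_steps = nrow(tr),
              drift_kind = object$drift$kind,
              mean_abs_tracking_error = mean(err),
              late_mean_abs_tracking_error = mean(err[late]),
              final_cum_regret = if (!is.null(object$regret))
                object$regret$cum_regret[nrow(tr)] else NA_real_,
              regret_auc = if (!is.null(object$regret))
                object$regret$auc else NA_real_)
  class(out) <- "summary.tvbo_run"
  out
}

#' @export
print.summary.tvbo_run <- function(x, ...) {
  cat(sprintf("%s controller, %d steps, %s drift\n",
              x$mode, x$n_steps, x$drift_kind))
  cat(sprintf("  mean |tracking error|: %.3f rad (last quarter: %.3f rad)\n",
              x$mean_abs_tracking_error, x$late_mean_abs_tracking_error))
  if (!is.na(x$final_cum_regret))
    cat(sprintf("  final cumulative regret: %.4f, AUC: %.4f\n",
                x$final_cum_regret, x$regret_auc))
  invisible(x)
}

#' Plot a closed-loop optimization run
#'
#' Two base-graphics panels: tested vs true optimal phase over steps, and
#' the cumulative (running-mean) regret curve when regret was computed.
#'
#' @param x a `tvbo_run` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.tvbo_run <- function(x, ...) {
  tr <- x$trace
  has_reg <- !is.null(x$regret)
  old <- graphics::par(mfrow = c(if (has_reg) 2 else 1, 1),
                       mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  graphics::plot(tr$step, tr$psi_true, pch = 16, cex = 0.4, col = "black",
                 ylim = c(-pi, pi), xlab = "optimization step",
                 ylab = "phase (rad)",
                 main = sprintf("%s controller, %s drift", x$mode,
                                x$drift$kind), ...)
  graphics::points(tr$step, tr$psi_target, pch = 1, cex = 0.4, col = "blue")
  graphics::legend("topright", legend = c("true optimum", "tested"),
                   pch = c(16, 1), col = c("black", "blue"), cex = 0.8)
  if (has_reg) {
    graphics::plot(tr$step, tr$cum_regret, type = "l",
                   xlab = "optimization step", ylab = "cumulative regret")
  }
  invisible(x)
}
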