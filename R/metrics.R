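#' Per-step regret
#'
#' R_k = f(psi*_k) - f(psi_target_k): the objective value at the true
#' optimum minus the value achieved at the tested phase, both measured under
#' the same step's conditions. Since the objective (delta_rho) is minimized
#' and f(psi*_k) is its minimum, R_k is non-positive up to observation
#' noise; a perfect controller keeps it at 0.
#'
#' @param f_true objective value(s) at the true optimum psi*_k.
#' @param f_tested objective value(s) at the tested phase.
#' @return regret value(s).
#' @export
regret <- function(f_true, f_tested) f_true - f_tested

#' Cumulative regret series and its AUC
#'
#' The cumulative regret at step k is the running mean of the per-step
#' regrets, CR_k = sum(R_1..R_k) / k (the printed definition divides by the
#' step count, so the curve is an average; the undivided running sum is
#' exposed as `sum_regret`). The scalar summary is the trapezoidal area
#' under the CR curve over the step index (`auc`, signed) together with its
#' magnitude (`auc_mag`), which is the "high = inaccurate optimization"
#' scale used for controller comparisons.
#'
#' @param regrets numeric vector of per-step regrets.
#' @return an object of class `regret_series`: list with `regret`,
#'   `cum_regret`, `sum_regret`, `auc`, `auc_mag`.
#' @examples
#' cumulative_regret(c(-0.5, 0))   # CR = (-0.5, -0.25), AUC = -0.375
#' @export
cumulative_regret <- function(regrets) {
  if (length(regrets) < 1L)
    stop_tvbo("empty regret sequence", "tvbo_invalid_parameter")
  cr <- cumsum(regrets) / seq_along(regrets)
  auc <- if (length(cr) == 1L) 0 else
    sum((cr[-1] + cr[-length(cr)]) / 2)
  structure(list(regret = regrets, cum_regret = cr,
                 sum_regret = cumsum(regrets), auc = auc,
                 auc_mag = abs(auc)),
            class = "regret_series")
}

#' @export
print.regret_series <- function(x, ...) {
  n <- length(x$regret)
  cat(sprintf("Regret series over %d steps: final CR = %.4f, AUC = %.4f\n",
              n, x$cum_regret[n], x$auc))
  invisible(x)
}

#' Sensitivity sweep over the forgetting factor
#'
#' For each forgetting factor on the grid, runs the full closed-loop
#' optimization under the configured (superimposed) drift twice -- once with
#' the forgetting kernel alone, once with the forgetting-periodic kernel --
#' using common seeds per grid point, and tabulates the cumulative-regret
#' AUC of each run. Low epsilon under-forgets (stale samples mislead the
#' surrogate unless the periodic component supplies the cycle structure);
#' very high epsilon forgets too fast to estimate the optimum at all.
#'
#' @param config list of run settings as produced by
#'   [tvbo_config()]/[parse_config()]; the scenario block should describe a
#'   superimposed drift.
#' @param epsilon_grid forgetting factors to test.
#' @param seeds one or more seeds; runs are paired across kernel kinds.
#' @return data.frame with columns `sweep_value`, `mode`, `auc`, `auc_mag`,
#'   `n_steps`, `seed`.
#' @export
sweep_epsilon <- function(config, epsilon_grid, seeds = config$seed) {
  rows <- list()
  for (eps in epsilon_grid) for (seed in seeds) {
    for (kind in c("forgetting", "forgetting_periodic")) {
      cf <- config
      cf$gp$epsilon <- eps
      cf$gp$kernel_kind <- kind
      cf$seed <- seed
      run <- run_from_config(cf)
      rows[[length(rows) + 1L]] <-
        data.frame(sweep_value = eps, mode = kind, auc = run$regret$auc,
                   auc_mag = run$regret$auc_mag,
                   n_steps = nrow(run$trace), seed = seed)
    }
  }
  do.call(rbind, rows)
}

#' Sensitivity sweep over the drift-period offset
#'
#' Varies the *true* period of a periodic drift away from the period
#' anticipated by the controller (which stays fixed at the configured
#' `gp$T_t`), and compares three controllers at each offset with paired
#' seeds: the fixed scheduler replaying the anticipated-period optimum
#' trajectory, TV-BayesOpt with the periodic kernel, and TV-BayesOpt with
#' the forgetting-periodic kernel.
#'
#' @param config list of run settings (scenario block: periodic drift; the
#'   anticipated period is `config$gp$T_t`).
#' @param offset_grid offsets (in steps) added to the anticipated period to
#'   form the true drift period.
#' @param seeds one or more seeds; paired across controllers.
#' @return data.frame with columns `sweep_value`, `mode`, `auc`, `auc_mag`,
#'   `n_steps`, `seed`.
#' @export
sweep_period_offset <- function(config, offset_grid, seeds = config$seed) {
  rows <- list()
  for (off in offset_grid) for (seed in seeds) {
    cf <- config
    cf$scenario$period_steps <- config$gp$T_t + off
    cf$seed <- seed
    for (mode in c("scheduler", "periodic", "forgetting_periodic")) {
      cfm <- cf
      if (mode == "scheduler") {
        cfm$mode <- "scheduler"
      } else {
        cfm$mode <- "tv"
        cfm$gp$kernel_kind <- mode
      }
      run <- run_from_config(cfm)
      rows[[length(rows) + 1L]] <-
        data.frame(sweep_value = off, mode = mode, auc = run$regret$auc,
                   auc_mag = run$regret$auc_mag,
                   n_steps = nrow(run$trace), seed = seed)
    }
  }
  do.call(rbind, rows)
}
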