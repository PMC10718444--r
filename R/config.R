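# Run configuration: defaults, JSON parsing/validation, trace serialization.

default_config <- function() {
  list(
    schema_version = 1L,
    mode = "tv",                # tv | static | scheduler
    backend = "kuramoto",       # kuramoto | toy
    n_steps = 3000L,
    n_init = 12L,
    seed = 1L,
    burn_in_s = 200,
    f_true = NULL,              # objective value at the optimum (for regret)
    model = list(n_oscillators = 50L, f0 = 8, sigma = 0.0075, gamma = 0.8,
                 intensity = 30, dt = 1e-3, freq_clip = 0.15,
                 sigma_mode = "relative"),
    protocol = list(step_duration_s = 58, stim_window_s = 8,
                    baseline_window_s = 25, pulse_width_s = 0.002,
                    refractory = 0.5),
    gp = list(l_x = 1, T_x = 2 * pi, epsilon = 0, T_t = 100, l_tp = 1,
              sigma_n2 = 1e-2, kernel_kind = "static", window = 500),
    acquisition = list(kappa = 0.3, grid_size = 360L, tie_break = "smallest"),
    scenario = list(kind = "none", period_steps = 100L, amplitude = pi,
                    noise_std = 0),
    toy = list(amplitude = 1, noise_std_y = 0),
    out = NULL
  )
}

# merge user values over defaults, rejecting keys the schema does not know
merge_config <- function(defaults, user, path = "") {
  for (key in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(defaults))
      stop_tvbo(sprintf("unknown configuration key '%s'", full),
                "tvbo_config_error")
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      if (!is.list(user[[key]]))
        stop_tvbo(sprintf("configuration key '%s' must be a block", full),
                  "tvbo_config_error")
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]], full)
    } else {
      # [key] <- list(...) keeps explicit NULLs instead of dropping the slot
      defaults[key] <- list(user[[key]])
    }
  }
  defaults
}

#' Build a validated run configuration
#'
#' Fills documented defaults (the reference model parameters and the 58 s /
#' 8 s / 25 s trial protocol with 12 burn-in samples) and validates every
#' block; unknown keys are rejected with a message naming the key.
#'
#' @param ... configuration overrides, possibly nested lists (e.g.
#'   `gp = list(epsilon = 0.22)`).
#' @return a validated configuration list of class `tvbo_config`.
#' @examples
#' cfg <- tvbo_config(mode = "tv", gp = list(kernel_kind = "forgetting"))
#' cfg$gp$kernel_kind
#' @export
tvbo_config <- function(...) {
  validate_config(merge_config(default_config(), list(...)))
}

validate_config <- function(config) {
  if (!config$mode %in% c("tv", "static", "scheduler"))
    stop_tvbo(sprintf("unknown mode '%s'", config$mode), "tvbo_config_error")
  if (!config$backend %in% c("kuramoto", "toy"))
    stop_tvbo(sprintf("unknown backend '%s'", config$backend),
              "tvbo_config_error")
  if (!is.numeric(config$n_steps) || config$n_steps < 1)
    stop_tvbo("n_steps must be a positive integer", "tvbo_config_error")
  config$n_steps <- as.integer(config$n_steps)
  if (!config$scenario$kind %in% c("none", "gradual", "periodic",
                                   "superimposed"))
    stop_tvbo(sprintf("unknown scenario kind '%s'", config$scenario$kind),
              "tvbo_config_error")
  # constructors perform the per-block range validation
  do.call(kuramoto_params, config$model)
  do.call(stim_protocol, config$protocol)
  do.call(gp_hyperparams, config$gp)
  do.call(acquisition_spec, config$acquisition)
  class(config) <- c("tvbo_config", "list")
  config
}

#' Parse a JSON run configuration
#'
#' Reads a configuration from a JSON file (or inline JSON text), merges it
#' over the documented defaults and validates it. Round-trips with
#' [write_trace()]'s sidecar JSON: `parse_config(write(config))` equals
#' `config`.
#'
#' @param path path to a JSON document, or a JSON string.
#' @return a validated `tvbo_config` list.
#' @export
parse_config <- function(path) {
  txt <- if (length(path) == 1L && !grepl("[{]", path) && file.exists(path))
    paste(readLines(path, warn = FALSE), collapse = "\n") else path
  user <- tryCatch(jsonlite::fromJSON(txt, simplifyVector = TRUE),
                   error = function(e)
                     stop_tvbo(sprintf("malformed JSON configuration: %s",
                                       conditionMessage(e)),
                               "tvbo_config_error"))
  if (length(user) == 0L) user <- list()
  validate_config(merge_config(default_config(), user))
}

#' Execute one configured optimization run
#'
#' Builds the drift schedule, the objective (oscillator-model-backed or the
#' analytic toy), and runs the controller selected by `config$mode`:
#' `"tv"` uses the configured temporal kernel, `"static"` forces the
#' time-invariant kernel, `"scheduler"` replays the anticipated-period
#' oracle schedule.
#'
#' @param config a `tvbo_config` list.
#' @param verbose log the resolved-configuration hash, the seed, per-100-step
#'   progress, and the final regret AUC.
#' @return a `tvbo_run` object.
#' @export
run_from_config <- function(config, verbose = FALSE) {
  if (!inherits(config, "tvbo_config")) config <- validate_config(config)
  if (verbose) {
    tf <- tempfile(fileext = ".json")
    jsonlite::write_json(unclass(config), tf, auto_unbox = TRUE,
                         digits = I(17), null = "null")
    message(sprintf("run config md5 %s, seed %d, mode %s",
                    unname(tools::md5sum(tf)), config$seed, config$mode))
    unlink(tf)
  }
  drift <- make_drift(config$scenario$kind, n_steps = config$n_steps,
                      period_steps = config$scenario$period_steps,
                      amplitude = config$scenario$amplitude,
                      noise_std = config$scenario$noise_std,
                      seed = config$seed)
  f_true <- config$f_true
  if (config$backend == "toy") {
    objective <- toy_objective(drift, amplitude = config$toy$amplitude,
                               noise_std_y = config$toy$noise_std_y,
                               seed = config$seed)
    if (is.null(f_true)) f_true <- -config$toy$amplitude
  } else {
    params <- do.call(kuramoto_params, config$model)
    protocol <- do.call(stim_protocol, config$protocol)
    objective <- kuramoto_objective(drift, params, protocol,
                                    seed = config$seed,
                                    burn_in_s = config$burn_in_s)
    if (is.null(f_true)) f_true <- "probe"
  }
  if (config$mode == "scheduler") {
    sched <- oracle_schedule(config$gp$T_t,
                             amplitude = config$scenario$amplitude)
    run <- run_scheduler(objective, drift, sched, n_steps = config$n_steps,
                         f_true = f_true, seed = config$seed)
    if (verbose && !is.null(run$regret))
      message(sprintf("final regret AUC %.4f", run$regret$auc))
    return(run)
  }
  gp_cfg <- config$gp
  if (config$mode == "static") gp_cfg$kernel_kind <- "static"
  hp <- do.call(gp_hyperparams, gp_cfg)
  spec <- do.call(acquisition_spec, config$acquisition)
  run <- run_bayesopt(objective, drift, hp = hp, spec = spec,
                      n_steps = config$n_steps, n_init = config$n_init,
                      f_true = f_true, seed = config$seed,
                      mode = config$mode, verbose = verbose)
  if (verbose && !is.null(run$regret))
    message(sprintf("final regret AUC %.4f", run$regret$auc))
  run
}

#' Serialize an optimization trace
#'
#' Writes the per-step trace as CSV (columns: step, sim_time_s, delta_theta,
#' psi_true, psi_target, delta_rho, regret, cum_regret; angles in radians
#' wrapped to (-pi, pi], 6 decimal places) plus a sidecar `<path>.json`
#' holding the resolved configuration and seed for exact replay.
#'
#' @param run a `tvbo_run` object.
#' @param path output CSV path.
#' @param config the resolved `tvbo_config` used for the run (serialized to
#'   the sidecar; also supplies the per-step simulated time).
#' @return `path`, invisibly.
#' @export
write_trace <- function(run, path, config = NULL) {
  tr <- run$trace
  step_s <- if (!is.null(config)) config$protocol$step_duration_s else NA_real_
  fmt <- function(v) sprintf("%.6f", v)
  out <- data.frame(
    step = tr$step,
    sim_time_s = if (is.na(step_s)) rep("", nrow(tr)) else
      fmt(tr$step * step_s),
    delta_theta = fmt(wrap_angle(tr$delta_theta)),
    psi_true = fmt(tr$psi_true),
    psi_target = fmt(tr$psi_target),
    delta_rho = fmt(tr$y),
    regret = if (!is.null(tr$regret)) fmt(tr$regret) else rep("", nrow(tr)),
    cum_regret = if (!is.null(tr$cum_regret)) fmt(tr$cum_regret) else
      rep("", nrow(tr)))
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop_tvbo(sprintf("cannot write trace to '%s'", path),
                     "tvbo_io_error")
  if (!is.null(config)) {
    cf <- unclass(config)
    # I(17) significant digits so every double survives the round trip
    # bit-exactly (replay must reproduce the trace byte for byte)
    jsonlite::write_json(cf, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = I(17), null = "null")
  }
  invisible(path)
}
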