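#' Acquisition settings for GP-LCB sampling
#'
#' @param kappa exploration weight kappa >= 0 multiplying the posterior
#'   standard deviation; high values favour exploration of uncertain phases,
#'   low values exploitation of the estimated minimum. Default 0.3
#'   (exploitation-leaning; see the methods vignette).
#' @param grid_size number of candidate phases on the uniform grid over
#'   (-pi, pi] (default 360, i.e. 1 degree resolution).
#' @param tie_break rule for exactly tied acquisition minima; `"smallest"`
#'   returns the smallest candidate phase.
#' @return an object of class `acquisition_spec`.
#' @export
acquisition_spec <- function(kappa = 0.3, grid_size = 360,
                             tie_break = "smallest") {
  check_scalar(kappa, "kappa", lower = 0)
  check_scalar(grid_size, "grid_size", lower = 2)
  structure(list(kappa = kappa, grid_size = as.integer(grid_size),
                 tie_break = tie_break),
            class = "acquisition_spec")
}

#' Uniform candidate phase grid
#'
#' `grid_size` phases equally spaced on the periodic interval, starting at
#' -pi (the endpoint pi is excluded since -pi and pi coincide).
#'
#' @param grid_size number of candidates.
#' @return phases in radians.
#' @export
candidate_grid <- function(grid_size = 360) {
  -pi + 2 * pi * (seq_len(grid_size) - 1L) / grid_size
}

#' Lower-confidence-bound acquisition values
#'
#' alpha(x) = mu*(x) - kappa * sigma*(x), evaluated elementwise on a
#' posterior. The next sample is the minimizer of alpha (the objective is
#' minimized: more negative delta_rho means stronger desynchronization).
#'
#' @param post posterior data.frame from [predict.tv_gp()] (columns `mu`,
#'   `var`).
#' @param spec an [acquisition_spec()].
#' @return numeric vector of acquisition values.
#' @export
lcb <- function(post, spec = acquisition_spec()) {
  if (any(post$var < -1e-10))
    stop_tvbo("negative posterior variance", "tvbo_numerical_conditioning")
  post$mu - spec$kappa * sqrt(pmax(post$var, 0))
}

#' Select the next phase to test
#'
#' Returns the candidate phase minimizing the acquisition values; exact ties
#' are broken per `spec$tie_break` (default: the smallest phase value).
#'
#' @param acq acquisition values from [lcb()].
#' @param grid candidate phases, same length as `acq`.
#' @param spec an [acquisition_spec()].
#' @return a single phase in radians.
#' @export
select_next <- function(acq, grid, spec = acquisition_spec()) {
  if (length(grid) < 1L || length(acq) != length(grid))
    stop_tvbo("acquisition values and grid must be non-empty and equal length",
              "tvbo_invalid_parameter")
  idx <- which(acq == min(acq))
  if (length(idx) > 1L) idx <- idx[which.min(grid[idx])]
  grid[idx]
}

#' Burn-in phase schedule
#'
#' `n_init` equally spaced stimulation phases over the periodic interval:
#' psi_k = -pi + 2*pi*k/n_init, k = 0..n_init-1 (endpoint excluded since
#' -pi and pi coincide). The default 12 samples coarsely characterize the
#' amplitude response curve before the acquisition loop starts.
#'
#' @param n_init number of burn-in samples (>= 1).
#' @return phases in radians, first element -pi.
#' @export
burn_in_schedule <- function(n_init = 12) {
  check_scalar(n_init, "n_init", lower = 1)
  n_init <- as.integer(n_init)
  -pi + 2 * pi * (seq_len(n_init) - 1L) / n_init
}
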