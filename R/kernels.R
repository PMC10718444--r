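#' Gaussian-process hyperparameters for the spatio-temporal surrogate
#'
#' Collects the kernel hyperparameters of the surrogate: the spatial
#' exponential-sine-squared kernel over stimulation phases (lengthscale
#' `l_x`, period `T_x`, fixed at 2*pi by the periodicity of phase space), and
#' the temporal kernel over optimization-step indices, selected by
#' `kernel_kind`:
#' \describe{
#'   \item{static}{K_t = 1 (time-invariant surrogate).}
#'   \item{forgetting}{K_t = (1 - epsilon)^(|t - t'| / 2); `epsilon` in
#'     \[0, 1) is the forgetting factor.}
#'   \item{periodic}{K_t = exp(-2 sin^2(pi |t - t'| / T_t) / l_tp^2);
#'     `T_t` the anticipated drift period in steps.}
#'   \item{forgetting_periodic}{product of the previous two.}
#' }
#'
#' @param l_x spatial lengthscale.
#' @param T_x spatial period in radians.
#' @param epsilon forgetting factor in \[0, 1).
#' @param T_t temporal period in optimization steps.
#' @param l_tp temporal lengthscale of the periodic component.
#' @param sigma_n2 observation-noise variance.
#' @param kernel_kind one of `"static"`, `"forgetting"`, `"periodic"`,
#'   `"forgetting_periodic"`.
#' @param window sliding-window size: only the most recent `window` samples
#'   enter the exact GP solve (`Inf` keeps everything). Old samples are
#'   down-weighted to negligibility by the forgetting kernel anyway; the
#'   window bounds the O(n^3) cost of long runs.
#' @return an object of class `gp_hyperparams`.
#' @export
gp_hyperparams <- function(l_x = 1, T_x = 2 * pi, epsilon = 0,
                           T_t = 100, l_tp = 1, sigma_n2 = 1e-2,
                           kernel_kind = c("static", "forgetting", "periodic",
                                           "forgetting_periodic"),
                           window = 500) {
  kernel_kind <- match.arg(kernel_kind)
  check_scalar(l_x, "l_x", lower = 0, strict_lower = TRUE)
  check_scalar(T_x, "T_x", lower = 0, strict_lower = TRUE)
  if (!is.numeric(epsilon) || length(epsilon) != 1L ||
      epsilon < 0 || epsilon >= 1)
    stop_tvbo("'epsilon' must lie in [0, 1)", "tvbo_invalid_parameter")
  check_scalar(T_t, "T_t", lower = 0, strict_lower = TRUE)
  check_scalar(l_tp, "l_tp", lower = 0, strict_lower = TRUE)
  check_scalar(sigma_n2, "sigma_n2", lower = 0)
  check_scalar(window, "window", lower = 1)
  structure(list(l_x = l_x, T_x = T_x, epsilon = epsilon, T_t = T_t,
                 l_tp = l_tp, sigma_n2 = sigma_n2, kernel_kind = kernel_kind,
                 window = window),
            class = "gp_hyperparams")
}

#' @export
print.gp_hyperparams <- function(x, ...) {
  cat(sprintf("GP hyperparameters (%s kernel)\n", x$kernel_kind))
  cat(sprintf("  spatial: l_x = %g, T_x = %g\n", x$l_x, x$T_x))
  cat(sprintf("  temporal: epsilon = %g, T_t = %g, l_tp = %g\n",
              x$epsilon, x$T_t, x$l_tp))
  cat(sprintf("  noise sigma_n^2 = %g, window = %g\n", x$sigma_n2, x$window))
  invisible(x)
}

#' Spatial covariance between stimulation phases
#'
#' Exponential-sine-squared (periodic) kernel
#' K_s(x, x') = exp(-2 sin^2(pi |x - x'| / T_x) / l_x^2),
#' matching the periodicity of the phase parameter space (-pi and pi are the
#' same stimulation setting). Values in (0, 1\], symmetric, periodic in T_x.
#'
#' @param x,x2 phases in radians (vectorized, recycled).
#' @param hp a [gp_hyperparams()] object.
#' @return covariance value(s).
#' @export
spatial_kernel <- function(x, x2, hp = gp_hyperparams()) {
  exp(-2 * sin(pi * abs(x - x2) / hp$T_x)^2 / hp$l_x^2)
}

#' Temporal covariance between optimization-step indices
#'
#' Dispatches on `hp$kernel_kind`; see [gp_hyperparams()] for the four
#' forms. With `epsilon = 0` the forgetting kernel is identically 1, i.e.
#' no data are forgotten and the surrogate is time-invariant.
#'
#' @param t,t2 step indices (vectorized, recycled).
#' @param hp a [gp_hyperparams()] object.
#' @return covariance value(s) in (0, 1].
#' @export
temporal_kernel <- function(t, t2, hp = gp_hyperparams()) {
  lag <- abs(t - t2)
  switch(hp$kernel_kind,
    static = rep(1, length(lag)),
    forgetting = (1 - hp$epsilon)^(lag / 2),
    periodic = exp(-2 * sin(pi * lag / hp$T_t)^2 / hp$l_tp^2),
    forgetting_periodic =
      (1 - hp$epsilon)^(lag / 2) *
      exp(-2 * sin(pi * lag / hp$T_t)^2 / hp$l_tp^2))
}

#' Spatio-temporal covariance between samples
#'
#' Hadamard product of the spatial kernel over phases and the temporal
#' kernel over step indices: K(a, b) = K_s(a_x, b_x) * K_t(a_t, b_t). A
#' product of positive-semidefinite kernels, hence itself PSD on any finite
#' sample set.
#'
#' @param x,x2 phases in radians.
#' @param t,t2 step indices.
#' @param hp a [gp_hyperparams()] object.
#' @return covariance value(s).
#' @export
spatiotemporal_kernel <- function(x, t, x2, t2, hp = gp_hyperparams()) {
  spatial_kernel(x, x2, hp) * temporal_kernel(t, t2, hp)
}

#' Forgetting factor from a data half-life
#'
#' epsilon = ln(2) / t_half: the half-life convention used to interpret the
#' forgetting factor, where a sample `t_half` steps old contributes 50% of
#' its original weight under [half_life_weight()].
#'
#' Note this convention and the forgetting kernel
#' (1 - epsilon)^(|lag| / 2) are two distinct printed formulas that do not
#' coincide (the kernel decays roughly half as fast as exp(-epsilon * lag));
#' both are provided exactly as defined, not reconciled.
#'
#' @param t_half half-life in number of samples (> 0).
#' @return the forgetting factor epsilon.
#' @examples
#' half_life_to_epsilon(100)          # ~0.00693
#' log(2) / 0.22                      # the half-life implied by eps = 0.22
#' @export
half_life_to_epsilon <- function(t_half) {
  check_scalar(t_half, "t_half", lower = 0, strict_lower = TRUE)
  log(2) / t_half
}

#' Half-life decay weight of an aged sample
#'
#' weight = 2^(-lag / t_half) = exp(-lambda * lag) with
#' lambda = ln(2) / t_half; equals 1 at lag 0 and 0.5 at one half-life.
#'
#' @param lag sample age in steps (>= 0, vectorized).
#' @param t_half half-life in samples (> 0).
#' @return relative weight(s) in (0, 1].
#' @export
half_life_weight <- function(lag, t_half) {
  check_scalar(t_half, "t_half", lower = 0, strict_lower = TRUE)
  2^(-lag / t_half)
}
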