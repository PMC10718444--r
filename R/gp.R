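# Gaussian-process surrogate with exact posterior inference.
#
# Zero prior mean (the objective delta_rho is centered on 0 by
# construction); Gram matrix factorized by Cholesky with adaptive jitter.

# internal: full kernel matrix between two sample sets
kernel_matrix <- function(x1, t1, x2, t2, hp) {
  Ks <- outer(x1, x2, function(a, b) spatial_kernel(a, b, hp))
  Kt <- outer(t1, t2, function(a, b) temporal_kernel(a, b, hp))
  Ks * Kt
}

# internal: Cholesky with adaptive jitter, 1e-10 doubling up to 1e-6
chol_jitter <- function(K) {
  R <- tryCatch(chol(K), error = function(e) NULL)
  jit <- 1e-10
  while (is.null(R) && jit <= 1e-6) {
    R <- tryCatch(chol(K + diag(jit, nrow(K))), error = function(e) NULL)
    jit <- jit * 2
  }
  if (is.null(R))
    stop_tvbo("Gram matrix not factorizable even after maximum jitter",
              "tvbo_numerical_conditioning")
  R
}

#' Fit the Gaussian-process surrogate to an observation history
#'
#' Conditions the zero-mean GP prior with spatio-temporal covariance on the
#' sampled (phase, step, outcome) records. When the history exceeds
#' `hp$window`, only the most recent `window` records enter the solve.
#'
#' @param history data.frame with columns `x` (tested phase, radians), `t`
#'   (optimization-step index) and `y` (observed outcome delta_rho); may have
#'   zero rows (prior only).
#' @param hp a [gp_hyperparams()] object.
#' @return an object of class `tv_gp`; use [predict.tv_gp()] for posterior
#'   mean and variance at query points.
#' @examples
#' h <- data.frame(x = c(-1, 0, 1), t = 0:2, y = c(-0.2, 0.3, -0.1))
#' fit <- tv_gp(h, gp_hyperparams(kernel_kind = "forgetting", epsilon = 0.1))
#' predict(fit, x = seq(-pi, pi, length.out = 5), t = 3)
#' @export
tv_gp <- function(history, hp = gp_hyperparams()) {
  if (is.null(history)) history <- data.frame(x = numeric(), t = numeric(),
                                              y = numeric())
  stopifnot(all(c("x", "t", "y") %in% names(history)))
  n_all <- nrow(history)
  if (n_all > hp$window)
    history <- history[(n_all - hp$window + 1L):n_all, , drop = FALSE]
  n <- nrow(history)
  fit <- list(history = history, hp = hp, n = n)
  if (n > 0L) {
    K <- kernel_matrix(history$x, history$t, history$x, history$t, hp)
    R <- chol_jitter(K + diag(hp$sigma_n2, n))
    fit$chol <- R
    fit$alpha <- backsolve(R, forwardsolve(t(R), history$y))
  }
  structure(fit, class = "tv_gp")
}

#' Posterior mean and variance of the surrogate
#'
#' Exact GP posterior at query (phase, step) points:
#' mu* = K*' (K + sigma_n^2 I)^-1 y,
#' var* = K** - K*' (K + sigma_n^2 I)^-1 K*.
#' Tiny negative variances from round-off (> -1e-10) are clamped to zero.
#'
#' @param object a fitted [tv_gp()] object.
#' @param x query phases in radians.
#' @param t query step index (scalar, recycled, or vector matching `x`).
#' @param ... unused.
#' @return data.frame with columns `x`, `t`, `mu`, `var`.
#' @export
predict.tv_gp <- function(object, x, t = 0, ...) {
  if (length(x) < 1L) stop_tvbo("no query points", "tvbo_invalid_parameter")
  t <- rep_len(t, length(x))
  hp <- object$hp
  prior_var <- spatiotemporal_kernel(x, t, x, t, hp)
  if (object$n == 0L) {
    return(data.frame(x = x, t = t, mu = 0, var = prior_var))
  }
  Kq <- kernel_matrix(x, t, object$history$x, object$history$t, hp)
  mu <- drop(Kq %*% object$alpha)
  V <- forwardsolve(t(object$chol), t(Kq))
  v <- prior_var - colSums(V^2)
  if (any(v < -1e-10))
    stop_tvbo("posterior variance below numerical tolerance",
              "tvbo_numerical_conditioning")
  v[v < 0] <- 0
  data.frame(x = x, t = t, mu = mu, var = v)
}

#' @export
print.tv_gp <- function(x, ...) {
  cat(sprintf("Gaussian-process surrogate (%s kernel), %d observation%s\n",
              x$hp$kernel_kind, x$n, if (x$n == 1L) "" else "s"))
  invisible(x)
}

#' One-call GP posterior over a query set
#'
#' Convenience wrapper: fit the surrogate to `history` and evaluate the
#' posterior at `queries`.
#'
#' @inheritParams tv_gp
#' @param queries data.frame with columns `x` and `t`.
#' @return data.frame with columns `x`, `t`, `mu`, `var`.
#' @export
gp_posterior <- function(history, queries, hp = gp_hyperparams()) {
  predict(tv_gp(history, hp), x = queries$x, t = queries$t)
}
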