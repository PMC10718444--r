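# Independent brute-force GP oracle: builds every kernel entry from the
# printed covariance formulas with scalar arithmetic and inverts the Gram
# matrix explicitly with solve(). Deliberately shares no code with the
# package's Cholesky-based inference path.
oracle_posterior <- function(history, qx, qt, l_x, T_x, eps, T_t, l_tp,
                             sigma_n2, kind) {
  ks <- function(a, b) exp(-2 * sin(pi * abs(a - b) / T_x)^2 / l_x^2)
  kt <- function(a, b) {
    lag <- abs(a - b)
    if (kind == "static") 1
    else if (kind == "forgetting") (1 - eps)^(lag / 2)
    else if (kind == "periodic") exp(-2 * sin(pi * lag / T_t)^2 / l_tp^2)
    else (1 - eps)^(lag / 2) * exp(-2 * sin(pi * lag / T_t)^2 / l_tp^2)
  }
  n <- nrow(history)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    K[i, j] <- ks(history$x[i], history$x[j]) * kt(history$t[i], history$t[j])
  Kinv <- solve(K + sigma_n2 * diag(n))
  m <- length(qx)
  mu <- numeric(m); v <- numeric(m)
  for (q in seq_len(m)) {
    kq <- numeric(n)
    for (i in seq_len(n))
      kq[i] <- ks(qx[q], history$x[i]) * kt(qt[q], history$t[i])
    mu[q] <- drop(t(kq) %*% Kinv %*% history$y)
    v[q] <- ks(qx[q], qx[q]) * kt(qt[q], qt[q]) -
      drop(t(kq) %*% Kinv %*% kq)
  }
  list(mu = mu, var = v)
}

# random sample history for kernel / GP property tests
random_history <- function(n, t_max = 50) {
  data.frame(x = stats::runif(n, -pi, pi),
             t = sort(sample.int(t_max, n)),
             y = stats::rnorm(n, 0, 0.3))
}

# random hyperparameter set spanning all kernel kinds
random_hp <- function(kind = sample(c("static", "forgetting", "periodic",
                                      "forgetting_periodic"), 1)) {
  gp_hyperparams(l_x = stats::runif(1, 0.4, 2), T_x = 2 * pi,
                 epsilon = stats::runif(1, 0, 0.6),
                 T_t = stats::runif(1, 5, 60),
                 l_tp = stats::runif(1, 0.4, 2),
                 sigma_n2 = stats::runif(1, 1e-4, 0.05),
                 kernel_kind = kind)
}

# reference parameters shared by the oscillator-model tests
test_params <- function(...) kuramoto_params(...)
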