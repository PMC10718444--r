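test_that("spatial kernel matches direct evaluation and is periodic", {
  hp <- gp_hyperparams(l_x = 1, T_x = 2 * pi)
  expect_equal(spatial_kernel(0.7, 0.7, hp), 1)
  # half a period apart with unit lengthscale
  expect_equal(spatial_kernel(0, pi, hp), exp(-2), tolerance = 1e-12)
  expect_equal(spatial_kernel(0, pi, hp), 0.1353353, tolerance = 1e-6)
  # periodicity in T_x, symmetry
  xs <- seq(-pi, pi, length.out = 7)
  for (x in xs) {
    expect_equal(spatial_kernel(x + 2 * pi, 0.3, hp),
                 spatial_kernel(x, 0.3, hp), tolerance = 1e-12)
    expect_equal(spatial_kernel(x, 0.3, hp), spatial_kernel(0.3, x, hp))
  }
})

test_that("temporal kernel dispatches on kind with the printed forms", {
  for (kind in c("static", "forgetting", "periodic", "forgetting_periodic")) {
    hp <- gp_hyperparams(epsilon = 0.5, T_t = 10, l_tp = 1,
                         kernel_kind = kind)
    expect_equal(temporal_kernel(7, 7, hp), 1)
  }
  hp_f <- gp_hyperparams(epsilon = 0.5, kernel_kind = "forgetting")
  expect_equal(temporal_kernel(5, 3, hp_f), 0.5)  # (1 - 0.5)^(2/2)
  hp_p <- gp_hyperparams(T_t = 10, l_tp = 1, kernel_kind = "periodic")
  expect_equal(temporal_kernel(0, 10, hp_p), 1, tolerance = 1e-12)
  # forgetting with epsilon = 0 forgets nothing: identical to static
  hp0 <- gp_hyperparams(epsilon = 0, kernel_kind = "forgetting")
  lags <- 0:40
  expect_equal(temporal_kernel(lags, 0, hp0), rep(1, length(lags)))
})

test_that("forgetting-periodic kernel is the elementwise product form", {
  hp_fp <- gp_hyperparams(epsilon = 0.3, T_t = 17, l_tp = 0.8,
                          kernel_kind = "forgetting_periodic")
  hp_f <- gp_hyperparams(epsilon = 0.3, kernel_kind = "forgetting")
  hp_p <- gp_hyperparams(T_t = 17, l_tp = 0.8, kernel_kind = "periodic")
  tg <- expand.grid(t = 0:25, t2 = 0:25)
  expect_equal(temporal_kernel(tg$t, tg$t2, hp_fp),
               temporal_kernel(tg$t, tg$t2, hp_f) *
                 temporal_kernel(tg$t, tg$t2, hp_p),
               tolerance = 1e-12)
})

test_that("spatio-temporal kernel is the Hadamard product of its parts", {
  hp <- gp_hyperparams(epsilon = 0.5, kernel_kind = "forgetting")
  expect_equal(spatiotemporal_kernel(0.3, 4, 0.3, 4, hp), 1)
  # spatial half-period factor times forgetting factor at lag 2
  expect_equal(spatiotemporal_kernel(0, 0, pi, 2, hp),
               exp(-2) * 0.5, tolerance = 1e-12)
  expect_equal(spatiotemporal_kernel(0, 0, pi, 2, hp), 0.06766764,
               tolerance = 1e-6)
  # static reduction: equals the spatial kernel exactly
  hp_s <- gp_hyperparams(kernel_kind = "static")
  x <- stats::runif(20, -pi, pi)
  expect_identical(spatiotemporal_kernel(x, 1:20, 0.5, 0, hp_s),
                   spatial_kernel(x, 0.5, hp_s))
})

test_that("kernel values stay in (0, 1] and Gram matrices are symmetric PSD", {
  set.seed(42)
  for (rep in 1:50) {
    hp <- random_hp()
    h <- random_history(sample(3:15, 1))
    K <- outer(seq_len(nrow(h)), seq_len(nrow(h)), function(i, j)
      spatiotemporal_kernel(h$x[i], h$t[i], h$x[j], h$t[j], hp))
    expect_true(all(K > 0 & K <= 1 + 1e-12))
    expect_equal(K, t(K), tolerance = 1e-12)
    expect_gte(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values),
               -1e-10)
  }
})

test_that("half-life algebra follows the printed decay convention", {
  expect_identical(half_life_weight(100, 100), 0.5)
  expect_identical(half_life_weight(0, 100), 1)
  expect_identical(half_life_weight(200, 100), 0.25)
  expect_equal(half_life_to_epsilon(100), log(2) / 100)
  expect_equal(half_life_to_epsilon(100), 0.0069315, tolerance = 1e-5)
  # the inverse mapping: epsilon 0.22 corresponds to ~3.15-sample half-life
  expect_equal(round(log(2) / 0.22, 2), 3.15)
  expect_lt(half_life_to_epsilon(1e6), 1e-5)
  expect_error(half_life_to_epsilon(0), class = "tvbo_invalid_parameter")
})

test_that("hyperparameter validation rejects out-of-range values", {
  expect_error(gp_hyperparams(epsilon = 1), class = "tvbo_invalid_parameter")
  expect_error(gp_hyperparams(epsilon = -0.1),
               class = "tvbo_invalid_parameter")
  expect_error(gp_hyperparams(l_x = 0), class = "tvbo_invalid_parameter")
  expect_error(gp_hyperparams(sigma_n2 = -1),
               class = "tvbo_invalid_parameter")
})
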