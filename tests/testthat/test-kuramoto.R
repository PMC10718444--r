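test_that("population initialization respects the frequency specification", {
  p <- test_params()   # N = 50, f0 = 8 Hz, relative sigma 0.0075
  st <- init_population(p, seed = 1)
  expect_length(st$phases, 50)
  expect_true(all(st$phases > -pi & st$phases <= pi))
  freqs <- st$omegas / (2 * pi)
  expect_true(all(abs(freqs - 8) < 0.5))
  # clipping: every draw within f0 +/- 0.15 Hz for any seed
  for (s in 1:10) {
    f <- init_population(p, seed = s)$omegas / (2 * pi)
    expect_true(all(f >= 7.85 & f <= 8.15))
  }
  # degenerate spread: all frequencies exactly 2*pi*8
  st0 <- init_population(kuramoto_params(sigma = 0), seed = 1)
  expect_equal(st0$omegas, rep(2 * pi * 8, 50))
  # reproducibility
  expect_identical(init_population(p, seed = 9), init_population(p, seed = 9))
  expect_error(kuramoto_params(n_oscillators = 0),
               class = "tvbo_invalid_parameter")
  expect_error(kuramoto_params(dt = 0), class = "tvbo_invalid_parameter")
})

test_that("order parameter is the complex mean of unit phasors", {
  expect_equal(order_parameter(list(phases = rep(1.2, 7))),
               list(rho = 1, psi = 1.2))
  op0 <- order_parameter(list(phases = c(0, pi / 2, pi, 3 * pi / 2)))
  expect_equal(op0$rho, 0, tolerance = 1e-12)
  op2 <- order_parameter(list(phases = c(0, pi / 2)))
  expect_equal(op2$rho, sqrt(2) / 2)
  expect_equal(op2$psi, pi / 4)
  expect_error(order_parameter(list(phases = numeric())),
               class = "tvbo_invalid_state")
})

test_that("single integration step follows the coupled phase equation", {
  p <- kuramoto_params(n_oscillators = 3, gamma = 0, intensity = 0,
                       sigma = 0, dt = 1e-3)
  st <- structure(list(phases = c(0.1, -0.4, 2), omegas = c(50, 50.5, 49),
                       time_s = 0), class = "population_state")
  # uncoupled drift: theta advances by omega * dt
  st2 <- step_population(st, p)
  expect_equal(st2$phases, wrap_angle(st$phases + st$omegas * 1e-3))
  # identical oscillators in phase stay in phase under coupling
  pc <- kuramoto_params(n_oscillators = 2, gamma = 0.8, sigma = 0)
  eq <- structure(list(phases = c(0.3, 0.3), omegas = c(50, 50), time_s = 0),
                  class = "population_state")
  eq2 <- step_population(eq, pc)
  expect_equal(eq2$phases[1], eq2$phases[2])
})

test_that("mean-field and pairwise drift are the same arithmetic", {
  set.seed(21)
  p <- kuramoto_params(n_oscillators = 20)
  st <- init_population(p, seed = 21)
  for (stim in c(FALSE, TRUE)) {
    a <- step_population(st, p, prc_spec(0.4), stim_active = stim,
                         method = "meanfield")
    b <- step_population(st, p, prc_spec(0.4), stim_active = stim,
                         method = "pairwise")
    expect_equal(a$phases, b$phases, tolerance = 1e-9)
  }
  # and the compiled integrator agrees with both over many steps
  r_mf <- kuramoto_integrate_cpp(st$phases, st$omegas, p$dt, p$gamma,
                                 p$intensity, 0, 500L, FALSE, 0, 1L, 1L,
                                 FALSE, FALSE)
  r_pw <- kuramoto_integrate_cpp(st$phases, st$omegas, p$dt, p$gamma,
                                 p$intensity, 0, 500L, FALSE, 0, 1L, 1L,
                                 TRUE, FALSE)
  expect_equal(r_mf$rho, r_pw$rho, tolerance = 1e-9)
  expect_equal(r_mf$phases, r_pw$phases, tolerance = 1e-9)
})

test_that("compiled and reference single-step integrators agree", {
  p <- test_params()
  st <- init_population(p, seed = 4)
  res <- simulate_population(st, p, p$dt)
  ref <- step_population(st, p)
  expect_equal(res$state$phases, ref$phases, tolerance = 1e-12)
})

test_that("a small phase difference decays at the coupling rate", {
  # two identical oscillators: d(delta)/dt = -gamma * sin(delta) ~ -gamma*delta
  p <- kuramoto_params(n_oscillators = 2, gamma = 0.8, sigma = 0, dt = 1e-4)
  delta0 <- 0.01
  st <- structure(list(phases = c(0, delta0), omegas = c(2 * pi * 8,
                                                         2 * pi * 8),
                       time_s = 0), class = "population_state")
  out <- simulate_population(st, p, 1)
  delta1 <- abs(angle_diff(out$state$phases[2], out$state$phases[1]))
  expect_equal(delta1 / delta0, exp(-0.8), tolerance = 0.01)
})

test_that("phase wrapping does not affect the synchrony trajectory", {
  p <- kuramoto_params(n_oscillators = 10)
  st <- init_population(p, seed = 2)
  a <- st; b <- st
  for (i in 1:200) {
    a <- step_population(a, p, wrap = TRUE)
    b <- step_population(b, p, wrap = FALSE)
  }
  expect_equal(order_parameter(a)$rho, order_parameter(b)$rho,
               tolerance = 1e-9)
})

test_that("mean phase-coherence stays in [0, 1] throughout a simulation", {
  p <- test_params()
  st <- init_population(p, seed = 3)
  sim <- simulate_population(st, p, 20, psi_target = -pi,
                             prc = prc_spec(0.3))
  expect_true(all(sim$rho >= 0 & sim$rho <= 1))
})

test_that("stimulation trials produce the expected synchrony changes", {
  p <- test_params()
  proto <- scaled_protocol()
  st <- burn_in(init_population(p, seed = 1), p, 100)
  # stimulation at the mean-phase antipode desynchronizes ...
  tr_de <- run_stimulation_trial(st, p, prc_spec(0), proto, -pi)
  expect_lt(tr_de$delta_rho, 0)
  expect_gt(tr_de$n_pulses, 0)
  # ... while stimulation at the attracting phase increases synchrony
  tr_sy <- run_stimulation_trial(st, p, prc_spec(0), proto, 0)
  expect_gt(tr_sy$delta_rho, 0)
  expect_true(tr_de$rho_baseline > 0 && tr_de$rho_baseline <= 1)
  # trial advances the state by the full protocol duration
  expect_equal(tr_de$state$time_s - st$time_s, proto$step_duration_s)
})

test_that("zero-intensity stimulation stays within the fluctuation floor", {
  p0 <- kuramoto_params(intensity = 0)
  proto <- scaled_protocol()
  st <- burn_in(init_population(p0, seed = 1), p0, 100)
  # fluctuation floor from unstimulated variability of the same windows
  floor_dr <- numeric(4)
  s <- st
  for (i in 1:4) {
    tr <- run_stimulation_trial(s, p0, prc_spec(0), proto, 0.5)
    floor_dr[i] <- tr$delta_rho
    s <- tr$state
  }
  expect_lt(max(abs(floor_dr)), 0.1)
})

test_that("a fully desynchronized symmetric state has no usable baseline", {
  p <- kuramoto_params(n_oscillators = 2, sigma = 0)
  st <- structure(list(phases = c(0, pi), omegas = rep(2 * pi * 8, 2),
                       time_s = 0), class = "population_state")
  expect_error(
    run_stimulation_trial(st, p, prc_spec(0), scaled_protocol(), 0),
    class = "tvbo_degenerate_baseline")
})

test_that("halving the integration step barely changes a trial outcome", {
  for (s in 1:2) {
    dr <- vapply(c(1e-3, 5e-4), function(dt) {
      p <- kuramoto_params(dt = dt)
      st <- burn_in(init_population(p, seed = s), p, 20)
      run_stimulation_trial(st, p, prc_spec(0), scaled_protocol(),
                            -pi)$delta_rho
    }, numeric(1))
    expect_lt(abs(dr[1] - dr[2]), 1e-2)
  }
})

test_that("protocol validation enforces window consistency", {
  expect_error(stim_protocol(step_duration_s = 10, stim_window_s = 6,
                             baseline_window_s = 5),
               class = "tvbo_invalid_parameter")
  expect_error(arc_scan(phase_grid = numeric()),
               class = "tvbo_invalid_parameter")
})
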