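test_that("a stationary objective is locked in under the static kernel", {
  d <- make_drift("none", n_steps = 80)
  run <- run_bayesopt(toy_objective(d), d, hp = gp_hyperparams(),
                      n_steps = 80, f_true = -1, seed = 1)
  tr <- run$trace
  late <- tr$step > 60
  spacing <- 2 * pi / 360
  frac <- mean(abs(angle_diff(tr$psi_target[late], -pi)) <= spacing + 1e-9)
  expect_gt(frac, 0.8)
  # late regret is essentially zero
  expect_lt(max(abs(tr$regret[late])), 0.05)
  expect_equal(run$mode, "static")
})

test_that("the trace records burn-in, sample ages, and the drifting optimum", {
  d <- make_drift("gradual", n_steps = 40)
  run <- run_bayesopt(toy_objective(d), d, n_steps = 40, n_init = 12,
                      f_true = -1, seed = 2)
  tr <- run$trace
  expect_equal(nrow(tr), 40)
  expect_equal(tr$t, 0:39)
  expect_equal(tr$psi_target[1:12], burn_in_schedule(12))
  expect_equal(tr$psi_true, true_optimum(d$offsets[1:40]))
  expect_equal(tr$cum_regret, cumsum(tr$regret) / seq_len(40))
})

test_that("time-varying mode degrades gracefully to the static controller", {
  d <- make_drift("gradual", n_steps = 60)
  base <- run_bayesopt(toy_objective(d), d,
                       hp = gp_hyperparams(kernel_kind = "static"),
                       n_steps = 60, f_true = -1, seed = 5)
  degr <- run_bayesopt(toy_objective(d), d,
                       hp = gp_hyperparams(kernel_kind = "forgetting",
                                           epsilon = 0),
                       n_steps = 60, f_true = -1, seed = 5)
  expect_equal(degr$trace$psi_target, base$trace$psi_target)
  expect_equal(degr$trace$y, base$trace$y)
})

test_that("forgetting-periodic surrogate tracks a known sinusoidal drift", {
  d <- make_drift("periodic", n_steps = 300, period_steps = 100)
  run <- run_bayesopt(toy_objective(d, noise_std_y = 0.05, seed = 3), d,
                      hp = gp_hyperparams(kernel_kind = "forgetting_periodic",
                                          epsilon = 0.05, T_t = 100),
                      n_steps = 300, f_true = -1, seed = 3)
  tr <- run$trace
  lock <- tr$step > 100   # after one full drift period
  err <- abs(angle_diff(tr$psi_target[lock], tr$psi_true[lock]))
  expect_lt(mean(err), pi / 6)
})

test_that("time-varying kernels beat the static surrogate under drift", {
  d <- make_drift("gradual", n_steps = 200)
  tv <- run_bayesopt(toy_objective(d, noise_std_y = 0.05, seed = 6), d,
                     hp = gp_hyperparams(kernel_kind = "forgetting",
                                         epsilon = 0.22),
                     n_steps = 200, f_true = -1, seed = 6)
  st <- run_bayesopt(toy_objective(d, noise_std_y = 0.05, seed = 6), d,
                     hp = gp_hyperparams(kernel_kind = "static"),
                     n_steps = 200, f_true = -1, seed = 6)
  expect_lt(tv$regret$auc_mag, st$regret$auc_mag)
})

test_that("identical configuration and seed reproduce the trace exactly", {
  cfg <- tvbo_config(backend = "toy", n_steps = 60, seed = 11,
                     scenario = list(kind = "periodic", period_steps = 30),
                     gp = list(kernel_kind = "forgetting_periodic",
                               epsilon = 0.1, T_t = 30),
                     toy = list(amplitude = 1, noise_std_y = 0.1))
  a <- run_from_config(cfg)
  b <- run_from_config(cfg)
  expect_identical(a$trace, b$trace)
})

test_that("the scheduler replays its schedule and an oracle schedule wins", {
  d <- make_drift("periodic", n_steps = 90, period_steps = 30)
  sched <- oracle_schedule(30)
  run <- run_scheduler(toy_objective(d), d, sched, f_true = -1)
  tr <- run$trace
  expect_equal(tr$psi_target, sched[(0:89) %% 30 + 1])
  # anticipated period equals the true period: essentially zero regret
  expect_lt(max(abs(tr$regret)), 1e-6)
  expect_equal(run$mode, "scheduler")
  # a mismatched anticipated period accumulates regret
  mis <- run_scheduler(toy_objective(d), d, oracle_schedule(40), f_true = -1)
  expect_gt(mis$regret$auc_mag, run$regret$auc_mag)
})

test_that("controller input validation catches degenerate requests", {
  d <- make_drift("none", n_steps = 5)
  expect_error(run_bayesopt(toy_objective(d), d, n_steps = 10),
               class = "tvbo_invalid_parameter")
  expect_error(run_scheduler(toy_objective(d), d, numeric()),
               class = "tvbo_invalid_parameter")
  expect_error(run_bayesopt(toy_objective(d), d, n_steps = 5,
                            f_true = "probe"),
               class = "tvbo_invalid_parameter")
})
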