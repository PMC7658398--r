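test_that("unforced pendulum below threshold freezes at the stall time", {
  p <- gait_params()
  thr <- unforced_freeze_threshold(0.1, p)
  om0 <- -0.9 * thr
  sim <- simulate_gait(p, "pendulum", x0 = om0, t_max = 5, dt = 0.001)
  expect_true(sim$froze)
  expect_identical(sim$n_steps, 0L)
  expect_equal(sim$t_freeze, unforced_stall_time(0.1, om0, p),
               tolerance = 1e-6)
  # detect_freeze on the recorded trajectory agrees
  df <- detect_freeze(sim$trajectory, p)
  expect_true(df$froze)
  expect_equal(df$t_freeze, sim$t_freeze, tolerance = 1e-4)
})

test_that("conservative unforced walking recurs indefinitely with constant speed", {
  p <- gait_params(theta_h = 0)   # no collision dissipation
  sim <- simulate_gait(p, "pendulum", x0 = -0.6, t_max = 10, dt = 0.01)
  expect_false(sim$froze)
  hs <- sim$steps[sim$steps$ended_by == "heel_strike", ]
  expect_gt(nrow(hs), 5)
  expect_lt(max(abs(abs(hs$omega_end) - 0.6)), 1e-7)
  # and all stance durations equal the closed-form reset time
  expect_equal(hs$t_end - hs$t_start,
               rep(unforced_reset_time(0.1, -0.6, p), nrow(hs)),
               tolerance = 1e-7)
})

test_that("unforced stance conserves energy and descends monotonically", {
  p <- gait_params()
  sim <- simulate_gait(p, "pendulum", x0 = -0.6, t_max = 2, dt = 0.001)
  st <- sim$trajectory[sim$trajectory$step_index == 0, ]
  E <- st$omega^2 - (p$g / p$l) * st$theta^2
  expect_lt(max(abs(E - E[1])), 1e-9)
  expect_true(all(diff(st$theta) < 0))
})

test_that("unforced stance flow is time-reversible", {
  p <- gait_params()
  x0 <- pendulum_state(0.1, -0.6)
  d_fwd <- function(t, y, parms) list(pendulum_field(0, y, p))
  d_bwd <- function(t, y, parms) list(-pendulum_field(0, y, p))
  T_end <- 0.3
  fwd <- deSolve::lsoda(x0, c(0, T_end), d_fwd, NULL, rtol = 1e-11, atol = 1e-13)
  y1 <- fwd[nrow(fwd), c("theta", "omega")]
  bwd <- deSolve::lsoda(y1, c(0, T_end), d_bwd, NULL, rtol = 1e-11, atol = 1e-13)
  expect_equal(unname(bwd[nrow(bwd), c("theta", "omega")]), unname(unclass(x0)),
               tolerance = 1e-8)
})

test_that("dissipative unforced walking freezes after the geometric step count", {
  p <- gait_params(theta_h = 0.2)
  n_star <- unforced_freeze_step_count(0.1, -0.6, p)   # 20
  sim <- simulate_gait(p, "pendulum", x0 = -0.6, t_max = 30, dt = 0.01)
  expect_true(sim$froze)
  expect_identical(sim$n_steps, as.integer(n_star))
  # walk_time_before_freeze reports the last heel strike
  wt <- walk_time_before_freeze(p, "pendulum", x0 = -0.6, window = 30, dt = 0.01)
  expect_equal(wt, sim$t_last_heel_strike)
  # below threshold: no heel strike, zero walk time
  expect_equal(walk_time_before_freeze(p, "pendulum", x0 = -0.2, window = 5,
                                       dt = 0.01), 0)
})

test_that("non-freezing runs report the full window", {
  p <- gait_params(theta_h = 0)
  expect_equal(walk_time_before_freeze(p, "pendulum", x0 = -0.8, window = 4,
                                       dt = 0.01), 4)
})

test_that("the biped walks then freezes under the published demonstration setup", {
  fx <- gait_fixture("fig5")
  sim <- simulate_gait(set_inertia(fx$params, calibrated_inertia), "biped",
                       fx$x0, t_max = 10, dt = 0.01)
  expect_true(sim$froze)
  expect_gte(sim$n_steps, 3L)          # several heel strikes before the freeze
  expect_lte(sim$t_freeze, 10)
  # step lengths (successive |theta1| at heel strike) shrink towards the freeze
  hs <- sim$steps[sim$steps$ended_by == "heel_strike", ]
  lens <- abs(hs$theta1_end)
  expect_lt(lens[length(lens)], lens[1])
})

test_that("per-step forcing clock restarts at each heel strike", {
  p <- set_inertia(gait_params(tau_l = 2, tau_r = 11, phi = -pi / 2), 25)
  sim <- simulate_gait(p, "pendulum", x0 = -1, t_max = 3, dt = 0.01)
  tb <- sim$trajectory
  for (s in unique(tb$step_index)) {
    expect_lt(min(tb$phase_time[tb$step_index == s]), 0.011)
  }
  # trajectory is continuous within steps and jumps only at resets
  within_jumps <- tapply(tb$theta, tb$step_index,
                         function(v) max(abs(diff(v))))
  expect_true(all(within_jumps < 0.05))
})

test_that("global-clock mode changes the dynamics after the first step", {
  p_step <- set_inertia(gait_params(tau_l = 2, tau_r = 11, phi = -pi / 2), 25)
  p_glob <- modify_params(p_step, clock = "global")
  s1 <- simulate_gait(p_step, "pendulum", x0 = -1, t_max = 4, dt = 0.01)
  s2 <- simulate_gait(p_glob, "pendulum", x0 = -1, t_max = 4, dt = 0.01)
  # first stance phase identical (clock origin coincides)...
  expect_equal(s1$steps$t_end[1], s2$steps$t_end[1], tolerance = 1e-9)
  # ...later phases differ
  expect_false(isTRUE(all.equal(s1$steps$t_end[3], s2$steps$t_end[3],
                                tolerance = 1e-6)))
})
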