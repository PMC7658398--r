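test_that("unforced reset time matches the quadratic-in-exp closed form", {
  p <- gait_params()
  for (om in c(-0.45, -0.6, -1, -2)) {
    expect_equal(reset_time(om, p), unforced_reset_time(0.1, om, p),
                 tolerance = 1e-10)
  }
  # below the energy threshold the map freezes
  expect_true(is.na(reset_time(-0.3, p)))
  expect_true(is.na(omega_map(-0.3, p)))
})

test_that("reset time satisfies its defining property under forcing", {
  set.seed(31)
  for (i in 1:20) {
    p <- random_forced_params()
    om <- stats::runif(1, -1.2, -0.45)
    tr <- reset_time(om, p)
    if (is.na(tr)) next
    expect_lt(abs(flow_theta(tr, abs(p$theta_reset), om, p) - p$theta_reset),
              1e-10)
  }
})

test_that("unforced map is multiplication by cos(theta_h)", {
  p0 <- gait_params(theta_h = 0)
  p2 <- gait_params(theta_h = 0.2)
  grid <- seq(-2, -0.42, length.out = 100)
  expect_lt(max(abs(omega_map(grid, p0) - grid)), 1e-9)       # identity
  expect_lt(max(abs(omega_map(grid, p2) - grid * cos(0.2))), 1e-9)
  # compositions of the linear map, and its derivative
  expect_equal(composed_map(-0.9, 3, p2), -0.9 * cos(0.2)^3,
               tolerance = 1e-8)
  expect_equal(map_derivative(-0.9, 1, p2), cos(0.2), tolerance = 1e-5)
})

test_that("freezing is monotone in speed for the unforced map", {
  p <- gait_params(theta_h = 0.2)
  grid <- seq(-1.5, -0.05, length.out = 120)
  frozen <- is.na(omega_map(grid, p))
  # frozen set is an upper tail in omega (low |omega|)
  expect_true(all(diff(frozen) >= 0))
})

test_that("map iteration reproduces full hybrid simulation step by step", {
  set.seed(33)
  n_checked <- 0
  for (i in 1:20) {
    p <- random_forced_params()
    om0 <- stats::runif(1, -1.2, -0.5)
    sim <- simulate_gait(p, "pendulum", x0 = om0, t_max = 8, dt = 0.01)
    ends <- sim$steps$omega_end[sim$steps$ended_by == "heel_strike"] *
      cos(p$theta_h)
    n <- min(length(ends), 10L)
    if (n == 0) next
    it <- iterate_map(om0, n, p)
    expect_identical(length(it), length(ends[seq_len(n)]))
    expect_lt(max(abs(it - ends[seq_len(n)])), 1e-7)
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 10)
})

test_that("iteration truncates at the freeze and counts the geometric decay", {
  p <- gait_params(theta_h = 0.2)
  seq_it <- iterate_map(-0.6, 40, p)
  expect_identical(length(seq_it), as.integer(unforced_freeze_step_count(0.1, -0.6, p)))
  expect_equal(seq_it, -0.6 * cos(0.2)^seq_along(seq_it), tolerance = 1e-8)
})

test_that("no non-freezing fixed point exists without forcing", {
  p <- gait_params(theta_h = 0.2)
  orb <- find_periodic_orbits(p, 1, c(-2, -0.1), n_scan = 500)
  expect_identical(nrow(orb), 0L)
})

test_that("fixed points are reproduced and the high-speed attractor is stable", {
  p <- set_inertia(gait_params(tau_l = 5, tau_r = 35, phi = -1.57),
                   calibrated_inertia)
  orb <- find_periodic_orbits(p, 1, c(-3, -0.1), n_scan = 800)
  expect_gt(nrow(orb), 0)
  for (i in seq_len(nrow(orb))) {
    expect_equal(omega_map(orb$omega[i], p), orb$omega[i], tolerance = 1e-8)
  }
  # the large-|omega| walking attractor exists and is stable
  hi <- orb[which.min(orb$omega), ]
  expect_lt(abs(hi$multiplier), 1)
  expect_true(hi$stable)
  # fixed-point input reproduces itself under iteration
  it <- iterate_map(hi$omega, 5, p)
  expect_lt(max(abs(it - hi$omega)), 1e-6)
})

test_that("periodic orbits verify cyclic mapping and the chain-rule multiplier", {
  p <- set_inertia(gait_params(tau_l = 5, tau_r = 35, phi = -1.2),
                   calibrated_inertia)
  for (per in c(2L, 3L)) {
    orb <- find_periodic_orbits(p, per, c(-0.6, -0.2), n_scan = 600)
    if (!nrow(orb)) next
    for (i in seq_len(nrow(orb))) {
      pts <- orb$points[[i]]
      expect_identical(length(pts), as.integer(per))
      # cyclic closure
      expect_lt(abs(omega_map(pts[per], p) - pts[1]), 1e-8)
      # multiplier equals the product of pointwise derivatives
      chain <- prod(map_derivative(pts, 1, p))
      expect_equal(orb$multiplier[i], chain, tolerance = 1e-4)
    }
  }
})

test_that("map tables flag frozen inputs and feed the plot helpers", {
  p <- gait_params(theta_h = 0.2)
  tb <- map_table(seq(-0.8, -0.2, by = 0.1), p)
  expect_named(tb, c("omega_in", "omega_out", "reset_time", "frozen"))
  expect_true(any(tb$frozen))
  expect_true(all(is.na(tb$omega_out[tb$frozen])))
  gg <- plot_stride_map(p, seq(-0.9, -0.45, by = 0.05), periods = 1:2)
  expect_s3_class(gg, "ggplot")
})
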