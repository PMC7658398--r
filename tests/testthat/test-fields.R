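test_that("unforced biped field vanishes at the upright fixed point", {
  p <- gait_params(m1 = 1, m2 = 0.3)
  expect_equal(unname(biped_field(biped_state(0, 0, 0, 0), p)),
               rep(0, 4))
})

test_that("unforced biped field matches the Lagrangian oracle", {
  set.seed(11)
  for (i in 1:100) {
    p <- gait_params(m1 = stats::runif(1, 0.5, 80),
                     m2 = stats::runif(1, 0.01, 10),
                     l = stats::runif(1, 0.4, 1.1))
    x <- biped_state(stats::runif(1, -0.6, 0.6), stats::runif(1, -0.6, 0.6),
                     stats::runif(1, -2, 2), stats::runif(1, -2, 2))
    f <- biped_field(x, p)
    o <- lagrangian_biped_accel(x, p)
    expect_equal(f[["omega1"]], o[["omega1"]], tolerance = 1e-10)
    expect_equal(f[["omega2"]], o[["omega2"]], tolerance = 1e-10)
    expect_equal(f[["theta1"]], x[["omega1"]])
    expect_equal(f[["theta2"]], x[["omega2"]])
  }
})

test_that("massless swing leg reduces the stance row to the pendulum", {
  set.seed(3)
  for (i in 1:20) {
    p <- gait_params(m1 = stats::runif(1, 1, 80), m2 = 0)
    x <- biped_state(stats::runif(1, -0.5, 0.5), stats::runif(1, -0.5, 0.5),
                     stats::runif(1, -2, 2), stats::runif(1, -2, 2))
    expect_equal(biped_field(x, p)[["omega1"]],
                 p$g * sin(x[["theta1"]]) / p$l, tolerance = 1e-12)
  }
})

test_that("small-angle limit of the full field matches the linearised one", {
  # m2 -> 0 and |angles| small: full nonlinear field approaches the
  # unforced linearised field to first order
  p <- gait_params(m1 = 70, m2 = 1e-8)
  for (th in c(-0.05, -0.01, 0.02, 0.05)) {
    x <- biped_state(th, -th / 2, -0.3, 0.4)
    full <- biped_field(x, p)
    lin <- biped_field_forced(0, x, p)   # tau = 0: unforced linear field
    expect_equal(full[["omega1"]], lin[["omega1"]], tolerance = 5e-4)
    expect_equal(full[["omega2"]], lin[["omega2"]], tolerance = 5e-3)
  }
})

test_that("forced biped field implements the linearised stance dynamics", {
  p0 <- gait_params()   # unforced
  x <- biped_state(0.12, 0, 0, 0)
  expect_equal(unname(biped_field_forced(0.3, x, p0)),
               c(0, 0, p0$g * 0.12 / p0$l, 0))
  # swing acceleration vanishes on the centrifugal balance omega1^2 = g/l
  xb <- biped_state(0.05, 0.3, -sqrt(p0$g / p0$l), 0.7)
  expect_equal(biped_field_forced(1.1, xb, p0)[["omega2"]], 0,
               tolerance = 1e-12)
  # the printed magnitude check: l * omega1^2 = 0.7 * 0.8^2 = 0.448
  p7 <- gait_params(l = 0.7)
  x7 <- biped_state(0, 1, 0.8, 0)
  lw2 <- p7$g + p7$l * biped_field_forced(0, x7, p7)[["omega2"]] / x7[["theta2"]]
  expect_equal(lw2, 0.448, tolerance = 1e-12)
})

test_that("pendulum field agrees with the stance rows of the biped field", {
  set.seed(5)
  p <- random_forced_params()
  for (i in 1:10) {
    th <- stats::runif(1, -0.2, 0.2); om <- stats::runif(1, -1, 0)
    tt <- stats::runif(1, 0, 2)
    fp <- pendulum_field(tt, pendulum_state(th, om), p)
    fb <- biped_field_forced(tt, biped_state(th, 0, om, 0), p)
    expect_equal(fp[["theta"]], fb[["theta1"]])
    expect_equal(fp[["omega"]], fb[["omega1"]])
  }
  # unforced field is odd
  p0 <- gait_params()
  f1 <- pendulum_field(0, pendulum_state(0.1, -0.4), p0)
  f2 <- pendulum_field(0, pendulum_state(-0.1, 0.4), p0)
  expect_equal(unname(f1), -unname(f2))
})

test_that("heel-strike resets negate angles and dissipate speed", {
  p <- gait_params(theta_h = 0.2, omega20 = 2)
  xb <- biped_state(-0.1, 0.1, -0.6, 2)
  rb <- biped_reset(xb, p)
  expect_equal(unname(rb), c(0.1, -0.1, -0.6 * cos(0.2), 2))
  # theta_h = 0: no dissipation
  r0 <- biped_reset(xb, modify_params(p, theta_h = 0))
  expect_equal(r0[["omega1"]], -0.6)
  # pendulum
  rp <- pendulum_reset(pendulum_state(-0.1, -0.5), p)
  expect_equal(unname(rp), c(0.1, -0.5 * cos(0.2)))
  rp0 <- pendulum_reset(pendulum_state(-0.1, -0.5), modify_params(p, theta_h = 0))
  expect_equal(unname(rp0), c(0.1, -0.5))
  # dissipativity and antisymmetry across random pre-collision states
  set.seed(9)
  for (i in 1:20) {
    th <- stats::runif(1, 0.01, 0.45)
    om <- stats::runif(1, -2, 2)
    hip <- stats::runif(1, 0, 1.2)
    pp <- gait_params(theta_reset = -th, theta_h = hip)
    r <- pendulum_reset(pendulum_state(-th, om), pp)
    expect_identical(r[["theta"]], th)
    expect_lte(abs(r[["omega"]]), abs(om))
    if (hip == 0) expect_equal(abs(r[["omega"]]), abs(om))
  }
})

test_that("resets refuse states off the guard surface", {
  p <- gait_params()
  expect_error(pendulum_reset(pendulum_state(-0.05, -0.5), p), "guard")
  expect_error(biped_reset(biped_state(-0.1, 0.2, -0.5, 1), p), "guard")
  expect_error(biped_reset(biped_state(0.1, -0.1, -0.5, 1), p), "guard")
})
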