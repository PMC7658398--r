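test_that("Feigenbaum estimator recovers the logistic accumulation point", {
  logistic_period <- function(r) {
    x <- 0.5
    for (i in 1:1900) x <- r * x * (1 - x)
    kept <- numeric(100)
    for (i in 1:100) {
      x <- r * x * (1 - x)
      kept[i] <- x
    }
    for (p in 1:64) {
      if (max(abs(utils::head(kept, -p) - utils::tail(kept, -p))) < 1e-5) {
        return(p)
      }
    }
    -1L
  }
  est <- feigenbaum_estimate(logistic_period, c(2.9, 3.58))
  expect_gte(length(est$onsets), 3)
  expect_lt(abs(est$accumulation - 3.5699), 1e-2)
})

test_that("a window without doublings raises the no-cascade error", {
  flat_period <- function(x) 1L
  expect_error(feigenbaum_estimate(flat_period, c(0, 1)), "cascade")
  dead_period <- function(x) 0L
  expect_error(feigenbaum_estimate(dead_period, c(0, 1)), "periodic attractor")
})

test_that("unforced sweeps end in freezing everywhere", {
  p <- gait_params()
  bd <- bifurcation_diagram(p, "theta_h", seq(0.05, 0.3, by = 0.05), -0.6,
                            n_total = 500, n_keep = 50)
  expect_true(all(bd$summary$label == "freeze"))
})

test_that("the diagram classifies periodic windows of the stride map", {
  p <- set_inertia(gait_params(tau_l = 5, tau_r = 35), calibrated_inertia)
  # straddle the first doubling onsets (1->2 near -0.81, 2->4 near -1.24)
  bd <- bifurcation_diagram(p, "phi", c(-1.3, -1.0, -0.7), -0.433,
                            n_total = 400, n_keep = 40)
  expect_identical(bd$summary$period[bd$summary$param_value == -0.7], 1L)
  expect_identical(bd$summary$period[bd$summary$param_value == -1.0], 2L)
  expect_identical(bd$summary$period[bd$summary$param_value == -1.3], 4L)
  tb <- tidy(bd)
  expect_true(all(c("param_value", "omega", "label") %in% names(tb)))
  expect_s3_class(autoplot(bd), "ggplot")
  g <- glance(bd)
  expect_identical(g$n_grid, 3L)
})

test_that("period classification is invariant to doubling the iteration budget", {
  p <- set_inertia(gait_params(tau_l = 5, tau_r = 35), calibrated_inertia)
  phis <- c(-1.6, -1.3, -1.1, -0.9)
  b1 <- bifurcation_diagram(p, "phi", phis, -0.433, n_total = 500, n_keep = 50)
  b2 <- bifurcation_diagram(p, "phi", phis, -0.433, n_total = 1000, n_keep = 50)
  chaotic <- b1$summary$label %in% c("chaotic", "aperiodic")
  expect_identical(b1$summary$period[!chaotic], b2$summary$period[!chaotic])
})

test_that("walk-time heatmaps are deterministic and ordered by push-off", {
  p <- set_inertia(gait_params(phi = -pi / 2), calibrated_inertia)
  grid_l <- c(0, 2); grid_r <- c(0, 20, 40)
  h1 <- freeze_time_heatmap(p, "pendulum", grid_l, grid_r, x0 = -0.6,
                            window = 4, dt = 0.02)
  h2 <- freeze_time_heatmap(p, "pendulum", grid_l, grid_r, x0 = -0.6,
                            window = 4, dt = 0.02)
  expect_identical(h1, h2)                 # no randomness anywhere
  expect_s3_class(autoplot(h1), "ggplot")
  # zero push-off with opposing torque: freezes inside the window
  expect_lt(h1$walk_time[h1$tau_l == 2 & h1$tau_r == 0], 4)
  # walk time non-decreasing in tau_r along each tau_l row on this grid
  for (tl in grid_l) {
    row <- h1$walk_time[h1$tau_l == tl][order(grid_r)]
    expect_true(all(diff(row) >= -1e-9))
  }
})

test_that("fixed-point contours track orbit creation across the plane", {
  p <- set_inertia(gait_params(phi = -1.57), calibrated_inertia)
  fp <- fixed_point_contour(p, "tau_l", "tau_r", c(0, 5), c(35, 55),
                            period = 1, omega_range = c(-0.5, -0.2),
                            n_scan = 200)
  # low-speed period-1 orbits exist at high tau_l / low tau_r only
  expect_true(nrow(fp[fp$x == 5 & fp$y == 35, ]) > 0)
  expect_identical(nrow(fp[fp$x == 0 & fp$y == 35, ]), 0L)
  expect_identical(nrow(fp[fp$x == 5 & fp$y == 55, ]), 0L)
})

test_that("degenerate calibration ranges return the single candidate", {
  p <- set_inertia(gait_params(tau_l = 2, tau_r = 11, phi = -pi / 2), 1)
  cal <- calibration_sweep(p, "freeze_time", reference = 18,
                           inertia_grid = 36, l_grid = 0.5, omega0 = -1)
  expect_identical(nrow(cal), 1L)
  best <- attr(cal, "best")
  expect_equal(best$inertia, 36)
  expect_equal(best$l, 0.5)
  # the residual is reported, never hidden
  expect_true(is.finite(best$residual))
  expect_equal(best$residual, abs(best$value - 18))
})
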