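#' Stance-phase speed gain by shooting
#'
#' Solves the two-point boundary-value problem of the stance flow: find the
#' initial angular velocity `omega(0)` such that the stance angle moves from
#' `theta_start` at `t = 0` to `theta_end` at `t = t_end`, and report the
#' speed gain `|omega(0)| - |omega(t_end)|` — the net kinetic-energy effect
#' of gravity and the two plantar-flexor inputs over the step. A negative
#' gain means the step ends faster than it began.
#'
#' For the pendulum the flow is linear in the state, so `theta(t_end)` is
#' affine in `omega(0)` and two evaluations of the analytic flow determine
#' the solution exactly (a single secant step). For the biped the boundary
#' condition is solved by iterative secant shooting on numerically
#' integrated trajectories.
#'
#' No heel strike may occur inside the window: trajectories that reach the
#' reset angle before `t_end` are flagged (`converged = FALSE`) rather than
#' silently continued through a collision.
#'
#' @param p A [gait_params()] object.
#' @param model `"pendulum"` or `"biped"`.
#' @param theta_start,theta_end Boundary angles (rad).
#' @param t_end Window length (s).
#' @param extra_ics For the biped, named numeric with the swing-leg initial
#'   conditions `theta2`, `omega2`.
#' @param max_iter Maximum secant iterations (biped).
#' @param tol Boundary-residual tolerance (rad).
#' @return A one-row tibble: `omega_start`, `omega_end`, `gain`,
#'   `residual`, `converged`.
#' @examples
#' solve_speed_gain(gait_params())   # unforced: gravity speeds the leg up
#' @export
solve_speed_gain <- function(p, model = c("pendulum", "biped"),
                             theta_start = 0, theta_end = -0.1, t_end = 0.5,
                             extra_ics = c(theta2 = -0.1, omega2 = 1),
                             max_iter = 100L, tol = 1e-8) {
  model <- match.arg(model)
  stopifnot(t_end > 0)
  if (model == "pendulum") {
    # theta(t_end) = alpha + beta * omega0: two flow evaluations solve it
    th0 <- flow_theta(t_end, theta_start, 0, p)
    th1 <- flow_theta(t_end, theta_start, 1, p)
    beta <- th1 - th0
    omega0 <- (theta_end - th0) / beta
    omega_end <- flow_omega(t_end, theta_start, omega0, p)
    resid <- abs(flow_theta(t_end, theta_start, omega0, p) - theta_end)
    ok <- resid <= tol && no_reset_inside(theta_start, omega0, p, t_end)
    return(tibble::tibble(omega_start = omega0, omega_end = omega_end,
                          gain = abs(omega0) - abs(omega_end),
                          residual = resid, converged = ok))
  }
  shoot <- function(omega0) {
    x0 <- biped_state(theta_start, extra_ics[["theta2"]], omega0,
                      extra_ics[["omega2"]])
    d <- function(t, y, parms) list(biped_field_forced(t, y, p))
    out <- deSolve::lsoda(y = x0, times = c(0, t_end), func = d,
                          parms = NULL, rtol = 1e-10, atol = 1e-12)
    as.numeric(out[nrow(out), -1])
  }
  om_a <- -1; om_b <- 0
  fa <- shoot(om_a)[1] - theta_end
  fb <- shoot(om_b)[1] - theta_end
  omega0 <- om_b; fcur <- fb
  for (i in seq_len(max_iter)) {
    if (abs(fcur) <= tol) break
    if (fb == fa) break
    om_new <- om_b - fb * (om_b - om_a) / (fb - fa)
    om_a <- om_b; fa <- fb
    om_b <- om_new; fb <- shoot(om_b)[1] - theta_end
    omega0 <- om_b; fcur <- fb
  }
  yend <- shoot(omega0)
  resid <- abs(yend[1] - theta_end)
  tibble::tibble(omega_start = omega0, omega_end = yend[3],
                 gain = abs(omega0) - abs(yend[3]),
                 residual = resid, converged = resid <= tol)
}

# TRUE when the pendulum BVP trajectory stays above the reset angle on
# [0, t_end) (sampled finely; the flow has at most a few extrema there)
no_reset_inside <- function(theta_start, omega0, p, t_end) {
  tg <- seq(0, t_end, length.out = 201)[-201]
  all(flow_theta(tg, theta_start, omega0, p) > p$theta_reset - 1e-12)
}

#' Speed-gain contour over the forcing amplitudes
#'
#' [solve_speed_gain()] on every cell of a `tau_l` x `tau_r` grid.
#' Nonconvergent cells are kept with `converged = FALSE`, never
#' interpolated.
#'
#' @inheritParams solve_speed_gain
#' @param tau_l_grid,tau_r_grid Amplitude grids (N m / N).
#' @return A tibble: `tau_l`, `tau_r`, `gain`, `converged`.
#' @export
speed_gain_contour <- function(p, model = c("pendulum", "biped"),
                               tau_l_grid, tau_r_grid, ...) {
  model <- match.arg(model)
  cells <- expand.grid(tau_l = tau_l_grid, tau_r = tau_r_grid)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    pi_ <- modify_params(p, tau_l = cells$tau_l[i], tau_r = cells$tau_r[i])
    sg <- solve_speed_gain(pi_, model, ...)
    tibble::tibble(tau_l = cells$tau_l[i], tau_r = cells$tau_r[i],
                   gain = sg$gain, converged = sg$converged)
  })
  dplyr::bind_rows(rows)
}
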