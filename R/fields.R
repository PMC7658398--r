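#' State constructors
#'
#' Light named-vector states for the two models. The biped state is
#' `[theta1, theta2, omega1, omega2]`: stance angle from the vertical,
#' swing angle, and the two angular rates. The pendulum state is
#' `[theta, omega]` for the stance leg alone. Counterclockwise angles are
#' positive and forward walking has negative angular velocity.
#'
#' @param theta1,theta2,omega1,omega2,theta,omega Components (rad, rad s^-1).
#' @return A named numeric vector.
#' @examples
#' biped_state(0.1, -0.1, -0.6, 2)
#' pendulum_state(0.1, -0.6)
#' @name states
NULL

#' @rdname states
#' @export
biped_state <- function(theta1, theta2, omega1, omega2) {
  x <- c(theta1 = theta1, theta2 = theta2, omega1 = omega1, omega2 = omega2)
  stopifnot("biped state must be finite" = all(is.finite(x)))
  x
}

#' @rdname states
#' @export
pendulum_state <- function(theta, omega) {
  x <- c(theta = theta, omega = omega)
  stopifnot("pendulum state must be finite" = all(is.finite(x)))
  x
}

#' Unforced biped vector field (full nonlinear)
#'
#' Time derivative of the biped state for the passive two-link walker:
#' point masses `m1` at the hip and `m2` at the swing foot on massless rigid
#' legs of length `l`, no muscle forcing. The swing angle `theta2` is
#' measured relative to the stance leg while `omega2` is the absolute spin
#' rate of the swing leg.
#'
#' @param x A [biped_state()].
#' @param p A [gait_params()] object.
#' @return Named derivative vector `c(theta1, theta2, omega1, omega2)`.
#' @examples
#' p <- gait_params(m1 = 1, m2 = 0.2)
#' biped_field(biped_state(0.1, -0.1, -0.6, 2), p)
#' @export
biped_field <- function(x, p) {
  th1 <- x[["theta1"]]; th2 <- x[["theta2"]]
  w1 <- x[["omega1"]]; w2 <- x[["omega2"]]
  m1 <- p$m1; m2 <- p$m2; l <- p$l; g <- p$g
  den <- m1 + m2 * sin(th2)^2
  if (abs(den) < 1e-12) {
    stop("singular configuration: m1 + m2*sin(theta2)^2 vanished", call. = FALSE)
  }
  dw1 <- (2 * g * m1 * sin(th1) - g * m2 * sin(th1 + 2 * th2) +
            g * m2 * sin(th1) + l * m2 * w1^2 * sin(2 * th2) -
            2 * l * m2 * w2^2 * sin(th2)) / (2 * l * den)
  dw2 <- -sin(th2) * (g * m1 * cos(th1) + g * m2 * cos(th1) -
                        l * w1^2 * (m1 + m2) + l * m2 * w2^2 * cos(th2)) /
    (l * den)
  c(theta1 = w1, theta2 = w2, omega1 = dw1, omega2 = dw2)
}

#' Forced biped vector field (small-angle, massless swing leg)
#'
#' The simulated stance dynamics: the stance leg obeys the forced linear
#' pendulum equation and the swing leg the small-angle pendulum about the
#' moving hip,
#' \deqn{\dot\omega_1 = \Gamma(t) + g\theta_1/l, \quad
#'       \dot\omega_2 = -(g - l\omega_1^2)\theta_2/l.}
#'
#' @param t Forcing-clock time (s).
#' @param x A [biped_state()].
#' @param p A [gait_params()] object.
#' @return Named derivative vector.
#' @export
biped_field_forced <- function(t, x, p) {
  th1 <- x[["theta1"]]; th2 <- x[["theta2"]]
  w1 <- x[["omega1"]]; w2 <- x[["omega2"]]
  c(theta1 = w1,
    theta2 = w2,
    omega1 = gamma_forcing(t, p) + p$g * th1 / p$l,
    omega2 = -(p$g - p$l * w1^2) * th2 / p$l)
}

#' Heel-strike reset maps
#'
#' Instantaneous state jumps applied on the guard surface. For the biped the
#' guard is `theta1 + theta2 = 0` with `theta1 < 0`; the reset negates both
#' angles, scales the stance rate by `cos(theta_h)` (inelastic collision
#' conserving angular momentum about the new contact point) and restarts the
#' swing leg at the constant rate `omega20`. For the pendulum the guard is
#' `theta = theta_reset`; the reset is `[theta, omega] -> [-theta,
#' omega cos(theta_h)]`.
#'
#' Both refuse states off their guard surface (beyond `guard_tol`), since
#' applying a collision map mid-flow has no physical meaning.
#'
#' @param x State immediately before the collision.
#' @param p A [gait_params()] object.
#' @param guard_tol Tolerance for the guard-surface check (rad).
#' @return The post-collision state.
#' @examples
#' p <- gait_params()
#' pendulum_reset(pendulum_state(-0.1, -0.5), p)
#' @name resets
NULL

#' @rdname resets
#' @export
biped_reset <- function(x, p, guard_tol = 1e-8) {
  g_val <- x[["theta1"]] + x[["theta2"]]
  if (abs(g_val) > guard_tol || x[["theta1"]] >= 0) {
    stop(sprintf(
      "biped_reset called off the guard surface (theta1+theta2 = %.3g, theta1 = %.3g)",
      g_val, x[["theta1"]]), call. = FALSE)
  }
  biped_state(-x[["theta1"]], -x[["theta2"]],
              x[["omega1"]] * cos(p$theta_h), p$omega20)
}

#' @rdname resets
#' @export
pendulum_reset <- function(x, p, guard_tol = 1e-8) {
  if (abs(x[["theta"]] - p$theta_reset) > guard_tol) {
    stop(sprintf(
      "pendulum_reset called off the guard surface (theta = %.3g, theta_reset = %.3g)",
      x[["theta"]], p$theta_reset), call. = FALSE)
  }
  pendulum_state(-x[["theta"]], x[["omega"]] * cos(p$theta_h))
}

#' Forced inverted-pendulum vector field
#'
#' The reduced stance dynamics
#' \deqn{\dot\theta = \omega, \quad \dot\omega = \Gamma(t) + g\theta/l,}
#' i.e. the stance-leg rows of [biped_field_forced()].
#'
#' @param t Forcing-clock time (s).
#' @param x A [pendulum_state()].
#' @param p A [gait_params()] object.
#' @return Named derivative vector `c(theta, omega)`.
#' @export
pendulum_field <- function(t, x, p) {
  c(theta = x[["omega"]],
    omega = gamma_forcing(t, p) + p$g * x[["theta"]] / p$l)
}
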