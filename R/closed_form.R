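#' Analytic stance-phase flow of the forced linear pendulum
#'
#' The stance dynamics \eqn{\ddot\theta = (g/l)\,\theta + \Gamma(t)} is a
#' linear ODE whose forcing is a sum of two sinusoids and a constant, so the
#' flow is available in closed form: with \eqn{k = \sqrt{g/l}},
#' \deqn{\theta(t) = c_1\cosh(kt) + c_2\sinh(kt)
#'   + A_1\sin(\nu_1 t + \phi) + A_2\sin(\nu_2 t) + A_c}
#' where each sinusoidal particular amplitude is
#' \eqn{A_i = -a_i/(\nu_i^2 + k^2)} for an acceleration amplitude
#' \eqn{a_i} at angular frequency \eqn{\nu_i}, the constant offset is
#' \eqn{A_c = -C/k^2}, and \eqn{c_1, c_2} match the initial conditions.
#' `flow_omega()` is the exact time derivative. The closed form is the
#' backbone of the stride return map, where event times must be located to
#' high accuracy for the bifurcation structure to be trustworthy.
#'
#' The resonance denominator \eqn{\nu^2 + k^2} is strictly positive for
#' real forcing frequencies (`k^2 = g/l > 0`), so the particular form never
#' degenerates; this is asserted.
#'
#' @param theta0,omega0 Initial stance angle (rad) and rate (rad s^-1) at
#'   `t = 0` of the forcing clock.
#' @param p A [gait_params()] object.
#' @return `flow_coefficients()` returns a list with `k`, `c1`, `c2`,
#'   sinusoid amplitudes `A1`, `A2` (rad), angular frequencies `nu1`, `nu2`
#'   (rad s^-1), phase `phi`, and constant offset `Ac` (rad).
#' @examples
#' p <- gait_params(tau_l = 5, tau_r = 35, phi = -pi / 2)
#' co <- flow_coefficients(0.1, -0.6, p)
#' flow_theta(0, 0.1, -0.6, p)   # = 0.1
#' flow_omega(0, 0.1, -0.6, p)   # = -0.6
#' @export
flow_coefficients <- function(theta0, omega0, p) {
  k2 <- p$g / p$l
  k <- sqrt(k2)
  nu1 <- 2 * pi * p$fr1
  nu2 <- 2 * pi * p$fr2
  inert <- inertia(p)
  a1 <- p$tau_l / inert                              # sin(nu1 t + phi) term
  a2 <- -p$tau_r * p$l * sin(p$theta_h) / inert      # sin(nu2 t) term
  C  <- (p$tau_l - p$tau_r * p$l * sin(p$theta_h)) / inert
  stopifnot(nu1^2 + k2 > 0, nu2^2 + k2 > 0)
  A1 <- -a1 / (nu1^2 + k2)
  A2 <- -a2 / (nu2^2 + k2)
  Ac <- -C / k2
  c1 <- theta0 - A1 * sin(p$phi) - Ac
  c2 <- (omega0 - A1 * nu1 * cos(p$phi) - A2 * nu2) / k
  list(k = k, c1 = c1, c2 = c2, A1 = A1, A2 = A2, Ac = Ac,
       nu1 = nu1, nu2 = nu2, phi = p$phi)
}

#' @rdname flow_coefficients
#' @param t Time since step start (s); vectorised.
#' @param co Optional precomputed [flow_coefficients()]; supplying it skips
#'   recomputation in tight loops.
#' @return `flow_theta()` the stance angle (rad); `flow_omega()` the stance
#'   angular velocity (rad s^-1).
#' @export
flow_theta <- function(t, theta0, omega0, p, co = NULL) {
  if (is.null(co)) co <- flow_coefficients(theta0, omega0, p)
  co$c1 * cosh(co$k * t) + co$c2 * sinh(co$k * t) +
    co$A1 * sin(co$nu1 * t + co$phi) + co$A2 * sin(co$nu2 * t) + co$Ac
}

#' @rdname flow_coefficients
#' @export
flow_omega <- function(t, theta0, omega0, p, co = NULL) {
  if (is.null(co)) co <- flow_coefficients(theta0, omega0, p)
  co$k * (co$c1 * sinh(co$k * t) + co$c2 * cosh(co$k * t)) +
    co$A1 * co$nu1 * cos(co$nu1 * t + co$phi) +
    co$A2 * co$nu2 * cos(co$nu2 * t)
}

#' Minimum speed for an unforced step
#'
#' Without muscle forcing the stance energy
#' \eqn{E = \omega^2 - k^2\theta^2} is conserved, so a step launched at
#' `theta0 > 0` crosses the vertical (and completes) iff
#' `|omega0| > k * theta0` with `k = sqrt(g/l)`. At or below the threshold
#' the leg stalls before vertical and gravity pulls it back: a freeze.
#'
#' @param theta0 Initial stance angle (rad), positive.
#' @param p A [gait_params()] object.
#' @return The threshold speed `k * theta0` (rad s^-1).
#' @examples
#' unforced_freeze_threshold(0.1, gait_params())  # sqrt(9.8/0.6) * 0.1
#' @export
unforced_freeze_threshold <- function(theta0, p) {
  stopifnot(theta0 > 0)
  sqrt(p$g / p$l) * theta0
}
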