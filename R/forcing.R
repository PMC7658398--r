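#' Plantar-flexor forcing terms
#'
#' The neuromuscular drive of the stance phase is carried by two sinusoidal
#' envelopes, both nonnegative: the stance-leg plantar-flexor torque
#' \deqn{G_l(t) = \tau_l (\sin(2\pi f_{r1} t + \phi) + 1)}
#' which opposes forward progression, and the trailing-leg ankle push-off
#' force
#' \deqn{F(t) = \tau_r (\sin(2\pi f_{r2} t) + 1)}
#' which propels the centre of mass. `F` acts on the stance leg through the
#' moment arm `l sin(theta_h)`, giving the push-off torque
#' `zeta1(t) = tau_r * l * sin(theta_h) * (sin(2 pi fr2 t) + 1)`; the
#' stance-leg torque is `zeta2(t) = Gl(t)`. The net angular acceleration
#' contributed by the muscles is
#' \deqn{\Gamma(t) = (\zeta_2(t) - \zeta_1(t)) / (m_1 l^2).}
#'
#' All functions are vectorised over `t` and total (no error conditions).
#'
#' @param t Time (s) since the forcing clock origin; under the default
#'   per-step clock this is time since the last heel strike.
#' @param p A [gait_params()] object.
#' @return `gl_torque`, `zeta1`, `zeta2` return torques (N m);
#'   `push_off_force` a force (N); `gamma_forcing` an angular acceleration
#'   (rad s^-2).
#' @name forcing
#' @examples
#' p <- gait_params(tau_l = 5, tau_r = 35, phi = -pi / 2)
#' curve(gamma_forcing(x, p), 0, 1, xlab = "t (s)")
#' max(zeta1(seq(0, 1, 1e-4), p)) / p$tau_r  # ~ 2 l sin(theta_h)
NULL

#' @rdname forcing
#' @export
gl_torque <- function(t, p) {
  p$tau_l * (sin(2 * pi * p$fr1 * t + p$phi) + 1)
}

#' @rdname forcing
#' @export
push_off_force <- function(t, p) {
  p$tau_r * (sin(2 * pi * p$fr2 * t) + 1)
}

#' @rdname forcing
#' @export
zeta1 <- function(t, p) {
  p$tau_r * p$l * sin(p$theta_h) * (sin(2 * pi * p$fr2 * t) + 1)
}

#' @rdname forcing
#' @export
zeta2 <- function(t, p) gl_torque(t, p)

#' @rdname forcing
#' @export
gamma_forcing <- function(t, p) {
  (zeta2(t, p) - zeta1(t, p)) / inertia(p)
}

#' Convert between push-off force and trailing-leg ankle torque
#'
#' The push-off force results from the trailing-leg plantar-flexor torque
#' `Gr` acting over the foot lever arm `l_f`:
#' `F = Gr / (l_f * cos(theta1))`. `gr_from_force()` inverts this to recover
#' the ankle torque from a prescribed force; `force_from_gr()` is the
#' forward direction. Both require the stance angle to be within the
#' physiological range `|theta1| < pi/2` (the conversion is singular when
#' the leg is horizontal).
#'
#' @param force Push-off force `F` (N).
#' @param gr Trailing-leg ankle torque `Gr` (N m).
#' @param theta1 Stance angle (rad), `|theta1| < pi/2`.
#' @param p A [gait_params()] object supplying the lever arm `l_f`.
#' @return A torque (N m) for `gr_from_force`, a force (N) for
#'   `force_from_gr`.
#' @examples
#' p <- gait_params()
#' gr_from_force(10, 0, p)   # 10 * l_f
#' force_from_gr(gr_from_force(10, 0.3, p), 0.3, p)
#' @export
gr_from_force <- function(force, theta1, p) {
  check_leg_angle(theta1)
  force * p$l_f * cos(theta1)
}

#' @rdname gr_from_force
#' @export
force_from_gr <- function(gr, theta1, p) {
  check_leg_angle(theta1)
  gr / (p$l_f * cos(theta1))
}

check_leg_angle <- function(theta1) {
  if (any(cos(theta1) <= 0)) {
    stop("stance angle out of physiological range: cos(theta1) <= 0",
         call. = FALSE)
  }
  invisible(theta1)
}
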