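#' Model parameters for the gait models
#'
#' Collects every physical and neuromuscular constant shared by the biped and
#' inverted-pendulum stance models. All quantities are SI: masses in kg,
#' lengths in m, torques in N m, forces in N, angles in rad, frequencies in
#' Hz, times in s.
#'
#' The forcing scale of the stance dynamics enters only through the inertia
#' `m1 * l^2` (the torque-to-angular-acceleration denominator). The default
#' `m1` is chosen so that `m1 * l^2 = 1` N m s^2, a pure normalisation that
#' makes torques and angular accelerations numerically equal; use
#' [calibration_sweep()] to resolve the inertia scale against a known outcome
#' when absolute timing matters.
#'
#' @param m1 Body mass (kg), concentrated at the hip. Must be positive.
#' @param m2 Swing-leg mass (kg). The reduced models take `m2 = 0`.
#' @param l Leg length (m). Must be positive.
#' @param g Gravitational acceleration (m s^-2).
#' @param tau_l Amplitude of the stance-leg plantar-flexor torque (N m).
#'   This torque opposes forward progression ("premature activation").
#' @param tau_r Amplitude of the trailing-leg ankle push-off force (N).
#' @param phi Phase offset of the stance-leg torque relative to the
#'   push-off force (rad).
#' @param fr1,fr2 Forcing frequencies of the stance-leg torque and the
#'   push-off force (Hz). Both default to 1.
#' @param theta_reset Stance angle at which the swing heel strikes the
#'   ground (rad). Negative: the stance phase runs from `+|theta_reset|`
#'   down through vertical to `theta_reset`.
#' @param theta_h Hip (inter-leg) angle at heel strike (rad), controlling
#'   collision dissipation `omega+ = omega- * cos(theta_h)`. Defaults to
#'   `2 * abs(theta_reset)`, the isosceles-triangle geometry of two legs of
#'   equal length standing `2 l sin(|theta_reset|)` apart.
#' @param omega20 Swing-leg angular velocity imposed at every heel strike
#'   (rad s^-1), accounting for the push-off impulse. Positive.
#' @param l_f Foot lever arm (m) between heel and ankle pivot; used only by
#'   the torque/force conversion [gr_from_force()].
#' @param clock Forcing clock convention: `"step"` restarts the forcing time
#'   at every heel strike (the default, under which successive stance phases
#'   are iterates of one autonomous stride map); `"global"` lets the forcing
#'   run on the wall clock across steps.
#'
#' @return An object of class `gait_params`: a validated named list with the
#'   fields above.
#' @seealso [modify_params()], [inertia()], [read_gait_config()]
#' @examples
#' p <- gait_params(tau_l = 5, tau_r = 35, phi = -pi / 2)
#' p$theta_h
#' inertia(p)
#' @export
gait_params <- function(m1 = 1 / 0.6^2,
                        m2 = 0,
                        l = 0.6,
                        g = 9.8,
                        tau_l = 0,
                        tau_r = 0,
                        phi = 0,
                        fr1 = 1,
                        fr2 = 1,
                        theta_reset = -0.1,
                        theta_h = NULL,
                        omega20 = 1,
                        l_f = 0.1,
                        clock = c("step", "global")) {
  clock <- match.arg(clock)
  if (is.null(theta_h)) theta_h <- 2 * abs(theta_reset)
  p <- structure(
    list(m1 = m1, m2 = m2, l = l, g = g,
         tau_l = tau_l, tau_r = tau_r, phi = phi,
         fr1 = fr1, fr2 = fr2,
         theta_reset = theta_reset, theta_h = theta_h,
         omega20 = omega20, l_f = l_f, clock = clock),
    class = "gait_params")
  validate_params(p)
  p
}

validate_params <- function(p) {
  num <- vapply(p[setdiff(names(p), "clock")], is.numeric, logical(1))
  if (!all(num)) {
    stop("non-numeric parameter field(s): ",
         paste(names(num)[!num], collapse = ", "), call. = FALSE)
  }
  stopifnot(
    "l must be > 0" = p$l > 0,
    "m1 must be > 0" = p$m1 > 0,
    "m2 must be >= 0" = p$m2 >= 0,
    "g must be > 0" = p$g > 0,
    "theta_reset must be < 0" = p$theta_reset < 0,
    "theta_h must lie in [0, pi/2)" = p$theta_h >= 0 && p$theta_h < pi / 2,
    "fr1 must be > 0" = p$fr1 > 0,
    "fr2 must be > 0" = p$fr2 > 0,
    "tau_l must be >= 0" = p$tau_l >= 0,
    "tau_r must be >= 0" = p$tau_r >= 0,
    "omega20 must be > 0" = p$omega20 > 0,
    "l_f must be > 0" = p$l_f > 0
  )
  invisible(p)
}

#' Modify a parameter set
#'
#' Returns a copy of `p` with the named fields replaced and invariants
#' re-checked. `theta_h` is re-derived from `theta_reset` when `theta_reset`
#' changes and `theta_h` is not itself supplied (it tracks the default
#' `2 |theta_reset|` geometry).
#'
#' @param p A [gait_params()] object.
#' @param ... Named fields to replace.
#' @return A `gait_params` object.
#' @examples
#' p <- gait_params(tau_l = 5)
#' modify_params(p, tau_l = 2, theta_reset = -0.05)$theta_h
#' @export
modify_params <- function(p, ...) {
  stopifnot(inherits(p, "gait_params"))
  new <- list(...)
  unknown <- setdiff(names(new), names(p))
  if (length(unknown)) {
    stop("unknown parameter field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if ("theta_reset" %in% names(new) && !("theta_h" %in% names(new)) &&
      isTRUE(all.equal(p$theta_h, 2 * abs(p$theta_reset)))) {
    new$theta_h <- 2 * abs(new$theta_reset)
  }
  p[names(new)] <- new
  validate_params(p)
  p
}

#' Inertia scale of the stance leg
#'
#' The denominator `m1 * l^2` (N m s^2) converting net plantar-flexor torque
#' into angular acceleration of the stance leg.
#'
#' @param p A [gait_params()] object.
#' @return A number (N m s^2).
#' @export
inertia <- function(p) p$m1 * p$l^2

#' Set the inertia scale directly
#'
#' Adjusts `m1` so that `m1 * l^2` equals `value`, leaving `l` unchanged.
#' Convenience for calibration, where the inertia product is the only way
#' the body mass enters the dynamics.
#'
#' @param p A [gait_params()] object.
#' @param value Target inertia `m1 * l^2` (N m s^2).
#' @return A `gait_params` object.
#' @export
set_inertia <- function(p, value) {
  stopifnot(value > 0)
  modify_params(p, m1 = value / p$l^2)
}

#' @export
print.gait_params <- function(x, ...) {
  cat("<gait_params>\n")
  cat(sprintf("  body: m1 = %.4g kg, m2 = %.4g kg, l = %.3g m, g = %.3g m/s^2  (m1*l^2 = %.4g)\n",
              x$m1, x$m2, x$l, x$g, inertia(x)))
  cat(sprintf("  forcing: tau_l = %.4g N m, tau_r = %.4g N, phi = %.4g rad, fr1 = %g Hz, fr2 = %g Hz, %s clock\n",
              x$tau_l, x$tau_r, x$phi, x$fr1, x$fr2, x$clock))
  cat(sprintf("  reset: theta_reset = %.4g rad, theta_h = %.4g rad, omega20 = %.4g rad/s, l_f = %.3g m\n",
              x$theta_reset, x$theta_h, x$omega20, x$l_f))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a parameter set into a long tibble
#'
#' One row per field, suitable for serialisation and joins. Round-trips
#' through [as_gait_params()].
#'
#' @param x A `gait_params` object.
#' @param ... Unused.
#' @return A tibble with columns `field`, `value`.
#' @exportS3Method generics::tidy
tidy.gait_params <- function(x, ...) {
  tibble::tibble(
    field = names(unclass(x)),
    value = vapply(unclass(x), function(v) as.character(v), character(1))
  )
}

#' Rebuild a parameter set from a flat named list
#'
#' Inverse of the flat serialisation used by [tidy.gait_params()] and the
#' YAML config files: numeric fields are parsed, `clock` is kept as a
#' string, unknown keys are an error.
#'
#' @param x A named list or named character/numeric vector of fields.
#' @return A `gait_params` object.
#' @export
as_gait_params <- function(x) {
  x <- as.list(x)
  if (is.null(names(x)) && length(x)) stop("fields must be named", call. = FALSE)
  defaults <- gait_params()
  unknown <- setdiff(names(x), names(defaults))
  if (length(unknown)) {
    stop("unknown parameter field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  num_fields <- setdiff(names(x), "clock")
  x[num_fields] <- lapply(x[num_fields], function(v) as.numeric(v))
  # theta_h default tracks theta_reset when absent from the input
  args <- utils::modifyList(list(), x)
  do.call(gait_params, args)
}
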