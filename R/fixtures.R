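# Canonical experiment presets. Each entry reproduces one published figure
# of the study programme this model family implements; names follow the
# figure numbering. Parameter values are stated in the entries themselves;
# `known` records the printed outcome a run should reproduce, where one
# exists (used as the calibration reference for the inertia scale).

fixture_registry <- function() {
  base <- gait_params()
  list(
    # biped freeze demonstration: tau_l = 2.3 N m, tau_r = 15.74 N,
    # phi = -pi/2; x0 = (theta1 = 0.1, theta2 = -0.1, omega1 = -0.6,
    # omega2 = 2)
    fig5 = list(
      kind = "simulate-biped",
      params = modify_params(base, tau_l = 2.3, tau_r = 15.74, phi = -pi / 2,
                             omega20 = 2),
      x0 = biped_state(0.1, -0.1, -0.6, 2),
      window = 10,
      known = list(froze = TRUE)),
    # biped walk-time heatmap: x0 = (0.1, -0.1, -0.6, 1), phi = -pi/2
    fig6a = list(
      kind = "freeze-heatmap",
      model = "biped",
      params = modify_params(base, phi = -pi / 2, omega20 = 1),
      x0 = biped_state(0.1, -0.1, -0.6, 1),
      tau_l_grid = seq(0, 5, length.out = 26),
      tau_r_grid = seq(0, 55, length.out = 26),
      window = 10,
      known = NULL),
    # biped speed-gain BVP: theta1: 0 -> -0.1 over 0.5 s;
    # theta2(0) = -0.1, omega2(0) = 1, phi = -pi/2
    fig6b = list(
      kind = "bvp-contour",
      model = "biped",
      params = modify_params(base, phi = -pi / 2, omega20 = 1),
      extra_ics = c(theta2 = -0.1, omega2 = 1),
      tau_l_grid = seq(0, 5, length.out = 11),
      tau_r_grid = seq(0, 55, length.out = 11),
      known = NULL),
    # pendulum freeze demonstration: phi = -pi/2, omega0 = -1,
    # tau_l = 2 N m, tau_r = 11 N, theta_reset = -0.1; printed outcome:
    # freezing sets in after 18 s
    fig7 = list(
      kind = "simulate-pendulum",
      params = modify_params(base, tau_l = 2, tau_r = 11, phi = -pi / 2),
      omega0 = -1,
      window = 20,
      known = list(freeze_time = 18)),
    # pendulum walk-time heatmap: theta_reset = -0.1, phi = -pi/2
    fig8a = list(
      kind = "freeze-heatmap",
      model = "pendulum",
      params = modify_params(base, phi = -pi / 2),
      omega0 = -0.6,
      tau_l_grid = seq(0, 5, length.out = 26),
      tau_r_grid = seq(0, 55, length.out = 26),
      window = 10,
      known = NULL),
    # pendulum speed-gain BVP: theta: 0 -> -0.1 over 0.5 s, phi = -pi/2
    fig8b = list(
      kind = "bvp-contour",
      model = "pendulum",
      params = modify_params(base, phi = -pi / 2),
      tau_l_grid = seq(0, 5, length.out = 11),
      tau_r_grid = seq(0, 55, length.out = 11),
      known = NULL),
    # phi bifurcation diagram: omega0 = -0.433, tau_l = 5 N m, tau_r = 35 N;
    # printed outcome: period-doubling accumulation (Feigenbaum bound) at
    # phi = -1.37 rad, cascade visible between -5*pi/8 and -pi/4
    fig9 = list(
      kind = "bifurcation",
      params = modify_params(base, tau_l = 5, tau_r = 35),
      omega0 = -0.433,
      param = "phi",
      values = seq(-2 * pi, -0.02, length.out = 400),
      known = list(feigenbaum_phi = -1.37,
                   cascade_window = c(-5 * pi / 8, -pi / 4))),
    # stride-map family over tau_l: tau_r = 35 N, phi = -1.57,
    # theta_reset = -0.1; low-velocity orbits appear near tau_l ~ 3 N m
    fig10 = list(
      kind = "stride-map",
      params = modify_params(base, tau_r = 35, phi = -1.57),
      tau_l_values = 0:5,
      omega_grid = seq(-1.2, -0.05, length.out = 241),
      known = list(orbit_onset_tau_l = 3)),
    # period-1 contour over (tau_l, tau_r): phi = -pi/2, omega0 = -0.4
    fig13c = list(
      kind = "fixed-points",
      params = modify_params(base, phi = -pi / 2),
      omega0 = -0.4,
      period = 1,
      tau_l_grid = seq(0, 5, length.out = 21),
      tau_r_grid = seq(30, 55, length.out = 21),
      known = NULL),
    # period-1 contour, faster start: phi = -pi/2, omega0 = -1
    fig13d = list(
      kind = "fixed-points",
      params = modify_params(base, phi = -pi / 2),
      omega0 = -1,
      period = 1,
      tau_l_grid = seq(0, 5, length.out = 21),
      tau_r_grid = seq(30, 55, length.out = 21),
      known = NULL),
    # period-3 contour over (tau_l, tau_r): phi = -pi/2, omega0 = -0.4
    fig14 = list(
      kind = "fixed-points",
      params = modify_params(base, phi = -pi / 2),
      omega0 = -0.4,
      period = 3,
      tau_l_grid = seq(0, 5, length.out = 21),
      tau_r_grid = seq(30, 55, length.out = 21),
      known = NULL)
  )
}

#' Canonical experiment presets
#'
#' Named parameter sets for the canonical simulation, map, bifurcation and
#' BVP experiments of this model family (named after the published figures
#' they regenerate). Each preset bundles a [gait_params()] object, the
#' initial state, the experiment kind with its grids, and — where one
#' exists — the printed outcome (`known`) that a run should reproduce,
#' which also serves as the reference for [calibration_sweep()].
#'
#' @param name Preset name; one of the names returned by
#'   `gait_fixture_names()`.
#' @return A list with at least `kind` and `params`; see the registry
#'   source for the per-kind fields.
#' @examples
#' fx <- gait_fixture("fig7")
#' fx$params$tau_r
#' fx$known$freeze_time
#' gait_fixture_names()
#' @export
gait_fixture <- function(name) {
  reg <- fixture_registry()
  if (!name %in% names(reg)) {
    stop("unknown fixture '", name, "'; available: ",
         paste(names(reg), collapse = ", "), call. = FALSE)
  }
  reg[[name]]
}

#' @rdname gait_fixture
#' @export
gait_fixture_names <- function() names(fixture_registry())
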