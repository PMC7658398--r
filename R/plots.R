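#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a simulated gait trajectory
#'
#' Time series of the stance angle and angular velocity with the freeze
#' episode (from the last heel strike to the freezing event) highlighted.
#'
#' @param object A `gait_sim` object.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.gait_sim <- function(object, ...) {
  tb <- object$trajectory
  ang <- if (object$model == "pendulum") "theta" else "theta1"
  vel <- if (object$model == "pendulum") "omega" else "omega1"
  long <- tidyr::pivot_longer(tb[, c("t", ang, vel)],
                              cols = dplyr::all_of(c(ang, vel)),
                              names_to = "state", values_to = "value")
  gg <- ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~state, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL,
                  title = sprintf("%s model: %d heel strikes%s",
                                  object$model, object$n_steps,
                                  if (object$froze) ", froze" else ""))
  if (object$froze && !is.na(object$t_last_heel_strike)) {
    gg <- gg + ggplot2::annotate("rect",
                                 xmin = object$t_last_heel_strike,
                                 xmax = object$t_freeze,
                                 ymin = -Inf, ymax = Inf,
                                 alpha = 0.2, fill = "red")
  }
  gg
}

#' Phase-plane plot of a simulation
#'
#' @param sim A `gait_sim` object.
#' @return A ggplot of angular velocity against angle.
#' @export
plot_phase_plane <- function(sim) {
  stopifnot(inherits(sim, "gait_sim"))
  ang <- if (sim$model == "pendulum") "theta" else "theta1"
  vel <- if (sim$model == "pendulum") "omega" else "omega1"
  ggplot2::ggplot(sim$trajectory,
                  ggplot2::aes(x = .data[[ang]], y = .data[[vel]],
                               group = .data$step_index)) +
    ggplot2::geom_path(linewidth = 0.3) +
    ggplot2::labs(x = "stance angle (rad)",
                  y = "stance angular velocity (rad/s)")
}

#' Plot stride-map curves
#'
#' Draws the first few compositions of the stride return map against the
#' identity line; intersections are period-1/2/3 orbits. Frozen inputs
#' appear as gaps.
#'
#' @param p A [gait_params()] object.
#' @param omega_grid Input velocities (rad s^-1, negative).
#' @param periods Compositions to draw.
#' @return A ggplot.
#' @export
plot_stride_map <- function(p, omega_grid, periods = 1:3) {
  curves <- lapply(periods, function(k) {
    tibble::tibble(omega_in = omega_grid,
                   omega_out = composed_map(omega_grid, k, p),
                   composition = factor(k))
  })
  tb <- dplyr::bind_rows(curves)
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$omega_in, y = .data$omega_out,
                                   colour = .data$composition)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::labs(x = expression(omega[n]), y = expression(omega[n + 1]))
}

#' Plot a bifurcation diagram
#'
#' Retained post-transient iterates against the swept parameter.
#'
#' @param object A `gait_bifurcation` object.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.gait_bifurcation <- function(object, ...) {
  ggplot2::ggplot(object$iterates,
                  ggplot2::aes(x = .data$param_value, y = .data$omega)) +
    ggplot2::geom_point(size = 0.1, alpha = 0.4) +
    ggplot2::labs(x = object$param, y = expression(omega ~ (rad / s)))
}

#' Plot a walk-time heatmap
#'
#' @param object A `gait_heatmap` tibble from [freeze_time_heatmap()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.gait_heatmap <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$tau_l, y = .data$tau_r,
                                       fill = .data$walk_time)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "walk time (s)") +
    ggplot2::labs(x = expression(tau[l] ~ (N %.% m)),
                  y = expression(tau[r] ~ (N)))
}

#' @importFrom rlang .data
NULL
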