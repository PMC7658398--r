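#' Read and write parameter configuration files
#'
#' Flat YAML key-value files whose keys are exactly the [gait_params()]
#' field names (SI units, angles in rad). Missing keys take the documented
#' defaults; unknown keys are rejected with the offending name. An empty
#' file yields the default parameter set. `write_gait_config()` is the
#' exact inverse.
#'
#' @param path File path.
#' @param p A [gait_params()] object.
#' @return `read_gait_config()` a `gait_params` object;
#'   `write_gait_config()` the path, invisibly.
#' @examples
#' f <- tempfile(fileext = ".yml")
#' write_gait_config(gait_params(tau_l = 5), f)
#' read_gait_config(f)$tau_l
#' @export
read_gait_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  as_gait_params(raw)
}

#' @rdname read_gait_config
#' @export
write_gait_config <- function(p, path) {
  stopifnot(inherits(p, "gait_params"))
  yaml::write_yaml(unclass(p), path)
  invisible(path)
}

#' Export simulation results
#'
#' `write_trajectory_csv()` writes the dense trajectory with columns `t`,
#' the state components, `step_index` and `phase_time` (one header row,
#' UTF-8, full double precision). `write_sim_summary_json()` writes the
#' freeze report and per-step records.
#'
#' @param sim A `gait_sim` object.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_trajectory_csv <- function(sim, path) {
  stopifnot(inherits(sim, "gait_sim"))
  tb <- sim$trajectory
  state_cols <- setdiff(names(tb), c("t", "step_index", "phase_time"))
  tb <- tb[, c("t", state_cols, "step_index", "phase_time")]
  utils::write.csv(as.data.frame(tb), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
write_sim_summary_json <- function(sim, path) {
  stopifnot(inherits(sim, "gait_sim"))
  payload <- list(
    model = sim$model,
    froze = sim$froze,
    t_freeze = sim$t_freeze,
    t_last_heel_strike = sim$t_last_heel_strike,
    n_steps = sim$n_steps,
    steps = sim$steps
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Run a registered experiment and write its artifacts
#'
#' Dispatches on the experiment `kind` of a preset (see [gait_fixture()]) or
#' a user-built spec of the same shape, runs the corresponding package
#' computation, and writes CSV/JSON artifacts into `out_dir`. File names are
#' derived deterministically from the spec (a stable hash of its
#' serialisation), so re-running the same spec overwrites the same files
#' with identical content. Progress, event counts and any freeze or
#' nonconvergence are logged to `stderr`.
#'
#' @param spec An experiment spec: a fixture name (string) or a list with
#'   `kind`, `params` and the kind-specific fields used by the registry.
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress logging.
#' @return Character vector of the files written, invisibly.
#' @export
run_experiment <- function(spec, out_dir = ".", quiet = FALSE) {
  if (is.character(spec) && length(spec) == 1) spec <- gait_fixture(spec)
  stopifnot(is.list(spec), !is.null(spec$kind), !is.null(spec$params))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tag <- substr(rlang::hash(spec), 1, 12)
  stem <- file.path(out_dir, paste0(gsub("[^a-z0-9]+", "-", spec$kind),
                                    "-", tag))
  log_msg <- function(...) if (!quiet) message(sprintf(...))
  p <- spec$params
  files <- character(0)
  add_csv <- function(tb, suffix) {
    f <- paste0(stem, "-", suffix, ".csv")
    utils::write.csv(as.data.frame(tb), f, row.names = FALSE,
                     fileEncoding = "UTF-8")
    files <<- c(files, f)
    f
  }

  if (spec$kind %in% c("simulate-pendulum", "simulate-biped")) {
    model <- if (spec$kind == "simulate-pendulum") "pendulum" else "biped"
    x0 <- if (model == "pendulum") spec$omega0 else spec$x0
    sim <- simulate_gait(p, model, x0,
                         t_max = spec$window %||% 10)
    log_msg("%s: %d heel strikes, froze = %s", spec$kind, sim$n_steps,
            sim$froze)
    add_csv(sim$trajectory, "trajectory")
    f <- paste0(stem, "-summary.json")
    write_sim_summary_json(sim, f)
    files <- c(files, f)
  } else if (spec$kind == "stride-map") {
    for (tl in spec$tau_l_values) {
      tb <- map_table(spec$omega_grid, modify_params(p, tau_l = tl))
      log_msg("stride-map tau_l = %g: %d frozen inputs", tl, sum(tb$frozen))
      add_csv(tb, paste0("tau-l-", tl))
    }
  } else if (spec$kind == "bifurcation") {
    bd <- bifurcation_diagram(p, spec$param, spec$values, spec$omega0)
    log_msg("bifurcation over %s: %s", spec$param,
            paste(capture_labels(bd), collapse = ", "))
    add_csv(bd$iterates, "iterates")
    add_csv(bd$summary, "summary")
  } else if (spec$kind == "fixed-points") {
    fp <- fixed_point_contour(p, "tau_l", "tau_r", spec$tau_l_grid,
                              spec$tau_r_grid, period = spec$period)
    log_msg("fixed-points period %d: %d orbit(s)", spec$period, nrow(fp))
    add_csv(fp, paste0("period-", spec$period))
  } else if (spec$kind == "freeze-heatmap") {
    x0 <- if (spec$model == "pendulum") spec$omega0 else spec$x0
    hm <- freeze_time_heatmap(p, spec$model, spec$tau_l_grid,
                              spec$tau_r_grid, x0,
                              window = spec$window %||% 10, dt = 0.01)
    log_msg("freeze-heatmap (%s): %d/%d cells walked the full window",
            spec$model, sum(hm$walk_time >= attr(hm, "window")), nrow(hm))
    add_csv(hm, "walk-time")
  } else if (spec$kind == "bvp-contour") {
    sg <- speed_gain_contour(p, spec$model, spec$tau_l_grid,
                             spec$tau_r_grid,
                             extra_ics = spec$extra_ics %||%
                               c(theta2 = -0.1, omega2 = 1))
    n_bad <- sum(!sg$converged)
    if (n_bad > 0) log_msg("bvp-contour: %d nonconvergent cell(s)", n_bad)
    add_csv(sg, "speed-gain")
  } else if (spec$kind == "calibrate") {
    cal <- calibration_sweep(p, spec$target, spec$reference,
                             inertia_grid = spec$inertia_grid %||%
                               seq(15, 40, by = 2.5),
                             l_grid = spec$l_grid,
                             omega0 = spec$omega0)
    best <- attr(cal, "best")
    log_msg("calibrate %s: best inertia %.4g (l = %.3g), residual %.4g",
            spec$target, best$inertia, best$l, best$residual)
    add_csv(cal, "calibration")
  } else {
    stop("unknown experiment kind: ", spec$kind, call. = FALSE)
  }
  invisible(files)
}

capture_labels <- function(bd) {
  tb <- table(bd$summary$label)
  paste0(names(tb), ":", as.integer(tb))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
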