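# Attractor classification for one parameter point: iterate the stride map,
# keep the tail, and find the minimal recurrence period. Returns period 0
# for a freeze and -1 when no period up to max_period recurs.
classify_attractor <- function(step_fn, x0, n_total = 500, n_keep = 50,
                               tol = 1e-5, max_period = 64L) {
  x <- x0
  n_burn <- n_total - n_keep
  for (i in seq_len(n_burn)) {
    x <- step_fn(x)
    if (is.na(x)) return(list(period = 0L, kept = numeric(0)))
  }
  kept <- numeric(n_keep)
  for (i in seq_len(n_keep)) {
    x <- step_fn(x)
    if (is.na(x)) return(list(period = 0L, kept = kept[seq_len(i - 1L)]))
    kept[i] <- x
  }
  for (pp in seq_len(min(max_period, n_keep - 1L))) {
    if (max(abs(kept[seq_len(n_keep - pp)] -
                  kept[(pp + 1L):n_keep])) < tol) {
      return(list(period = as.integer(pp), kept = kept))
    }
  }
  list(period = -1L, kept = kept)
}

#' Bifurcation diagram of the stride map
#'
#' Sweeps one model parameter over a grid; at each grid point the
#' one-dimensional stride map is iterated from the same initial velocity,
#' the transient is discarded, and the retained iterates are classified by
#' minimal recurrence. Grid points whose tail shows no period up to
#' `max_period` are labelled `"chaotic"` when the map-iterate Lyapunov
#' estimate (mean log absolute map derivative over the kept iterates) is
#' positive, and `"aperiodic"` otherwise; points whose iteration terminates
#' are `"freeze"`.
#'
#' @param p A [gait_params()] object (values of the swept parameter in `p`
#'   are ignored).
#' @param param Name of the swept field of `p` (e.g. `"phi"`, `"tau_l"`).
#' @param values Sorted numeric grid for the swept parameter.
#' @param omega0 Initial angular velocity (rad s^-1, negative) used at every
#'   grid point (no continuation warm-start).
#' @param n_total,n_keep Total iterations and retained tail per grid point.
#' @param tol Recurrence tolerance (rad s^-1) for period classification.
#' @param max_period Largest period searched.
#' @return An object of class `gait_bifurcation`: list with `iterates`
#'   (long tibble: `param`, `param_value`, `omega`) and `summary` (tibble:
#'   `param_value`, `period`, `label`, `lyapunov`).
#' @examples
#' \donttest{
#' p <- gait_params(tau_l = 5, tau_r = 35, m1 = 25 / 0.36)
#' bd <- bifurcation_diagram(p, "phi", seq(-2, -0.8, by = 0.05), -0.433,
#'                           n_total = 200, n_keep = 30)
#' head(tidy(bd))
#' }
#' @export
bifurcation_diagram <- function(p, param, values, omega0,
                                n_total = 500, n_keep = 50,
                                tol = 1e-5, max_period = 64L) {
  stopifnot(param %in% names(p), !is.unsorted(values), omega0 < 0)
  iterates <- vector("list", length(values))
  summaries <- vector("list", length(values))
  for (i in seq_along(values)) {
    pi_ <- do.call(modify_params,
                   c(list(p), stats::setNames(list(values[i]), param)))
    cls <- classify_attractor(function(om) omega_map(om, pi_), omega0,
                              n_total, n_keep, tol, max_period)
    label <- if (cls$period == 0L) "freeze"
             else if (cls$period > 0L) paste0("period-", cls$period)
             else NA_character_
    lyap <- NA_real_
    if (cls$period == -1L) {
      lyap <- lyapunov_estimate(cls$kept, pi_)
      label <- if (is.finite(lyap) && lyap > 0) "chaotic" else "aperiodic"
    }
    iterates[[i]] <- tibble::tibble(param = param, param_value = values[i],
                                    omega = cls$kept)
    summaries[[i]] <- tibble::tibble(
      param_value = values[i],
      period = if (cls$period > 0L) cls$period else NA_integer_,
      label = label, lyapunov = lyap)
  }
  structure(list(iterates = dplyr::bind_rows(iterates),
                 summary = dplyr::bind_rows(summaries),
                 param = param, omega0 = omega0, params = p),
            class = "gait_bifurcation")
}

lyapunov_estimate <- function(kept, p, h = 1e-5) {
  if (!length(kept)) return(NA_real_)
  d <- abs(map_derivative(kept, 1, p, h))
  d <- d[is.finite(d) & d > 0]
  if (!length(d)) return(NA_real_)
  mean(log(d))
}

#' @export
print.gait_bifurcation <- function(x, ...) {
  cat(sprintf("<gait_bifurcation: %s over [%.4g, %.4g], %d grid points>\n",
              x$param, min(x$summary$param_value), max(x$summary$param_value),
              nrow(x$summary)))
  print(table(x$summary$label, useNA = "ifany"))
  invisible(x)
}

#' @rdname bifurcation_diagram
#' @param x A `gait_bifurcation` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.gait_bifurcation <- function(x, ...) {
  dplyr::left_join(x$iterates, x$summary, by = "param_value")
}

#' @rdname bifurcation_diagram
#' @exportS3Method generics::glance
glance.gait_bifurcation <- function(x, ...) {
  tibble::tibble(
    param = x$param,
    n_grid = nrow(x$summary),
    n_freeze = sum(x$summary$label == "freeze"),
    n_chaotic = sum(x$summary$label == "chaotic"),
    max_period = suppressWarnings(max(x$summary$period, na.rm = TRUE))
  )
}

#' Estimate a period-doubling accumulation point
#'
#' Generic Feigenbaum-point estimator for a one-parameter family of
#' one-dimensional maps. Starting from the `window` end where the attractor
#' has the lowest period, the parameter is marched towards the other end;
#' each onset where the detected period doubles is located by bisection, and
#' the accumulation point is extrapolated geometrically from the last onset
#' spacings (using the ratio of successive spacings when three or more
#' onsets are available, and the universal ratio 4.669 otherwise).
#'
#' `feigenbaum_point()` is the stride-map front end;
#' `feigenbaum_estimate()` takes an arbitrary `period_fn` and is also used
#' to self-test the estimator on the logistic map.
#'
#' @param period_fn Function of the swept parameter returning the detected
#'   attractor period (0 for a terminating/freezing orbit, -1 for no
#'   detected period).
#' @param window Length-2 numeric: sweep from `window[1]` towards
#'   `window[2]` (period increases towards `window[2]`).
#' @param coarse_step Initial marching step (parameter units).
#' @param max_k Number of doubling onsets sought (k up to `max_k` gives
#'   onsets of periods `2, 4, ..., 2^max_k` relative to the base period).
#' @param bisect_iter Bisection refinements per onset.
#' @return A list: `onsets` (parameter values of successive doublings),
#'   `accumulation` (the extrapolated estimate), `delta_hat` (estimated
#'   spacing ratio, `NA` when assumed universal).
#' @examples
#' # logistic map self-test: accumulation near 3.5699
#' \donttest{
#' logistic_period <- function(r) {
#'   x <- 0.5
#'   for (i in 1:900) x <- r * x * (1 - x)
#'   kept <- numeric(100)
#'   for (i in 1:100) { x <- r * x * (1 - x); kept[i] <- x }
#'   for (p in 1:64)
#'     if (max(abs(head(kept, -p) - tail(kept, -p))) < 1e-5) return(p)
#'   -1L
#' }
#' feigenbaum_estimate(logistic_period, c(2.9, 3.58))$accumulation
#' }
#' @export
feigenbaum_estimate <- function(period_fn, window, coarse_step = NULL,
                                max_k = 4L, bisect_iter = 24L) {
  stopifnot(length(window) == 2, window[1] != window[2])
  dir <- sign(window[2] - window[1])
  if (is.null(coarse_step)) coarse_step <- abs(diff(window)) / 60
  step <- dir * coarse_step

  # find the starting (lowest-period) plateau
  x <- window[1]
  p_cur <- period_fn(x)
  while ((p_cur <= 0L) && dir * (window[2] - x) > 0) {
    x <- x + step
    p_cur <- period_fn(x)
  }
  if (p_cur <= 0L) stop("no periodic attractor found in the window",
                        call. = FALSE)

  onsets <- numeric(0)
  while (length(onsets) < max_k && dir * (window[2] - x) > 0) {
    x_next <- x + step
    if (dir * (window[2] - x_next) < 0) x_next <- window[2]
    p_next <- period_fn(x_next)
    if (p_next == p_cur) {
      x <- x_next
      next
    }
    # period changed in (x, x_next]: bisect the doubling onset
    lo <- x; hi <- x_next
    for (i in seq_len(bisect_iter)) {
      mid <- (lo + hi) / 2
      if (period_fn(mid) == p_cur) lo <- mid else hi <- mid
    }
    onset <- (lo + hi) / 2
    p_at_hi <- period_fn(hi)
    if (p_at_hi == 2L * p_cur || p_at_hi %% (2L * p_cur) == 0L ||
        p_at_hi <= 0L) {
      onsets <- c(onsets, onset)
      if (p_at_hi == 2L * p_cur) {
        p_cur <- p_at_hi
        x <- hi
        step <- step / 2      # cascade compresses geometrically
        next
      }
    }
    break  # jumped past resolvable doublings (chaos or freeze ahead)
  }
  if (length(onsets) < 2L) {
    stop("no period-doubling cascade detected in the window", call. = FALSE)
  }
  d <- diff(onsets)
  nd <- length(d)
  if (nd >= 2 && abs(d[nd]) > 0) {
    delta_hat <- d[nd - 1] / d[nd]
    if (!is.finite(delta_hat) || delta_hat <= 1) delta_hat <- 4.669
  } else {
    delta_hat <- 4.669
  }
  accumulation <- onsets[length(onsets)] + d[nd] / (delta_hat - 1)
  list(onsets = onsets, accumulation = accumulation,
       delta_hat = if (nd >= 2) delta_hat else NA_real_)
}

#' @rdname feigenbaum_estimate
#' @param p A [gait_params()] object.
#' @param omega0 Initial angular velocity for every map evaluation.
#' @param phi_window Length-2 sweep window for the phase offset `phi`
#'   (rad); the sweep runs from `phi_window[1]` towards `phi_window[2]`.
#' @param n_total,n_keep,tol,max_period Passed to the attractor classifier.
#' @export
feigenbaum_point <- function(p, omega0, phi_window = c(-0.8, -2.4),
                             coarse_step = 0.02, max_k = 4L,
                             n_total = 500, n_keep = 50,
                             tol = 1e-5, max_period = 64L) {
  period_fn <- function(phi) {
    pi_ <- modify_params(p, phi = phi)
    classify_attractor(function(om) omega_map(om, pi_), omega0,
                       n_total, n_keep, tol, max_period)$period
  }
  feigenbaum_estimate(period_fn, phi_window, coarse_step, max_k)
}

#' Fixed-point / periodic-orbit contours over a parameter plane
#'
#' Evaluates [find_periodic_orbits()] on every cell of a two-parameter grid
#' and returns the orbit locations with their stability, from which contour
#' plots of period-1 (normal walking cycles) or period-3 (chaos indicator)
#' orbits are drawn.
#'
#' @param p A [gait_params()] object (base values).
#' @param param_x,param_y Names of the two swept fields.
#' @param grid_x,grid_y Numeric grids.
#' @param period Orbit period sought.
#' @param omega_range,n_scan Passed to [find_periodic_orbits()].
#' @return A tibble: `x`, `y` (parameter values), `omega`, `multiplier`,
#'   `stable`; one row per orbit found in each cell.
#' @export
fixed_point_contour <- function(p, param_x, param_y, grid_x, grid_y,
                                period = 1, omega_range = c(-1.2, -0.05),
                                n_scan = 400) {
  stopifnot(param_x %in% names(p), param_y %in% names(p))
  cells <- expand.grid(x = grid_x, y = grid_y)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    args <- stats::setNames(list(cells$x[i], cells$y[i]),
                            c(param_x, param_y))
    pi_ <- do.call(modify_params, c(list(p), args))
    orb <- find_periodic_orbits(pi_, period, omega_range, n_scan)
    if (!nrow(orb)) return(NULL)
    tibble::tibble(x = cells$x[i], y = cells$y[i], omega = orb$omega,
                   multiplier = orb$multiplier, stable = orb$stable)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "param_x") <- param_x
  attr(out, "param_y") <- param_y
  out
}

#' Walk-time heatmap over the forcing amplitudes
#'
#' Simulates the hybrid model over an observation window for every
#' combination of the two plantar-flexor amplitudes and records the walking
#' time before freezing ([walk_time_before_freeze()]). The resulting map
#' separates freezing (short walk) from sustained-walking parameter regions.
#'
#' @param p A [gait_params()] object (its `tau_l`, `tau_r` are ignored).
#' @param model `"pendulum"` or `"biped"`.
#' @param tau_l_grid,tau_r_grid Amplitude grids (N m / N).
#' @param x0 Initial state, as in [simulate_gait()].
#' @param window Observation window (s).
#' @param ... Passed to [simulate_gait()] (e.g. a coarser `dt`).
#' @return A tibble of class `gait_heatmap`: `tau_l`, `tau_r`, `walk_time`.
#' @export
freeze_time_heatmap <- function(p, model = c("pendulum", "biped"),
                                tau_l_grid, tau_r_grid, x0, window = 10,
                                ...) {
  model <- match.arg(model)
  cells <- expand.grid(tau_l = tau_l_grid, tau_r = tau_r_grid)
  wt <- vapply(seq_len(nrow(cells)), function(i) {
    pi_ <- modify_params(p, tau_l = cells$tau_l[i], tau_r = cells$tau_r[i])
    walk_time_before_freeze(pi_, model, x0, window, ...)
  }, numeric(1))
  out <- tibble::tibble(tau_l = cells$tau_l, tau_r = cells$tau_r,
                        walk_time = wt)
  class(out) <- c("gait_heatmap", class(out))
  attr(out, "window") <- window
  out
}

#' Calibrate the inertia scale against a known outcome
#'
#' The body mass (hence the inertia `m1 * l^2` dividing the muscle torques)
#' is not identifiable from the model structure alone, and the leg length
#' only enters the reduced model through `g/l` and the push-off moment arm.
#' This utility grid-searches the inertia scale (optionally jointly with
#' `l`) to minimise the absolute difference between a computed outcome and
#' a reference value, and reports every candidate with its residual — the
#' residual is part of the result, never hidden.
#'
#' Two target quantities are built in: `"feigenbaum"` (the accumulation
#' point of the period-doubling cascade of the stride map under the
#' parameters in `p`, via [feigenbaum_point()]) and `"freeze_time"` (the
#' freeze onset time of the hybrid pendulum simulation started at
#' `omega0`).
#'
#' @param p A [gait_params()] object carrying the experiment parameters.
#' @param target `"feigenbaum"` or `"freeze_time"`.
#' @param reference The known outcome to match (rad for `"feigenbaum"`,
#'   s for `"freeze_time"`).
#' @param inertia_grid Candidate inertia scales `m1 * l^2` (N m s^2). The
#'   default spans the physiological body-mass range (roughly 40-110 kg at
#'   leg lengths near 0.6 m).
#' @param l_grid Optional candidate leg lengths (m); default keeps `p$l`.
#' @param omega0 Initial angular velocity (rad s^-1).
#' @param t_horizon Simulation horizon (s) for `"freeze_time"`.
#' @param ... Passed to [feigenbaum_point()] for the `"feigenbaum"` target.
#' @return A tibble of class `gait_calibration`: `l`, `inertia`, `value`,
#'   `residual`, ordered as evaluated, with the best candidate in
#'   `attr(, "best")`.
#' @export
calibration_sweep <- function(p, target = c("feigenbaum", "freeze_time"),
                              reference,
                              inertia_grid = seq(15, 40, by = 2.5),
                              l_grid = NULL, omega0 = -0.433,
                              t_horizon = 40, ...) {
  target <- match.arg(target)
  stopifnot(is.numeric(reference), length(reference) == 1)
  if (is.null(l_grid)) l_grid <- p$l
  cand <- expand.grid(l = l_grid, inertia = inertia_grid)
  vals <- vapply(seq_len(nrow(cand)), function(i) {
    pi_ <- set_inertia(modify_params(p, l = cand$l[i]), cand$inertia[i])
    if (target == "feigenbaum") {
      est <- tryCatch(feigenbaum_point(pi_, omega0, ...),
                      error = function(e) NULL)
      if (is.null(est)) NA_real_ else est$accumulation
    } else {
      sim <- simulate_gait(pi_, "pendulum", x0 = omega0,
                           t_max = t_horizon, dt = 0.01)
      if (sim$froze) sim$t_freeze else NA_real_
    }
  }, numeric(1))
  out <- tibble::tibble(l = cand$l, inertia = cand$inertia, value = vals,
                        residual = abs(vals - reference))
  class(out) <- c("gait_calibration", class(out))
  ok <- which(is.finite(out$residual))
  attr(out, "best") <- if (length(ok)) out[ok[which.min(out$residual[ok])], ]
                       else out[0, ]
  attr(out, "target") <- target
  attr(out, "reference") <- reference
  out
}
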