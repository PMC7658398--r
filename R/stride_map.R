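# One stance phase evaluated on the analytic flow. Scans forward in time in
# chunks for the first event — either the reset crossing theta = theta_reset
# (heel strike) or an upward zero crossing of omega while theta > theta_reset
# (freeze) — then refines the event time by Newton's method seeded from the
# bracket midpoint, with bisection as fallback. Chunked scanning keeps the
# grid fine (~2.4 ms) without paying for the full horizon on every call.
stride_step <- function(omega, p, theta_n = abs(p$theta_reset),
                        t_scan = 5, chunk = 0.625, n_chunk = 256L) {
  stopifnot(omega < 0, theta_n > 0)
  co <- flow_coefficients(theta_n, omega, p)
  th_fun <- function(t) flow_theta(t, theta_n, omega, p, co)
  om_fun <- function(t) flow_omega(t, theta_n, omega, p, co)

  t_lo <- 0
  th_prev <- theta_n
  om_prev <- omega
  while (t_lo < t_scan - 1e-12) {
    t_hi <- min(t_lo + chunk, t_scan)
    tg <- seq(t_lo, t_hi, length.out = n_chunk + 1L)[-1L]
    th <- th_fun(tg)
    om <- om_fun(tg)
    tg_all <- c(t_lo, tg)
    th_all <- c(th_prev, th)
    om_all <- c(om_prev, om)
    nn <- length(tg_all)
    hit <- which(th_all[-nn] > p$theta_reset & th_all[-1] <= p$theta_reset)
    up  <- which(om_all[-nn] < 0 & om_all[-1] >= 0 &
                   th_all[-nn] > p$theta_reset)
    i_hit <- if (length(hit)) hit[1] else Inf
    i_up  <- if (length(up)) up[1] else Inf
    if (i_up < i_hit) {
      t_fr <- refine_root(om_fun, tg_all[i_up], tg_all[i_up + 1],
                          deriv = NULL)
      return(list(frozen = TRUE, reset_time = NA_real_, omega_end = NA_real_,
                  t_freeze = t_fr, converged = TRUE))
    }
    if (is.finite(i_hit)) {
      tr <- refine_root(function(t) th_fun(t) - p$theta_reset,
                        tg_all[i_hit], tg_all[i_hit + 1], deriv = om_fun)
      resid <- abs(th_fun(tr) - p$theta_reset)
      return(list(frozen = FALSE, reset_time = tr,
                  omega_end = om_fun(tr), t_freeze = NA_real_,
                  converged = resid <= 1e-10))
    }
    t_lo <- t_hi
    th_prev <- th[length(th)]
    om_prev <- om[length(om)]
  }
  # no event inside the scan horizon: pathological non-progression
  list(frozen = TRUE, reset_time = NA_real_, omega_end = NA_real_,
       t_freeze = t_scan, converged = TRUE)
}

# Newton from the bracket midpoint with bisection fallback; the bracket
# [lo, hi] is assumed to contain a sign change of f.
refine_root <- function(f, lo, hi, deriv = NULL, tol = 1e-13, max_iter = 50L) {
  if (!is.null(deriv)) {
    t <- (lo + hi) / 2
    for (i in seq_len(max_iter)) {
      ft <- f(t)
      if (abs(ft) < tol) return(t)
      d <- deriv(t)
      if (d == 0) break
      t_new <- t - ft / d
      if (t_new <= lo || t_new >= hi) break  # left the bracket: fall back
      if (abs(t_new - t) < 1e-15) return(t_new)
      t <- t_new
    }
  }
  stats::uniroot(f, c(lo, hi), tol = 1e-14)$root
}

#' Reset time of a stance phase (analytic flow)
#'
#' The smallest `t > 0` at which the analytic stance flow started at
#' `(theta_n, omega_n)` reaches the reset angle `theta_reset` — the moment
#' the swing heel meets the ground. Returns `NA` (the FREEZE value) when the
#' stance leg stalls first: the angular velocity crosses zero from below
#' while the angle is still above `theta_reset`.
#'
#' @param omega_n Stance angular velocity at step start (rad s^-1, negative).
#' @param p A [gait_params()] object.
#' @param theta_n Stance angle at step start (rad); defaults to
#'   `|theta_reset|`, the fixed-step-length convention under which the
#'   stride map is one-dimensional.
#' @param t_scan Scan horizon (s) for the first event.
#' @return Reset time (s), or `NA` for a freeze.
#' @examples
#' p <- gait_params()          # unforced
#' reset_time(-0.5, p)         # crosses: |omega0| > sqrt(g/l)*theta0
#' reset_time(-0.3, p)         # NA: freezes
#' @export
reset_time <- function(omega_n, p, theta_n = abs(p$theta_reset), t_scan = 5) {
  vapply(omega_n, function(om) {
    st <- stride_step(om, p, theta_n, t_scan)
    if (!st$frozen && !st$converged) {
      stop("reset-time refinement failed to converge", call. = FALSE)
    }
    st$reset_time
  }, numeric(1))
}

#' The one-dimensional stride return map
#'
#' Maps the stance angular velocity at the start of one step to the start of
#' the next, at fixed step length `|theta_reset|`: the analytic flow is run
#' to its reset time and the heel-strike rule `omega -> omega * cos(theta_h)`
#' is applied. `NA` is the explicit FREEZE value (not an error), so
#' iteration, tabulation and plotting handle frozen inputs uniformly.
#'
#' @inheritParams reset_time
#' @return Next-step angular velocity (rad s^-1), `NA` if the step freezes.
#'   Vectorised over `omega_n`.
#' @examples
#' p <- gait_params(tau_l = 5, tau_r = 35, phi = -1.57, m1 = 25 / 0.36)
#' omega_map(-0.433, p)
#' @export
omega_map <- function(omega_n, p, theta_n = abs(p$theta_reset), t_scan = 5) {
  vapply(omega_n, function(om) {
    st <- stride_step(om, p, theta_n, t_scan)
    if (st$frozen) NA_real_ else st$omega_end * cos(p$theta_h)
  }, numeric(1))
}

#' Evaluate the stride map over a grid (map table)
#'
#' @param omega_grid Vector of input angular velocities (rad s^-1, negative).
#' @param p A [gait_params()] object.
#' @return A tibble with columns `omega_in`, `omega_out`, `reset_time`,
#'   `frozen`, ready for plotting map curves or export.
#' @seealso [plot_stride_map()]
#' @export
map_table <- function(omega_grid, p) {
  rows <- lapply(omega_grid, function(om) {
    st <- stride_step(om, p)
    tibble::tibble(omega_in = om,
                   omega_out = if (st$frozen) NA_real_
                               else st$omega_end * cos(p$theta_h),
                   reset_time = st$reset_time,
                   frozen = st$frozen)
  })
  dplyr::bind_rows(rows)
}

#' Iterate the stride map
#'
#' @param omega0 Starting angular velocity (rad s^-1, negative).
#' @param n_steps Number of iterates requested.
#' @param p A [gait_params()] object.
#' @return Numeric vector of successive angular velocities, truncated at the
#'   first freeze (the freeze itself is not included).
#' @examples
#' p <- gait_params(theta_h = 0.2)   # unforced, dissipative
#' iterate_map(-0.6, 20, p)          # geometric decay, then freeze
#' @export
iterate_map <- function(omega0, n_steps, p) {
  stopifnot(n_steps >= 1)
  out <- numeric(n_steps)
  om <- omega0
  for (i in seq_len(n_steps)) {
    om <- omega_map(om, p)
    if (is.na(om)) return(out[seq_len(i - 1L)])
    out[i] <- om
  }
  out
}

#' Composed stride map and its derivative
#'
#' `composed_map()` applies the stride map `period` times;
#' `map_derivative()` differentiates the composition numerically (central
#' difference) to give the orbit multiplier used for stability
#' classification: a period-p orbit is stable iff the magnitude of the
#' derivative of the p-fold composition at any of its points is below 1.
#'
#' @param omega Input angular velocity (rad s^-1, negative).
#' @param period Number of compositions (positive integer).
#' @param p A [gait_params()] object.
#' @param h Central-difference step (rad s^-1).
#' @return `composed_map`: the composed value (`NA` if any intermediate step
#'   freezes); `map_derivative`: the numerical derivative.
#' @export
composed_map <- function(omega, period, p) {
  stopifnot(period >= 1)
  vapply(omega, function(om) {
    for (i in seq_len(period)) {
      om <- omega_map(om, p)
      if (is.na(om)) return(NA_real_)
    }
    om
  }, numeric(1))
}

#' @rdname composed_map
#' @export
map_derivative <- function(omega, period, p, h = 1e-5) {
  (composed_map(omega + h, period, p) - composed_map(omega - h, period, p)) /
    (2 * h)
}

#' Find periodic orbits of the stride map
#'
#' Scans `composed_map(omega, period) - omega` for sign changes on a dense
#' grid, refines each bracket by bisection, drops roots whose minimal period
#' is a proper divisor of `period`, groups the surviving fixed points into
#' orbits, and labels each orbit with its multiplier. The map is
#' piecewise-smooth with discontinuities (branch switches of the first
#' reset-crossing), so dense bracketing before refinement is essential and
#' apparent roots at discontinuities are discarded by a residual check.
#'
#' @param p A [gait_params()] object.
#' @param period Orbit period sought (1, 2, 3, ...).
#' @param omega_range Scan window (rad s^-1), within the physiological
#'   range; both endpoints negative.
#' @param n_scan Number of scan-grid points.
#' @param root_tol Residual tolerance for accepting a refined root.
#' @return A tibble with one row per orbit: `period`, `omega` (first point),
#'   `points` (list column of the full orbit), `multiplier`, `stable`.
#'   Zero rows when no orbit exists.
#' @examples
#' p <- gait_params(theta_h = 0.2)
#' find_periodic_orbits(p, 1, c(-1, -0.3))   # unforced: no fixed point
#' @export
find_periodic_orbits <- function(p, period = 1, omega_range = c(-3, -0.05),
                                 n_scan = 2000, root_tol = 1e-8) {
  stopifnot(period >= 1, all(omega_range < 0))
  grid <- seq(min(omega_range), max(omega_range), length.out = n_scan)
  gv <- composed_map(grid, period, p) - grid
  roots <- c()
  for (i in seq_len(n_scan - 1L)) {
    if (is.na(gv[i]) || is.na(gv[i + 1])) next
    if (gv[i] == 0) roots <- c(roots, grid[i])
    if (gv[i] * gv[i + 1] < 0) {
      f <- function(om) composed_map(om, period, p) - om
      r <- tryCatch(stats::uniroot(f, c(grid[i], grid[i + 1]), tol = 1e-12),
                    error = function(e) NULL)
      if (!is.null(r) && is.finite(r$f.root) && abs(r$f.root) <= root_tol) {
        roots <- c(roots, r$root)
      }
    }
  }
  if (!length(roots)) return(empty_orbits())
  roots <- sort(unique(roots))
  # minimal-period filter: drop roots fixed by a proper divisor composition
  divisors <- setdiff(Filter(function(d) period %% d == 0, seq_len(period)),
                      period)
  minimal <- vapply(roots, function(om) {
    !any(vapply(divisors, function(d) {
      v <- composed_map(om, d, p)
      !is.na(v) && abs(v - om) <= 1e-6
    }, logical(1)))
  }, logical(1))
  roots <- roots[minimal]
  if (!length(roots)) return(empty_orbits())
  # group points that lie on the same orbit
  taken <- rep(FALSE, length(roots))
  out <- list()
  for (j in seq_along(roots)) {
    if (taken[j]) next
    om <- roots[j]
    pts <- numeric(period)
    pts[1] <- om
    cur <- om
    ok <- TRUE
    for (s in seq_len(period - 1L)) {
      cur <- omega_map(cur, p)
      if (is.na(cur)) { ok <- FALSE; break }
      pts[s + 1L] <- cur
    }
    if (!ok) next
    taken[j] <- TRUE
    for (q in seq_along(roots)) {
      if (!taken[q] && any(abs(roots[q] - pts) < 1e-6)) taken[q] <- TRUE
    }
    mult <- map_derivative(om, period, p)
    out[[length(out) + 1L]] <- tibble::tibble(
      period = as.integer(period), omega = om, points = list(pts),
      multiplier = mult, stable = is.finite(mult) && abs(mult) < 1)
  }
  if (!length(out)) return(empty_orbits())
  dplyr::bind_rows(out)
}

empty_orbits <- function() {
  tibble::tibble(period = integer(), omega = numeric(), points = list(),
                 multiplier = numeric(), stable = logical())
}
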