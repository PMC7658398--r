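#' Simulate a hybrid gait model
#'
#' Event-driven integration of the forced biped or inverted-pendulum stance
#' dynamics: the continuous flow is integrated with `deSolve::lsodar`, whose
#' internal root finding locates the heel-strike guard independently of the
#' output sampling grid; the discrete reset map is applied at each strike,
#' and integration resumes. Under the default per-step forcing clock the
#' muscle forcing restarts at every heel strike, so that successive stance
#' phases are iterates of one autonomous stride map.
#'
#' A *freeze* is declared the first time the stance angular velocity crosses
#' zero from below mid-stance (no forward progression; gravity subsequently
#' pulls the leg backward). A per-step timeout is kept as a backstop for
#' pathological non-progression without a zero crossing. Simulation ends at
#' the first freeze or at the time horizon.
#'
#' @param p A [gait_params()] object.
#' @param model `"pendulum"` or `"biped"`.
#' @param x0 Initial state: a [pendulum_state()] or [biped_state()]. For the
#'   pendulum, a single number is accepted and taken as the initial angular
#'   velocity with `theta0 = |theta_reset|` (the start-of-stance angle).
#' @param t_max Time horizon (s).
#' @param dt Dense-output sampling interval (s) for the returned trajectory.
#'   Event location does not depend on it.
#' @param step_timeout Maximum duration of a single stance phase (s) before
#'   it is classified as a freeze; a physiological stance lasts well under
#'   1.5 s.
#' @param rtol,atol Relative/absolute integration tolerances.
#' @param max_steps Safety cap on the number of stance phases.
#' @return An object of class `gait_sim`: a list with
#'   \describe{
#'     \item{steps}{tibble of stance-phase records: `index` (0-based),
#'       `t_start`, `t_end`, start/end state columns, and `ended_by`
#'       (one of `heel_strike`, `freeze`, `horizon`).}
#'     \item{trajectory}{tibble of dense samples: `t`, state columns,
#'       `step_index`, `phase_time` (time on the forcing clock).}
#'     \item{froze, t_freeze, t_last_heel_strike, n_steps}{freeze report;
#'       `n_steps` counts completed heel strikes.}
#'   }
#' @examples
#' p <- gait_params(tau_l = 2, tau_r = 11, phi = -pi / 2)
#' sim <- simulate_gait(p, "pendulum", x0 = -1, t_max = 5)
#' glance(sim)
#' @export
simulate_gait <- function(p, model = c("pendulum", "biped"), x0,
                          t_max = 10, dt = 1e-3, step_timeout = 5,
                          rtol = 1e-9, atol = 1e-11, max_steps = 100000L) {
  model <- match.arg(model)
  stopifnot(t_max > 0, dt > 0, step_timeout > 0)
  if (model == "pendulum") {
    if (length(x0) == 1 && is.null(names(x0))) {
      x0 <- pendulum_state(abs(p$theta_reset), as.numeric(x0))
    }
    stopifnot(all(c("theta", "omega") %in% names(x0)))
  } else {
    stopifnot(all(c("theta1", "theta2", "omega1", "omega2") %in% names(x0)))
  }
  stopifnot(all(is.finite(x0)))

  ang <- if (model == "pendulum") "theta" else "theta1"
  vel <- if (model == "pendulum") "omega" else "omega1"

  deriv <- function(t, y, parms) {
    tt <- if (p$clock == "step") t else t + parms$t0
    list(if (model == "pendulum") pendulum_field(tt, y, p)
         else biped_field_forced(tt, y, p))
  }
  rootfun <- function(t, y, parms) {
    if (model == "pendulum") c(y[["theta"]] - p$theta_reset, y[["omega"]])
    else c(y[["theta1"]] + y[["theta2"]], y[["omega1"]])
  }

  steps <- list()
  traj <- list()
  t_now <- 0
  x <- x0
  froze <- FALSE
  t_freeze <- NA_real_
  t_last_hs <- NA_real_
  n_hs <- 0L
  step_idx <- 0L

  while (t_now < t_max - 1e-12 && step_idx < max_steps) {
    horizon_left <- t_max - t_now
    t_step_max <- min(step_timeout, horizon_left)
    seg <- integrate_stance(x, deriv, rootfun, t_step_max, dt,
                            rtol, atol, model, p, t_now)
    seg_tb <- seg$samples
    seg_tb$t <- seg_tb$phase_time + t_now
    seg_tb$step_index <- step_idx
    traj[[length(traj) + 1L]] <- seg_tb

    x_end <- seg$state_end
    t_end <- t_now + seg$t_end
    ended_by <- seg$ended_by
    if (ended_by == "timeout") ended_by <- "freeze"
    if (ended_by == "none") {
      ended_by <- if (t_step_max < horizon_left - 1e-12) "freeze" else "horizon"
    }

    steps[[length(steps) + 1L]] <- step_row(step_idx, t_now, t_end, x, x_end,
                                            ended_by, model)
    if (ended_by == "freeze") {
      froze <- TRUE
      t_freeze <- t_end
      t_now <- t_end
      break
    }
    if (ended_by == "horizon") {
      t_now <- t_end
      break
    }
    # heel strike: apply reset map and continue
    n_hs <- n_hs + 1L
    t_last_hs <- t_end
    x <- if (model == "pendulum") {
      pendulum_reset(pendulum_state(p$theta_reset, x_end[[vel]]), p)
    } else {
      biped_reset(biped_state(x_end[["theta1"]], -x_end[["theta1"]],
                              x_end[["omega1"]], x_end[["omega2"]]), p)
    }
    t_now <- t_end
    step_idx <- step_idx + 1L
  }

  structure(list(
    steps = dplyr::bind_rows(steps),
    trajectory = dplyr::bind_rows(traj),
    froze = froze,
    t_freeze = t_freeze,
    t_last_heel_strike = t_last_hs,
    n_steps = n_hs,
    model = model,
    params = p
  ), class = "gait_sim")
}

# One stance phase in local (phase) time from 0. Returns samples, end state,
# local end time and how the phase ended: heel_strike / freeze / timeout / none.
integrate_stance <- function(x, deriv, rootfun, t_step_max, dt,
                             rtol, atol, model, p, t0_global) {
  ang <- if (model == "pendulum") "theta" else "theta1"
  vel <- if (model == "pendulum") "omega" else "omega1"
  parms <- list(t0 = t0_global)
  t_local <- 0
  x_cur <- x
  pieces <- list()
  repeat {
    times <- unique(c(seq(0, t_step_max - t_local, by = dt),
                      t_step_max - t_local))
    if (length(times) < 2) times <- c(0, t_step_max - t_local)
    d2 <- function(t, y, parms2) deriv(t + t_local, y, parms)
    r2 <- function(t, y, parms2) rootfun(t + t_local, y, parms)
    out <- deSolve::lsodar(y = x_cur, times = times, func = d2, parms = NULL,
                           rootfunc = r2, rtol = rtol, atol = atol)
    m <- as.data.frame(out)
    names(m)[1] <- "phase_time"
    m$phase_time <- m$phase_time + t_local
    pieces[[length(pieces) + 1L]] <- m
    t_root <- m$phase_time[nrow(m)]
    y_end <- as.numeric(m[nrow(m), names(x_cur) , drop = TRUE])
    names(y_end) <- names(x_cur)
    istate <- attr(out, "istate")[1]
    if (is.na(istate) || istate != 3) {         # no root: ran to end of times
      done <- if (t_root >= t_step_max - 1e-12) "none" else "timeout"
      return(list(samples = finish_samples(pieces), state_end = y_end,
                  t_end = t_root, ended_by = done))
    }
    g <- rootfun(t_root, y_end, parms)
    guard_hit <- abs(g[1]) <= 1e-7
    vel_zero <- abs(y_end[[vel]]) <= 1e-7
    if (guard_hit && (model == "pendulum" || y_end[["theta1"]] < 0)) {
      return(list(samples = finish_samples(pieces), state_end = y_end,
                  t_end = t_root, ended_by = "heel_strike"))
    }
    if (vel_zero) {
      # freeze only on an upward crossing (leg stalls while moving forward)
      dy <- deriv(t_root, y_end, parms)[[1]]
      dvel <- dy[[vel]]
      if (dvel > 0) {
        return(list(samples = finish_samples(pieces), state_end = y_end,
                    t_end = t_root, ended_by = "freeze"))
      }
    }
    # spurious root (biped guard crossing with theta1 >= 0, or a downward
    # velocity crossing): nudge past it and resume
    h <- 1e-8
    f <- deriv(t_root, y_end, parms)[[1]]
    x_cur <- y_end + h * f[names(y_end)]
    t_local <- t_root + h
    if (t_local >= t_step_max - 1e-12) {
      return(list(samples = finish_samples(pieces), state_end = x_cur,
                  t_end = t_local, ended_by = "none"))
    }
  }
}

finish_samples <- function(pieces) {
  tb <- tibble::as_tibble(dplyr::bind_rows(pieces))
  tb[!duplicated(tb$phase_time), ]
}

step_row <- function(idx, t_start, t_end, x_start, x_end, ended_by, model) {
  if (model == "pendulum") {
    tibble::tibble(index = idx, t_start = t_start, t_end = t_end,
                   theta_start = x_start[["theta"]], omega_start = x_start[["omega"]],
                   theta_end = x_end[["theta"]], omega_end = x_end[["omega"]],
                   ended_by = ended_by)
  } else {
    tibble::tibble(index = idx, t_start = t_start, t_end = t_end,
                   theta1_start = x_start[["theta1"]], theta2_start = x_start[["theta2"]],
                   omega1_start = x_start[["omega1"]], omega2_start = x_start[["omega2"]],
                   theta1_end = x_end[["theta1"]], theta2_end = x_end[["theta2"]],
                   omega1_end = x_end[["omega1"]], omega2_end = x_end[["omega2"]],
                   ended_by = ended_by)
  }
}

#' Locate a freeze in a sampled stance trajectory
#'
#' Scans a dense (t, theta, omega) record of a single stance phase for the
#' first time the angular velocity crosses zero from below while the stance
#' angle is still above the reset angle — the defining signature of a
#' freeze (forward progression stops; the leg then falls backward under
#' gravity). The crossing time is refined by linear interpolation between
#' samples.
#'
#' @param trajectory A data frame with columns `t`, `theta` (or `theta1`)
#'   and `omega` (or `omega1`).
#' @param p A [gait_params()] object.
#' @return A one-row tibble with `froze` (logical) and `t_freeze`
#'   (s, `NA` if no freeze).
#' @examples
#' p <- gait_params()  # unforced: a slow start stalls before vertical
#' sim <- simulate_gait(p, "pendulum", x0 = -0.3, t_max = 2)
#' detect_freeze(sim$trajectory, p)
#' @export
detect_freeze <- function(trajectory, p) {
  tb <- as.data.frame(trajectory)
  th <- if ("theta" %in% names(tb)) tb$theta else tb$theta1
  om <- if ("omega" %in% names(tb)) tb$omega else tb$omega1
  stopifnot(!is.null(th), !is.null(om), nrow(tb) > 1)
  i <- which(om[-length(om)] < 0 & om[-1] >= 0 &
               th[-length(th)] > p$theta_reset)
  if (!length(i)) {
    return(tibble::tibble(froze = FALSE, t_freeze = NA_real_))
  }
  i <- i[1]
  w <- om[i] / (om[i] - om[i + 1])
  tibble::tibble(froze = TRUE,
                 t_freeze = tb$t[i] + w * (tb$t[i + 1] - tb$t[i]))
}

#' Walking time before a freeze
#'
#' Runs a simulation over a fixed window and reports the time walked: the
#' time of the last heel strike before the freezing event if the model
#' froze within the window (0 if it froze before any heel strike), or the
#' full window length otherwise. In a 10 s window, 9 s or more of walking
#' indicates a non-freezing parameter combination.
#'
#' @param p A [gait_params()] object.
#' @param model `"pendulum"` or `"biped"`.
#' @param x0 Initial state, as in [simulate_gait()].
#' @param window Observation window (s).
#' @param ... Passed to [simulate_gait()].
#' @return Walking time (s).
#' @export
walk_time_before_freeze <- function(p, model = c("pendulum", "biped"), x0,
                                    window = 10, ...) {
  stopifnot(window > 0)
  sim <- simulate_gait(p, model, x0, t_max = window, ...)
  if (!sim$froze) return(window)
  if (is.na(sim$t_last_heel_strike)) return(0)
  sim$t_last_heel_strike
}

#' @export
print.gait_sim <- function(x, ...) {
  cat(sprintf("<gait_sim: %s model, %d heel strike(s)>\n", x$model, x$n_steps))
  if (x$froze) {
    cat(sprintf("  froze at t = %.4g s (last heel strike %s)\n", x$t_freeze,
                if (is.na(x$t_last_heel_strike)) "never"
                else sprintf("at %.4g s", x$t_last_heel_strike)))
  } else {
    cat(sprintf("  walked the full horizon (%.4g s)\n",
                max(x$trajectory$t)))
  }
  invisible(x)
}

#' Tidy / summarise a simulation
#'
#' `tidy()` returns the per-stance-phase step records; `glance()` a one-row
#' summary (freeze flag and times, heel-strike count, mean stance duration).
#'
#' @param x A `gait_sim` object.
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.gait_sim <- function(x, ...) x$steps

#' @rdname tidy.gait_sim
#' @exportS3Method generics::glance
glance.gait_sim <- function(x, ...) {
  hs <- x$steps[x$steps$ended_by == "heel_strike", ]
  tibble::tibble(
    model = x$model,
    n_steps = x$n_steps,
    froze = x$froze,
    t_freeze = x$t_freeze,
    t_last_heel_strike = x$t_last_heel_strike,
    mean_stance_duration = if (nrow(hs)) mean(hs$t_end - hs$t_start) else NA_real_
  )
}
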