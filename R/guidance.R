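#' Piecewise-constant shear schedule
#'
#' Time-dependent background shear rate gamma_d(t) for guidance experiments:
#' constant on each interval between breakpoints.
#'
#' @param times breakpoint times, seconds, starting at 0, strictly
#'   increasing.
#' @param rates shear rate on each interval, 1/s (same length as times).
#' @return a `shear_schedule`.
#' @export
shear_schedule <- function(times, rates) {
  if (length(times) != length(rates))
    stop("times and rates must have equal length")
  if (any(diff(times) <= 0)) stop("breakpoint times must be increasing")
  if (any(!is.finite(rates))) stop("rates must be finite")
  structure(list(times = times, rates = rates), class = "shear_schedule")
}

#' Shear rate of a schedule at time t
#' @param schedule a [shear_schedule()].
#' @param t time(s), seconds.
#' @return gamma_d(t), 1/s.
#' @export
schedule_rate <- function(schedule, t) {
  idx <- findInterval(t, schedule$times, rightmost.closed = FALSE)
  idx[idx < 1] <- 1
  schedule$rates[idx]
}

#' Sample initial orientations
#'
#' Either uniform on `[0, 2 pi)` or weighted by the residence-time density
#' of a Jeffery orbit, `p(theta) proportional to 1/thetadot(theta)` (the
#' fraction of orbit time spent near each orientation), sampled by inverse
#' transform on a fine grid.
#'
#' @param n sample count.
#' @param mode "uniform" or "jeffery".
#' @param r aspect ratio for the Jeffery weighting.
#' @param seed integer seed (all randomness in the package is seeded).
#' @return vector of n orientations, radians.
#' @export
sample_orientations <- function(n, mode = c("uniform", "jeffery"), r = NULL,
                                seed = 1) {
  mode <- match.arg(mode)
  if (n < 1) stop("n must be at least 1")
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  u <- stats::runif(n)
  if (mode == "uniform") return(2 * pi * u)
  if (is.null(r)) stop("jeffery mode requires an aspect ratio r")
  grid <- seq(0, 2 * pi, length.out = 4097)
  w <- 1 / jeffery_rate(grid, r, 1)
  if (any(!is.finite(w) | w <= 0))
    stop("non-positive rotation rate: residence density undefined")
  cdf <- cumsum(c(0, (w[-1] + w[-4097]) / 2 * diff(grid)))
  cdf <- cdf / cdf[4097]
  stats::approx(cdf, grid, xout = u, ties = "ordered")$y
}

#' Endpoints of an ensemble of phase-averaged bulk trajectories
#'
#' Integrates the reduced planar system (orientation from the phase-averaged
#' rotation rate, position from the phase-averaged swimming velocity plus
#' background shear advection) for swimmers released at the origin with
#' sampled initial orientations.
#'
#' @param field a [bulk_phase_field()].
#' @param n number of swimmers.
#' @param duration simulated time, seconds.
#' @param gamma_d shear rate, 1/s.
#' @param mode initial-orientation distribution, "uniform" or "jeffery".
#' @param seed integer seed.
#' @param r aspect ratio for the Jeffery weighting (default: fitted from
#'   the field's rotation period at gamma_d).
#' @return data frame (theta0, x1, x2, theta_end) with one row per swimmer;
#'   sampling metadata in attributes.
#' @export
ensemble_endpoints <- function(field, n, duration = 2, gamma_d = 1,
                               mode = c("uniform", "jeffery"), seed = 1,
                               r = NULL) {
  mode <- match.arg(mode)
  if (mode == "jeffery" && is.null(r)) {
    Td <- rotation_period(field, gamma_d)
    r <- fit_jeffery_ratio(data.frame(gamma_d = gamma_d, T_d = Td))$r
  }
  th0 <- sample_orientations(n, mode, r, seed)
  spT <- .periodic_spline(field$theta, field$Oshear[, 3])
  spU <- lapply(1:3, function(i)
    .periodic_spline(field$theta, field$Ushear[, i]))
  rhs <- function(t, y, parms) {
    th <- y[1] %% (2 * pi)
    Usw <- field$Uswim + gamma_d * c(spU[[1]](th), spU[[2]](th), spU[[3]](th))
    Ul <- .rot_z(th) %*% Usw
    list(c(-(field$Oswim[3] + gamma_d * spT(th)),
           Ul[1] + gamma_d * y[3], Ul[2]))
  }
  ends <- vapply(th0, function(t0) {
    out <- deSolve::ode(c(t0, 0, 0), c(0, duration), rhs, NULL,
                        method = "lsoda", rtol = 1e-8, atol = 1e-8)
    out[nrow(out), 2:4]
  }, numeric(3))
  res <- data.frame(theta0 = th0, x1 = ends[2, ], x2 = ends[3, ],
                    theta_end = ends[1, ] %% (2 * pi))
  attr(res, "mode") <- mode
  attr(res, "seed") <- seed
  attr(res, "gamma_d") <- gamma_d
  attr(res, "duration") <- duration
  res
}

#' Plan a shear schedule for straight-line guidance
#'
#' In bulk shear the swimmer tumbles with period T_d(gamma). Reversing the
#' shear each half period folds the orbit back on itself, so the
#' phase-averaged path repeats one lobe per reversal and progresses along
#' the flow axis: the first reversal falls at T_d/2 and subsequent
#' reversals every T_d/2 thereafter.
#'
#' @param fit a [fit_jeffery_ratio()] result (or a list with `r`).
#' @param gamma_mag magnitude of the shear rate, 1/s.
#' @param duration schedule horizon, seconds.
#' @param direction +1 to guide along +x1-hat, -1 for the reverse.
#' @return a [shear_schedule()].
#' @export
plan_schedule <- function(fit, gamma_mag, duration, direction = 1) {
  if (gamma_mag <= 0) stop("gamma_mag must be positive (tumbling regime)")
  Td <- jeffery_period(fit$r, gamma_mag)
  sw <- seq(Td / 2, duration, by = Td / 2)
  times <- c(0, sw)
  rates <- direction * gamma_mag * (-1)^(seq_along(times) - 1)
  shear_schedule(times[times < duration], rates[times < duration])
}

#' Reduced-dynamics path under a shear schedule
#'
#' Integrates the phase-averaged bulk system with a piecewise-constant
#' shear schedule (used as the cheap prediction against which the full
#' boundary-element simulation is compared).
#'
#' @param field a [bulk_phase_field()].
#' @param schedule a [shear_schedule()].
#' @param duration horizon, seconds.
#' @param theta0 initial orientation.
#' @param dt_out output spacing, seconds.
#' @return data frame (t, theta, x1, x2).
#' @export
reduced_guided_path <- function(field, schedule, duration, theta0 = 0,
                                dt_out = 0.02) {
  spT <- .periodic_spline(field$theta, field$Oshear[, 3])
  spU <- lapply(1:3, function(i)
    .periodic_spline(field$theta, field$Ushear[, i]))
  rhs <- function(t, y, parms) {
    g <- schedule_rate(schedule, t)
    th <- y[1] %% (2 * pi)
    Usw <- field$Uswim + g * c(spU[[1]](th), spU[[2]](th), spU[[3]](th))
    Ul <- .rot_z(th) %*% Usw
    list(c(-(field$Oswim[3] + g * spT(th)), Ul[1] + g * y[3], Ul[2]))
  }
  # integrate piecewise between schedule breakpoints (rhs is discontinuous)
  brk <- c(schedule$times[schedule$times < duration], duration)
  y <- c(theta0, 0, 0)
  segs <- list()
  for (k in seq_len(length(brk) - 1)) {
    times <- unique(c(seq(brk[k], brk[k + 1], by = dt_out), brk[k + 1]))
    out <- deSolve::ode(y, times, rhs, NULL, method = "lsoda",
                        rtol = 1e-9, atol = 1e-9)
    segs[[k]] <- as.data.frame(out)
    y <- as.numeric(out[nrow(out), 2:4])
  }
  out <- do.call(rbind, segs)
  names(out) <- c("t", "theta", "x1", "x2")
  out[!duplicated(out$t), ]
}

#' Full simulation against the phase-averaged prediction under a schedule
#'
#' Runs the time-stepped boundary-element simulation and the reduced
#' phase-averaged integration under the same time-dependent shear, and
#' reports the pointwise path discrepancy normalised by path length.
#'
#' @param field a [bulk_phase_field()].
#' @param schedule a [shear_schedule()].
#' @param duration horizon, seconds.
#' @param config a [swimmer_config()].
#' @param dt full-simulation time step (default beat period / 100).
#' @param refinement mesh refinement for the full simulation.
#' @param mu viscosity, Pa s.
#' @return list with `full` (trajectory states), `reduced` (data frame),
#'   `endpoint_discrepancy`, `path_length`, `relative_discrepancy`.
#' @export
simulate_guided <- function(field, schedule, duration,
                            config = swimmer_config(), dt = NULL,
                            refinement = 1, mu = 8.9e-4) {
  flow <- flow_model(gamma_d = schedule$rates[1], geometry = "bulk_shear",
                     mu = mu)
  traj <- simulate_swimmer(swimmer_state(), duration, config, flow, dt,
                           refinement, schedule = schedule)
  red <- reduced_guided_path(field, schedule, duration, theta0 = 0)
  st <- traj$states
  ep_full <- c(st$x1[nrow(st)], st$x2[nrow(st)])
  ep_red <- c(red$x1[nrow(red)], red$x2[nrow(red)])
  steps <- sqrt(diff(st$x1)^2 + diff(st$x2)^2)
  plen <- sum(steps)
  disc <- sqrt(sum((ep_full - ep_red)^2))
  list(full = st, reduced = red, endpoint_discrepancy = disc,
       path_length = plen,
       relative_discrepancy = disc / max(plen, .Machine$double.eps))
}

#' Behavior switching by shear reversal near a wall
#'
#' Classifies a reduced wall configuration against the separatrices of the
#' forward and reversed flows: the configuration is integrated under
#' gamma_d until the reversal time, the shear is then flipped to -gamma_d,
#' and the long-time fate (boundary collision vs escape) is reported before
#' and after.
#'
#' @param field a [wall_phase_field()] (gamma-affine, so the reversed flow
#'   needs no new solves).
#' @param theta,h initial reduced configuration.
#' @param gamma_d shear rate before reversal, 1/s.
#' @param reversal_time time of the instantaneous reversal, seconds.
#' @param t_max classification horizon, seconds.
#' @return list with `before`, `after` (fate labels), `at_reversal`
#'   (theta, h when the flow is flipped).
#' @export
wall_behavior_switch <- function(field, theta, h, gamma_d, reversal_time,
                                 t_max = 300) {
  before <- classify_wall_fate(field, gamma_d, theta, h, t_max)
  if (before == "collision" && is.null(attr(before, "path")))
    return(list(before = "collision", after = "collision",
                at_reversal = c(theta = theta, h = h)))
  pre <- .integrate_wall(field, gamma_d, c(theta, h), reversal_time,
                         dt_out = min(0.05, reversal_time / 4))
  z <- c(pre$theta[nrow(pre)], pre$h[nrow(pre)])
  after <- classify_wall_fate(field, -gamma_d, z[1], z[2], t_max)
  list(before = as.character(before), after = as.character(after),
       at_reversal = c(theta = z[1], h = z[2]))
}

#' Quasiperiodic boundary swimming with a repulsive wall
#'
#' Hybrid long-time simulation near a repulsive boundary in shear flow: the
#' full boundary-element system (with the short-range repulsive load) is
#' stepped whenever the swimmer surface is within a handoff clearance of
#' the wall, and the phase-averaged reduced dynamics are integrated when it
#' is farther away, where the repulsion is negligible and phase averaging
#' is reliable. Approach-reorient-escape-return cycles are detected and the
#' swimming mode labelled: "tumbling" if the unwrapped orientation gains a
#' full turn between wall approaches, "downstream_facing" otherwise.
#'
#' @param field a [wall_phase_field()] of the same swimmer.
#' @param config a [swimmer_config()].
#' @param theta0,h0 initial reduced configuration.
#' @param gamma_d shear rate, 1/s.
#' @param duration horizon, seconds.
#' @param repulsion a [wall_repulsion()].
#' @param handoff clearance at which the full solver takes over,
#'   micrometres (default three repulsion decay lengths).
#' @param dt full-simulation time step (default beat period / 60).
#' @param refinement mesh level for the full segments.
#' @param mu viscosity, Pa s.
#' @param max_events stop once this many approach events are recorded.
#' @return list with `path` (t, theta, h, clearance, x2, segment kind),
#'   `events` (times of wall-approach onsets, detected as the surface
#'   clearance dropping below the handoff clearance with hysteresis),
#'   `mode`, `n_cycles`, `drift_x2`.
#' @export
repulsive_wall_cycle <- function(field, config, theta0, h0, gamma_d,
                                 duration, repulsion = wall_repulsion(),
                                 handoff = NULL, dt = NULL, refinement = 0,
                                 mu = 8.9e-4, max_events = Inf) {
  if (is.null(handoff)) handoff <- 3 * repulsion$l
  if (is.null(dt)) dt <- 1 / (config$beat_frequency * 60)
  flow <- flow_model(gamma_d, "wall_shear", mu, wall_present = TRUE,
                     repulsion = repulsion)
  # an approach event: the surface enters the repulsion shell (the same
  # clearance at which the full solver takes over), with hysteresis
  approach_on <- handoff
  approach_off <- 2 * handoff
  t <- 0
  theta_un <- theta0            # unwrapped orientation
  z <- c(theta0, h0, 0)
  path <- list()
  events <- numeric(0)
  ev_theta <- numeric(0)        # unwrapped orientation at each event
  in_approach <- FALSE
  push <- function(df) path[[length(path) + 1]] <<- df
  note <- function(tt, cl, th_un) {
    if (!in_approach && cl < approach_on) {
      in_approach <<- TRUE
      events <<- c(events, tt)
      ev_theta <<- c(ev_theta, th_un)
    } else if (in_approach && cl > approach_off) in_approach <<- FALSE
  }
  while (t < duration - 0.05 && length(events) < max_events) {
    cl <- z[2] - field$support(z[1])
    if (cl > handoff) {
      # reduced segment until the swept surface re-enters the handoff shell
      tr <- .integrate_wall(field, gamma_d, z, duration - t, dt_out = 0.02,
                            h_stop_low = handoff * 0.98)
      tr$t <- tr$time + t
      dtheta <- tr$theta - tr$theta[1]
      push(data.frame(t = tr$t, theta = theta_un + dtheta, h = tr$h,
                      clearance = tr$h - field$support(tr$theta),
                      x2 = tr$x2, kind = "reduced"))
      theta_un <- theta_un + dtheta[nrow(tr)]
      z <- c(tr$theta[nrow(tr)], tr$h[nrow(tr)], tr$x2[nrow(tr)])
      t <- tr$t[nrow(tr)]
      if (t >= duration - 1e-9) break
    } else {
      # full boundary-element segment with the repulsive load; the
      # attachment point wobbles by ~A within every beat, so the handoff
      # back to the reduced system uses clearances and coordinates
      # averaged/minimised over a trailing beat window
      state <- planar_state(z[1] %% (2 * pi), z[2], t = t)
      x2_off <- z[3] - state$x0[2]
      th_prev <- state_theta(state)
      nb <- max(2L, round(1 / (config$beat_frequency * dt)))
      seg <- list()
      repeat {
        state <- step_heun(state, dt, config, flow, refinement)
        th <- state_theta(state)
        dth <- (th - th_prev + pi) %% (2 * pi) - pi
        theta_un <- theta_un + dth
        th_prev <- th
        clm <- .wall_clearance(state, config, refinement)
        note(state$t, clm, theta_un)
        seg[[length(seg) + 1]] <-
          data.frame(t = state$t, theta = theta_un, h = state$x0[1],
                     clearance = clm, x2 = x2_off + state$x0[2],
                     kind = "full")
        n <- length(seg)
        if (state$t >= duration || length(events) >= max_events) break
        if (n >= nb) {
          tail_cl <- vapply(seg[(n - nb + 1):n],
                            function(r) r$clearance, numeric(1))
          if (min(tail_cl) > handoff * 1.3) break
        }
        if (clm < 2e-3) break
      }
      seg <- do.call(rbind, seg)
      push(seg)
      t <- state$t
      n <- nrow(seg)
      w <- seg[max(1, n - nb + 1):n, ]
      z <- c(mean(w$theta) %% (2 * pi), mean(w$h), seg$x2[n])
      theta_un <- theta_un + (mean(w$theta) - seg$theta[n])
    }
  }
  path <- do.call(rbind, path)
  n_cycles <- length(events)
  mode <- if (n_cycles >= 2) {
    if (any(abs(diff(ev_theta)) >= 1.6 * pi)) "tumbling"
    else "downstream_facing"
  } else NA_character_
  list(path = path, events = events, mode = mode, n_cycles = n_cycles,
       drift_x2 = path$x2[nrow(path)] - path$x2[1])
}
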