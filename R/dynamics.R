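#' Laboratory-frame swimmer state
#'
#' Position of the flagellar attachment point x0, orientation as a unit
#' quaternion mapping the swimmer frame to the laboratory frame, and time.
#'
#' @param x0 3-vector, micrometres.
#' @param quat unit quaternion (w, x, y, z).
#' @param t time, seconds.
#' @return a `swimmer_state` object.
#' @export
swimmer_state <- function(x0 = c(0, 0, 0), quat = c(1, 0, 0, 0), t = 0) {
  quat <- quat / sqrt(sum(quat^2))
  structure(list(x0 = as.numeric(x0), quat = as.numeric(quat), t = t),
            class = "swimmer_state")
}

#' Planar state from the reduced coordinates
#'
#' The planar reduction describes orientation by the single clockwise angle
#' theta between the swimmer x1 axis and the laboratory x1-hat axis (rotation
#' about the x3 axis by -theta), and, near a wall at x1-hat = 0, the
#' separation h of x0 from the wall.
#'
#' @param theta clockwise orientation angle, radians.
#' @param h wall separation of x0 (used as the x1 coordinate), micrometres.
#' @param t time, seconds.
#' @return a `swimmer_state`.
#' @export
planar_state <- function(theta, h = 0, t = 0) {
  swimmer_state(x0 = c(h, 0, 0),
                quat = c(cos(theta / 2), 0, 0, -sin(theta / 2)), t = t)
}

#' Rotation matrix of a unit quaternion (swimmer frame to lab frame)
#' @param q unit quaternion (w, x, y, z).
#' @return 3 x 3 rotation matrix.
#' @export
quat_to_rot <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

.quat_mult <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

# quaternion exponential of a rotation vector w*dt (lab-frame angular velocity)
.quat_exp <- function(wdt) {
  ang <- sqrt(sum(wdt^2))
  if (ang < 1e-300) return(c(1, 0, 0, 0))
  c(cos(ang / 2), sin(ang / 2) * wdt / ang)
}

#' Clockwise planar angle of a state
#' @param state a `swimmer_state`.
#' @return theta in `[0, 2 pi)`: the clockwise angle between the swimmer x1
#'   axis and the laboratory x1-hat axis, extracted by projecting the
#'   swimmer axis onto the lab x1-x2 plane.
#' @export
state_theta <- function(state) {
  e1 <- quat_to_rot(state$quat)[, 1]
  (atan2(-e1[2], e1[1])) %% (2 * pi)
}

# instantaneous rigid-body rates from the boundary-element solve
.bem_rates <- function(state, config, flow, refinement, dt_frac = 1e-3) {
  phase <- (config$beat_frequency * state$t) %% 1
  mesh <- build_mesh(config, phase, refinement, dt_frac)
  R <- quat_to_rot(state$quat)
  mlab <- transform_mesh(mesh, R, state$x0)
  fext <- c(0, 0, 0); text <- c(0, 0, 0)
  rep <- flow$repulsion
  if (!is.null(rep) && isTRUE(rep$enabled) && isTRUE(flow$wall_present)) {
    load <- net_wall_load(mlab, state$x0, rep, flow$mu, config$beat_frequency)
    fext <- load$force; text <- load$torque
  }
  sol <- solve_mobility(mlab, state$x0, flow, fext, text)
  list(U = sol$U, Omega = sol$Omega, mesh = mlab)
}

#' Advance a swimmer state by one Heun (explicit trapezoidal) step
#'
#' Second-order predictor-corrector update of position and orientation; the
#' orientation update uses the quaternion exponential of the angular
#' velocity and is renormalised each step.
#'
#' @param state a `swimmer_state`.
#' @param dt time step, seconds.
#' @param config a [swimmer_config()].
#' @param flow a [flow_model()].
#' @param refinement mesh refinement level.
#' @param rates_fn optional function(state) returning list(U, Omega),
#'   substituting the boundary-element solve (used for verification against
#'   closed-form rigid motions).
#' @return the advanced `swimmer_state`, with attributes `U`, `Omega`.
#' @export
step_heun <- function(state, dt, config = NULL, flow = flow_model(),
                      refinement = 1, rates_fn = NULL) {
  f <- if (is.null(rates_fn))
    function(s) .bem_rates(s, config, flow, refinement) else rates_fn
  k1 <- f(state)
  pred <- swimmer_state(state$x0 + dt * k1$U,
                        .quat_mult(.quat_exp(k1$Omega * dt), state$quat),
                        state$t + dt)
  k2 <- f(pred)
  U <- (k1$U + k2$U) / 2
  Om <- (k1$Omega + k2$Omega) / 2
  out <- swimmer_state(state$x0 + dt * U,
                       .quat_mult(.quat_exp(Om * dt), state$quat),
                       state$t + dt)
  attr(out, "U") <- U
  attr(out, "Omega") <- Om
  out
}

# minimum wall clearance of the swimmer surface (wall at x1 = 0)
.wall_clearance <- function(state, config, refinement) {
  phase <- (config$beat_frequency * state$t) %% 1
  mesh <- build_mesh(config, phase, refinement)
  R <- quat_to_rot(state$quat)
  min(sweep(mesh$nodes %*% t(R), 2, state$x0, "+")[, 1])
}

#' Simulate a swimming trajectory
#'
#' Repeated Heun stepping of the full boundary-element dynamics. Near a
#' passive wall the run halts when the minimum distance between the swimmer
#' surface and the boundary reaches the collision threshold (~2 nm).
#'
#' @param initial a `swimmer_state`.
#' @param duration simulated time, seconds.
#' @param config a [swimmer_config()].
#' @param flow a [flow_model()].
#' @param dt time step; default one hundredth of a beat period.
#' @param refinement mesh refinement level.
#' @param halt_clearance collision threshold, micrometres (2e-3 = 2 nm).
#' @param rates_fn optional override of the boundary-element rates (see
#'   [step_heun()]).
#' @param schedule optional [shear_schedule()]: time-dependent shear rate
#'   gamma_d(t) replacing `flow$gamma_d`.
#' @return a `trajectory`: list with `states` data frame (t, x0, quaternion,
#'   U, Omega, clearance) and `halt_reason` ("completed" or
#'   "wall_collision").
#' @export
simulate_swimmer <- function(initial, duration, config, flow = flow_model(),
                             dt = NULL, refinement = 1,
                             halt_clearance = 2e-3, rates_fn = NULL,
                             schedule = NULL) {
  if (duration <= 0) stop("duration must be positive")
  if (is.null(dt)) dt <- 1 / (config$beat_frequency * 100)
  nstep <- ceiling(duration / dt - 1e-9)
  rows <- vector("list", nstep + 1)
  state <- initial
  halt <- "completed"
  rec <- function(state, U = rep(NA_real_, 3), Om = rep(NA_real_, 3), cl) {
    data.frame(t = state$t, x1 = state$x0[1], x2 = state$x0[2],
               x3 = state$x0[3], qw = state$quat[1], qx = state$quat[2],
               qy = state$quat[3], qz = state$quat[4], U1 = U[1], U2 = U[2],
               U3 = U[3], O1 = Om[1], O2 = Om[2], O3 = Om[3], clearance = cl)
  }
  wall <- isTRUE(flow$wall_present)
  passive <- wall && (is.null(flow$repulsion) ||
                        !isTRUE(flow$repulsion$enabled))
  cl <- if (wall && !is.null(config))
    .wall_clearance(state, config, refinement) else NA_real_
  rows[[1]] <- rec(state, cl = cl)
  k <- 1L
  t_end <- initial$t + duration
  while (state$t < t_end - 1e-12) {
    fl <- flow
    if (!is.null(schedule)) fl$gamma_d <- schedule_rate(schedule, state$t)
    # near a passive wall the surface can sweep to contact within one
    # step; bisect the step until the approach is resolved
    dt_cur <- min(dt, t_end - state$t)
    trial <- NULL
    repeat {
      trial <- tryCatch(step_heun(state, dt_cur, config, fl, refinement,
                                  rates_fn), error = function(e) e)
      if (!inherits(trial, "error")) break
      if (!passive || !grepl("penetrates", conditionMessage(trial)))
        stop(trial)
      dt_cur <- dt_cur / 2
      if (dt_cur < dt / 4096) break
    }
    if (inherits(trial, "error")) {
      halt <- "wall_collision"
      break
    }
    state <- trial
    cl <- if (wall && !is.null(config))
      .wall_clearance(state, config, refinement) else NA_real_
    k <- k + 1L
    rows[[k]] <- rec(state, attr(state, "U"), attr(state, "Omega"), cl)
    if (passive && !is.na(cl) && cl <= halt_clearance) {
      halt <- "wall_collision"
      break
    }
  }
  rows <- rows[seq_len(k)]
  structure(list(states = do.call(rbind, rows), halt_reason = halt,
                 final = state, config = config, flow = flow),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  n <- nrow(x$states)
  cat(sprintf("trajectory: %d states over %.4g s, halt: %s\n", n,
              x$states$t[n] - x$states$t[1], x$halt_reason))
  invisible(x)
}

#' Write a trajectory as CSV
#' @param traj a `trajectory`.
#' @param file output path.
#' @return the path, invisibly.
#' @export
trajectory_to_csv <- function(traj, file) {
  utils::write.csv(traj$states, file, row.names = FALSE)
  invisible(file)
}
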