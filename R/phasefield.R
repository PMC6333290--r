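#' Phase-averaged rigid-body velocities at a frozen configuration
#'
#' Solves the mobility problem at equispaced beat phases with the position
#' and orientation held fixed and returns the arithmetic mean of the linear
#' and angular velocities over the beat.
#'
#' @param config a [swimmer_config()].
#' @param state a `swimmer_state` (frozen configuration).
#' @param flow a [flow_model()].
#' @param n_phases number of equispaced beat phases (default 20).
#' @param refinement mesh refinement level.
#' @return list with `U` and `Omega` (lab frame, beat-averaged).
#' @export
phase_average <- function(config, state, flow = flow_model(), n_phases = 20,
                          refinement = 1) {
  if (n_phases < 2) stop("n_phases must be at least 2")
  R <- quat_to_rot(state$quat)
  acc_U <- acc_O <- c(0, 0, 0)
  for (p in (seq_len(n_phases) - 1) / n_phases) {
    mesh <- transform_mesh(build_mesh(config, p, refinement), R, state$x0)
    fext <- c(0, 0, 0); text <- c(0, 0, 0)
    rep <- flow$repulsion
    if (!is.null(rep) && isTRUE(rep$enabled) && isTRUE(flow$wall_present)) {
      load <- net_wall_load(mesh, state$x0, rep, flow$mu,
                            config$beat_frequency)
      fext <- load$force; text <- load$torque
    }
    sol <- solve_mobility(mesh, state$x0, flow, fext, text)
    acc_U <- acc_U + sol$U
    acc_O <- acc_O + sol$Omega
  }
  list(U = acc_U / n_phases, Omega = acc_O / n_phases)
}

.rot_z <- function(theta) {
  # rotation swimmer -> lab for clockwise angle theta
  matrix(c(cos(theta), sin(theta), 0, -sin(theta), cos(theta), 0, 0, 0, 1),
         3, 3, byrow = TRUE)
}

#' Phase-averaged bulk reduced dynamics over orientation
#'
#' Computes the beat-averaged linear and angular velocities of the swimmer
#' in bulk shear `u_b = gamma_d (x2, 0, 0)` as a function of the planar
#' orientation theta, exploiting two exact properties of Stokes flow: the
#' response is affine in the shear rate (solves at gamma = 0 and 1 suffice),
#' and the zero-shear swimming contribution is independent of theta in the
#' swimmer frame. One boundary-element assembly per beat phase serves every
#' orientation and shear rate.
#'
#' @param config a [swimmer_config()].
#' @param n_theta number of orientation samples on `[0, 2 pi)`.
#' @param n_phases beat phases per sample.
#' @param refinement mesh refinement level.
#' @param mu dynamic viscosity, Pa s.
#' @return a `bulk_phase_field` object.
#' @export
bulk_phase_field <- function(config, n_theta = 36, n_phases = 20,
                             refinement = 1, mu = 8.9e-4) {
  theta <- 2 * pi * (seq_len(n_theta) - 1) / n_theta
  A_lab <- matrix(0, 3, 3)
  A_lab[1, 2] <- 1                      # unit-shear velocity gradient
  Uswim <- Oswim <- rep(0, 3)
  Ush <- Osh <- matrix(0, n_theta, 3)
  for (p in (seq_len(n_phases) - 1) / n_phases) {
    mesh <- build_mesh(config, p, refinement)
    cen <- .tri_geom(mesh)$centroids
    ub <- vector("list", n_theta + 1)
    ub[[1]] <- matrix(0, nrow(cen), 3)
    for (k in seq_len(n_theta)) {
      R <- .rot_z(theta[k])
      A_sw <- t(R) %*% A_lab %*% R
      ub[[k + 1]] <- cen %*% t(A_sw)
    }
    sol <- .solve_mobility_multi(mesh, c(0, 0, 0), ub, mu)
    Uswim <- Uswim + sol$U[, 1]
    Oswim <- Oswim + sol$Omega[, 1]
    Ush <- Ush + t(sol$U[, -1, drop = FALSE] - sol$U[, 1])
    Osh <- Osh + t(sol$Omega[, -1, drop = FALSE] - sol$Omega[, 1])
  }
  structure(list(theta = theta, Uswim = Uswim / n_phases,
                 Oswim = Oswim / n_phases, Ushear = Ush / n_phases,
                 Oshear = Osh / n_phases, n_phases = n_phases,
                 refinement = refinement, config = config),
            class = "bulk_phase_field")
}

#' @export
print.bulk_phase_field <- function(x, ...) {
  cat(sprintf(
    "bulk_phase_field: %d orientations x %d phases, |U_swim| = %.3f um/s\n",
    length(x$theta), x$n_phases, sqrt(sum(x$Uswim^2))))
  invisible(x)
}

# periodic cubic spline on [0, 2 pi)
.periodic_spline <- function(x, y) {
  stats::splinefun(c(x, x[1] + 2 * pi), c(y, y[1]), method = "periodic")
}

#' Phase-averaged planar rotation rate in bulk shear
#'
#' The clockwise rate d theta/dt of the reduced bulk system, interpolated
#' periodically from a [bulk_phase_field()]. Positive for positive shear
#' away from boundaries (the flow vorticity turns the swimmer clockwise).
#'
#' @param field a `bulk_phase_field`.
#' @param theta orientation(s), radians.
#' @param gamma_d shear rate, 1/s.
#' @return d theta/dt, rad/s (vectorised over theta).
#' @export
bulk_angular_rate <- function(field, theta, gamma_d) {
  sp <- .periodic_spline(field$theta, field$Oshear[, 3])
  -(field$Oswim[3] + gamma_d * sp(theta %% (2 * pi)))
}

#' Lab-frame phase-averaged translational velocity in bulk shear
#'
#' @param field a `bulk_phase_field`.
#' @param theta orientation(s), radians.
#' @param gamma_d shear rate, 1/s.
#' @return matrix (length(theta) x 3) of velocities at the origin; at a
#'   general position add the background velocity `u_b(x)`.
#' @export
bulk_velocity <- function(field, theta, gamma_d) {
  sp <- lapply(1:3, function(i) .periodic_spline(field$theta,
                                                 field$Ushear[, i]))
  t(vapply(theta, function(th) {
    Usw <- field$Uswim + gamma_d *
      c(sp[[1]](th %% (2 * pi)), sp[[2]](th %% (2 * pi)),
        sp[[3]](th %% (2 * pi)))
    as.numeric(.rot_z(th) %*% Usw)
  }, numeric(3)))
}

#' Period of phase-averaged rotation in bulk shear
#'
#' Closed quadrature of d theta / thetadot(theta) over one turn of the
#' tumbling orbit.
#'
#' @param field a `bulk_phase_field`.
#' @param gamma_d shear rate, 1/s.
#' @return period, seconds.
#' @export
rotation_period <- function(field, gamma_d) {
  probe <- bulk_angular_rate(field, seq(0, 2 * pi, length.out = 181),
                             gamma_d)
  if (any(probe <= 0))
    stop("rotation rate changes sign: not in the tumbling regime")
  stats::integrate(function(th) 1 / bulk_angular_rate(field, th, gamma_d),
                   0, 2 * pi, rel.tol = 1e-9, subdivisions = 400L)$value
}

#' Jeffery rotation rate of a passive spheroid
#'
#' In-plane clockwise rate for aspect ratio r in shear of rate gamma_d:
#' `gamma_d (r^2 sin^2 theta + cos^2 theta) / (r^2 + 1)`; slowest when
#' flow-aligned (theta = 0, pi).
#'
#' @param theta orientation, radians.
#' @param r aspect ratio (>= 1 by convention).
#' @param gamma_d shear rate, 1/s.
#' @return d theta/dt, rad/s.
#' @export
jeffery_rate <- function(theta, r, gamma_d = 1) {
  gamma_d * (r^2 * sin(theta)^2 + cos(theta)^2) / (r^2 + 1)
}

#' Jeffery orbit period
#' @param r aspect ratio.
#' @param gamma_d shear rate, 1/s.
#' @return period `2 pi (r + 1/r) / gamma_d`, seconds.
#' @export
jeffery_period <- function(r, gamma_d = 1) 2 * pi * (r + 1 / r) / gamma_d

#' Closed-form Jeffery orbit
#' @param times evaluation times, seconds.
#' @param r aspect ratio.
#' @param gamma_d shear rate, 1/s.
#' @param theta0 initial orientation.
#' @return unwrapped theta(t), radians.
#' @export
jeffery_orbit <- function(times, r, gamma_d = 1, theta0 = 0) {
  # theta = atan((1/r) tan psi) with psi advancing uniformly
  psi0 <- atan2(r * sin(theta0), cos(theta0))
  psi <- psi0 + gamma_d * r / (r^2 + 1) * times
  th <- atan2(sin(psi) / r, cos(psi))
  th + 2 * pi * round((psi - th) / (2 * pi))
}

#' Fit the effective Jeffery aspect ratio from rotation periods
#'
#' Least-squares fit of `T = (2 pi / gamma)(r + 1/r)` with `r >= 1` to a set
#' of (shear rate, period) pairs; each pair is first inverted in closed form
#' (`r = (c + sqrt(c^2 - 4))/2`, `c = gamma T / 2 pi`) and the estimate then
#' polished by one-dimensional least squares.
#'
#' @param periods data frame with columns `gamma_d` and `T_d`.
#' @return a `jeffery_fit`: list with `r`, `residual`, `periods`.
#' @export
fit_jeffery_ratio <- function(periods) {
  if (nrow(periods) < 1) stop("need at least one (gamma_d, T_d) pair")
  cc <- periods$gamma_d * periods$T_d / (2 * pi)
  if (any(cc < 2))
    stop("period below the minimum 4 pi / gamma: no real aspect ratio")
  r0 <- mean((cc + sqrt(cc^2 - 4)) / 2)
  obj <- function(r) sum((periods$T_d - (2 * pi / periods$gamma_d) *
                            (r + 1 / r))^2)
  r <- stats::optimize(obj, c(1, 2 * r0 + 2), tol = 1e-10)$minimum
  # keep the closed-form average when the polish does not improve on it
  if (obj(r0) <= obj(r)) r <- r0
  if (obj(1) <= obj(r)) r <- 1
  structure(list(r = r, residual = sqrt(obj(r)), periods = periods),
            class = "jeffery_fit")
}

#' @export
print.jeffery_fit <- function(x, ...) {
  cat(sprintf("jeffery_fit: r = %.4f (residual %.3g, %d periods)\n", x$r,
              x$residual, nrow(x$periods)))
  invisible(x)
}

#' Rotation period as a function of body lengthscale
#'
#' Recomputes the phase-averaged rotation period with a scaling factor
#' applied to both body axes, holding the flagellum morphology and beat
#' fixed.
#'
#' @param scalings vector of body scale factors.
#' @param gamma_d shear rate, 1/s.
#' @param config base [swimmer_config()].
#' @param n_theta,n_phases,refinement discretisation of the phase average.
#' @return data frame (scaling, T_d) with attribute `argmax`.
#' @export
period_vs_bodyscale <- function(scalings, gamma_d = 1,
                                config = swimmer_config(), n_theta = 24,
                                n_phases = 12, refinement = 0) {
  Td <- vapply(scalings, function(s) {
    cfg <- config
    cfg$body_scale <- s
    f <- bulk_phase_field(cfg, n_theta, n_phases, refinement)
    rotation_period(f, gamma_d)
  }, numeric(1))
  out <- data.frame(scaling = scalings, T_d = Td)
  attr(out, "argmax") <- scalings[which.max(Td)]
  out
}

#' Rescale the swimming (active) part of a phase field
#'
#' By Stokes linearity and the kinematic scaling of the prescribed beat,
#' every active (zero-shear) velocity component of the swimmer is exactly
#' proportional to the beat frequency, while the passive shear response is
#' frequency-independent. Scaling the swim components of a stored field by
#' `factor` therefore yields, without any new solves, the exact
#' phase-averaged field of the same swimmer with beat frequency multiplied
#' by `factor` — equivalently, the reduced dynamics of a swimmer whose
#' free-space speed is `factor` times the original at the same shear rates.
#'
#' @param field a [bulk_phase_field()] or [wall_phase_field()].
#' @param factor positive scale factor on the beat frequency / swim speed.
#' @return a field of the same class.
#' @export
scale_swim_speed <- function(field, factor) {
  if (inherits(field, "bulk_phase_field")) {
    field$Uswim <- field$Uswim * factor
    field$Oswim <- field$Oswim * factor
  } else if (inherits(field, "wall_phase_field")) {
    field$T0 <- field$T0 * factor
    field$H0 <- field$H0 * factor
    field$Y0 <- field$Y0 * factor
    field$interp <- .wall_interp(field)
  } else stop("not a phase field")
  cfg <- field$config
  cfg$beat_frequency <- cfg$beat_frequency * factor
  field$config <- cfg
  field
}

# --- wall phase plane ------------------------------------------------------

# planar support function of the swimmer over the beat: E(theta) is the
# maximum depth of the surface below x0 along the wall normal when the
# swimmer is at clockwise angle theta. Precomputed from the convex hull of
# the beat-swept node cloud in the beat plane.
.planar_support <- function(config, refinement = 0, n_phases = 12) {
  pts <- do.call(rbind, lapply((seq_len(n_phases) - 1) / n_phases,
    function(p) build_mesh(config, p, refinement)$nodes[, 1:2]))
  hull <- pts[grDevices::chull(pts), , drop = FALSE]
  function(theta)
    vapply(theta, function(th)
      max(-(cos(th) * hull[, 1] + sin(th) * hull[, 2])), numeric(1))
}

#' Geometric admissibility of a reduced wall configuration
#' @param support support function from a wall field (or internal helper).
#' @param theta,h reduced coordinates.
#' @param margin required clearance, micrometres.
#' @return logical.
#' @export
wall_config_valid <- function(support, theta, h, margin = 0.05) {
  h - support(theta) > margin
}

#' Phase-averaged reduced dynamics near a no-slip wall
#'
#' Beat-averaged (thetadot, hdot) of the planar reduced system for a swimmer
#' at orientation theta and separation h above the wall x1 = 0, in
#' wall-bounded shear `u_b = gamma_d (0, -x1, 0)`, using the Blake image
#' kernels. The affine dependence on gamma_d is stored explicitly (solves at
#' gamma = 0 and 1), so the field can be evaluated at any shear rate.
#' Configurations whose surface would cross the wall at any sampled phase
#' are flagged invalid.
#'
#' @param config a [swimmer_config()].
#' @param theta_grid orientation samples (default 24 on `[0, 2 pi)`).
#' @param h_grid separation samples (default 16, log-spaced on 2.5-30 um).
#' @param n_phases beat phases per node.
#' @param refinement mesh refinement level.
#' @param mu dynamic viscosity, Pa s.
#' @param margin minimum wall clearance for a phase sample to be computed.
#' @return a `wall_phase_field` object.
#' @export
wall_phase_field <- function(config,
                             theta_grid = 2 * pi * (0:23) / 24,
                             h_grid = exp(seq(log(2.5), log(30),
                                              length.out = 16)),
                             n_phases = 20, refinement = 1, mu = 8.9e-4,
                             margin = 0.05) {
  nt <- length(theta_grid); nh <- length(h_grid)
  T0 <- Tsh <- H0 <- Hsh <- Y0 <- Ysh <- matrix(NA_real_, nt, nh)
  valid <- matrix(FALSE, nt, nh)
  support <- .planar_support(config, min(refinement, 1))
  meshes <- lapply((seq_len(n_phases) - 1) / n_phases,
                   function(p) build_mesh(config, p, refinement))
  for (j in seq_len(nh)) for (i in seq_len(nt)) {
    th <- theta_grid[i]; h <- h_grid[j]
    if (!wall_config_valid(support, th, h, margin)) next
    R <- .rot_z(th)
    x0 <- c(h, 0, 0)
    accU <- accO <- matrix(0, 3, 2)
    ok <- TRUE
    for (m in meshes) {
      ml <- transform_mesh(m, R, x0)
      if (min(ml$nodes[, 1]) <= margin) { ok <- FALSE; break }
      cen <- .tri_geom(ml)$centroids
      ub1 <- cbind(0, -cen[, 1], 0)      # unit wall shear
      sol <- .solve_mobility_multi(ml, x0,
                                   list(matrix(0, nrow(cen), 3), ub1),
                                   mu, wall = TRUE)
      accU <- accU + sol$U
      accO <- accO + sol$Omega
    }
    if (!ok) next
    accU <- accU / n_phases
    accO <- accO / n_phases
    valid[i, j] <- TRUE
    T0[i, j] <- -accO[3, 1]
    Tsh[i, j] <- -(accO[3, 2] - accO[3, 1])
    H0[i, j] <- accU[1, 1]
    Hsh[i, j] <- accU[1, 2] - accU[1, 1]
    Y0[i, j] <- accU[2, 1]
    Ysh[i, j] <- accU[2, 2] - accU[2, 1]
  }
  f <- structure(list(theta = theta_grid, h = h_grid, T0 = T0, Tsh = Tsh,
                      H0 = H0, Hsh = Hsh, Y0 = Y0, Ysh = Ysh,
                      valid = valid, support = support,
                      n_phases = n_phases, refinement = refinement,
                      config = config),
                 class = "wall_phase_field")
  f$interp <- .wall_interp(f)
  f
}

#' @export
print.wall_phase_field <- function(x, ...) {
  cat(sprintf(
    "wall_phase_field: %d x %d grid (%d valid), %d phases, h in [%.3g, %.3g] um\n",
    length(x$theta), length(x$h), sum(x$valid), x$n_phases, min(x$h),
    max(x$h)))
  invisible(x)
}

# row-wise periodic splines in theta (valid nodes only) for the four affine
# components, evaluated then splined in h
.wall_interp <- function(field) {
  nh <- length(field$h)
  comp <- c("T0", "Tsh", "H0", "Hsh", "Y0", "Ysh")
  rows <- lapply(seq_len(nh), function(j) {
    v <- field$valid[, j]
    if (sum(v) < 4) return(NULL)
    th <- field$theta[v]
    lapply(comp, function(nm) {
      y <- field[[nm]][v, j]
      stats::splinefun(c(th, th[1] + 2 * pi), c(y, y[1]),
                       method = "periodic")
    })
  })
  function(theta, h, gamma_d) {
    theta <- theta %% (2 * pi)
    usable <- which(!vapply(rows, is.null, logical(1)))
    # rows whose theta-coverage includes the query orientation
    okrow <- usable[vapply(usable, function(j)
      wall_config_valid(field$support, theta, field$h[j], 0.05), logical(1))]
    if (length(okrow) < 2)
      return(c(thetadot = NA_real_, hdot = NA_real_, x2dot = NA_real_))
    vals <- vapply(okrow, function(j) {
      s <- rows[[j]]
      c(s[[1]](theta) + gamma_d * s[[2]](theta),
        s[[3]](theta) + gamma_d * s[[4]](theta),
        s[[5]](theta) + gamma_d * s[[6]](theta))
    }, numeric(3))
    hv <- field$h[okrow]
    if (length(okrow) >= 3) {
      c(thetadot = stats::splinefun(hv, vals[1, ], method = "natural")(h),
        hdot = stats::splinefun(hv, vals[2, ], method = "natural")(h),
        x2dot = stats::splinefun(hv, vals[3, ], method = "natural")(h))
    } else {
      c(thetadot = stats::approx(hv, vals[1, ], h, rule = 2)$y,
        hdot = stats::approx(hv, vals[2, ], h, rule = 2)$y,
        x2dot = stats::approx(hv, vals[3, ], h, rule = 2)$y)
    }
  }
}

#' Reduced wall dynamics at a configuration
#' @param field a `wall_phase_field`.
#' @param theta,h reduced coordinates.
#' @param gamma_d shear rate, 1/s.
#' @return c(thetadot, hdot, x2dot); x2dot is the lab-frame downstream
#'   velocity component of x0 (background advection included).
#' @export
wall_rates <- function(field, theta, h, gamma_d) {
  field$interp(theta, h, gamma_d)
}

#' Locate the fixed point of the reduced wall dynamics
#'
#' Multistart two-dimensional Newton iteration on the interpolated
#' phase-averaged field, with finite-difference Jacobians; fixed points are
#' classified by the Jacobian eigenvalues (a saddle has real eigenvalues of
#' opposite sign).
#'
#' @param field a `wall_phase_field`.
#' @param gamma_d shear rate, 1/s.
#' @param theta_window search window for theta (default the full circle).
#' @param seeds optional matrix of (theta, h) starting points.
#' @return list with `found`, and when found `theta`, `h`, `jacobian`,
#'   `eigenvalues`, `type`.
#' @export
find_saddle <- function(field, gamma_d,
                        theta_window = c(1e-3, 2 * pi - 1e-3),
                        seeds = NULL) {
  Fv <- function(z) field$interp(z[1], z[2], gamma_d)[1:2]
  if (is.null(seeds)) {
    ths <- seq(theta_window[1], theta_window[2], length.out = 19)
    hs <- exp(seq(log(min(field$h)), log(max(field$h) / 2),
                  length.out = 8))
    seeds <- as.matrix(expand.grid(ths, hs))
  }
  best <- NULL
  for (k in seq_len(nrow(seeds))) {
    z <- as.numeric(seeds[k, ])
    if (!wall_config_valid(field$support, z[1], z[2], 0.05)) next
    conv <- FALSE
    for (it in 1:60) {
      fz <- Fv(z)
      if (any(is.na(fz))) break
      if (max(abs(fz)) < 1e-10) { conv <- TRUE; break }
      J <- .num_jac(Fv, z)
      if (any(is.na(J)) || abs(det(J)) < 1e-14) break
      dz <- solve(J, fz)
      dz <- dz * min(1, 1.0 / max(abs(dz)))  # damped step, at most 1 unit
      z <- z - dz
      if (z[2] < 0.3 || z[2] > 2 * max(field$h)) break
      z[1] <- z[1] %% (2 * pi)
    }
    if (conv && z[1] > theta_window[1] - 0.2 &&
        z[1] < theta_window[2] + 0.2) {
      J <- .num_jac(Fv, z)
      ev <- eigen(J)$values
      type <- if (all(Im(ev) == 0) && prod(Re(ev)) < 0) "saddle"
              else if (all(Re(ev) < 0)) "stable" else "other"
      root <- list(found = TRUE, theta = z[1], h = z[2], jacobian = J,
                   eigenvalues = ev, type = type)
      if (type == "saddle") return(root)
      if (is.null(best)) best <- root
    }
  }
  if (is.null(best)) return(list(found = FALSE))
  best
}

.num_jac <- function(Fv, z, eps = 1e-4) {
  J <- matrix(NA_real_, 2, 2)
  for (i in 1:2) {
    zp <- z; zm <- z
    zp[i] <- zp[i] + eps
    zm[i] <- zm[i] - eps
    J[, i] <- (Fv(zp) - Fv(zm)) / (2 * eps)
  }
  J
}

# integrate the reduced wall dynamics (optionally reversed in time)
.integrate_wall <- function(field, gamma_d, z0, t_max, dt_out = 0.05,
                            backward = FALSE, h_stop_low = NULL,
                            h_stop_high = NULL) {
  sgn <- if (backward) -1 else 1
  rhs <- function(t, y, parms) {
    f <- field$interp(y[1], y[2], gamma_d)
    if (any(is.na(f))) f <- c(0, 0, 0)
    list(sgn * f)
  }
  root <- function(t, y, parms) {
    lo <- y[2] - (field$support(y[1]) +
                    if (is.null(h_stop_low)) 0.4 else h_stop_low)
    hi <- (if (is.null(h_stop_high)) 1.05 * max(field$h) else h_stop_high) -
      y[2]
    c(lo, hi)
  }
  x20 <- if (length(z0) >= 3) z0[3] else 0
  y0 <- c(theta = z0[1], h = z0[2], x2 = x20)
  if (t_max <= dt_out)
    return(data.frame(time = 0, theta = y0[1], h = y0[2], x2 = y0[3]))
  out <- suppressWarnings(
    deSolve::ode(y = y0,
                 times = unique(c(seq(0, t_max, by = dt_out), t_max)),
                 func = rhs, rootfunc = root, method = "lsoda",
                 rtol = 1e-8, atol = 1e-8, maxsteps = 50000))
  out <- as.data.frame(out)
  out[stats::complete.cases(out), ]
}

#' Separatrix of the reduced wall dynamics
#'
#' The stable manifold of the saddle, obtained by integrating the reduced
#' system backward in time from small displacements along the stable
#' eigenvector; together with periodicity in theta it partitions the
#' (theta, h) phase plane into boundary-collision-bound and bulk-escape
#' configurations.
#'
#' @param field a `wall_phase_field`.
#' @param saddle result of [find_saddle()].
#' @param gamma_d shear rate, 1/s.
#' @param t_max backward-integration horizon, seconds.
#' @param eps initial displacement along the eigenvector.
#' @return data frame (theta, h, branch); theta unwrapped.
#' @export
compute_separatrix <- function(field, saddle, gamma_d, t_max = 400,
                               eps = 5e-3) {
  if (!isTRUE(saddle$found)) stop("saddle not found")
  ev <- eigen(saddle$jacobian)
  k <- which.min(Re(ev$values))
  v <- Re(ev$vectors[, k])
  v <- v / sqrt(sum(v^2))
  out <- lapply(c(1, -1), function(s) {
    z0 <- c(saddle$theta, saddle$h) + s * eps * v
    tr <- .integrate_wall(field, gamma_d, z0, t_max, dt_out = 0.1,
                          backward = TRUE)
    data.frame(theta = tr$theta, h = tr$h, branch = s)
  })
  do.call(rbind, out)
}

#' Long-time fate of a reduced wall configuration
#'
#' Forward integration of the phase-averaged wall dynamics until the
#' swimmer either closes to within a collision clearance of the boundary or
#' escapes beyond the outer edge of the field.
#'
#' @param field a `wall_phase_field`.
#' @param gamma_d shear rate, 1/s.
#' @param theta,h initial reduced configuration.
#' @param t_max integration horizon, seconds.
#' @param collision_clearance surface-to-wall clearance counted as
#'   collision, micrometres.
#' @param h_escape separation counted as escape to the bulk, micrometres.
#' @return "collision", "escape" or "undetermined", with the path in
#'   attribute `path`.
#' @export
classify_wall_fate <- function(field, gamma_d, theta, h, t_max = 300,
                               collision_clearance = 0.4, h_escape = NULL) {
  if (is.null(h_escape)) h_escape <- 0.95 * max(field$h)
  if (!wall_config_valid(field$support, theta, h, collision_clearance))
    return(structure("collision", path = NULL))
  tr <- .integrate_wall(field, gamma_d, c(theta, h), t_max, dt_out = 0.05,
                        h_stop_low = collision_clearance,
                        h_stop_high = h_escape)
  n <- nrow(tr)
  lab <- if (tr$h[n] - field$support(tr$theta[n]) <=
               collision_clearance * 1.02) "collision"
         else if (tr$h[n] >= h_escape * 0.999) "escape"
         else "undetermined"
  structure(lab, path = tr)
}

#' Critical shear rate for near-wall saddle collapse
#'
#' Tracks the saddle separation h*(gamma_d) by Newton continuation on the
#' gamma-affine field and returns the smallest shear rate at which the
#' saddle sits within one beat amplitude of the wall, the operational
#' criterion for configurations beneath the separatrix representing
#' effectively immediate boundary collision.
#'
#' @param field a `wall_phase_field`.
#' @param gamma_range range of shear rates scanned.
#' @param n_gamma number of continuation steps.
#' @param h_threshold saddle height counted as collapse (default the beat
#'   amplitude of the swimmer).
#' @return list with `gamma_crit`, `track` (data frame gamma, theta, h).
#' @export
critical_shear <- function(field, gamma_range = c(0.4, 3), n_gamma = 14,
                           h_threshold = NULL) {
  if (is.null(h_threshold)) h_threshold <- field$config$beat_amplitude
  gams <- exp(seq(log(gamma_range[1]), log(gamma_range[2]),
                  length.out = n_gamma))
  track <- data.frame(gamma = numeric(0), theta = numeric(0),
                      h = numeric(0))
  seed <- NULL
  for (g in gams) {
    s <- find_saddle(field, g, seeds = seed)
    if (!s$found) s <- find_saddle(field, g)
    if (!s$found || s$type != "saddle") next
    track <- rbind(track, data.frame(gamma = g, theta = s$theta, h = s$h))
    seed <- matrix(c(s$theta, s$h), 1)
  }
  if (nrow(track) < 2 || all(track$h > h_threshold))
    return(list(gamma_crit = NA_real_, track = track))
  hs <- function(g) {
    s <- find_saddle(field, g,
                     seeds = matrix(c(stats::approx(track$gamma, track$theta,
                                                    g, rule = 2)$y,
                                      stats::approx(track$gamma, track$h, g,
                                                    rule = 2)$y), 1))
    if (!s$found) NA_real_ else s$h
  }
  below <- which(track$h <= h_threshold)
  if (length(below) == 0 || below[1] == 1)
    return(list(gamma_crit = track$gamma[1], track = track))
  lo <- track$gamma[below[1] - 1]; hi <- track$gamma[below[1]]
  for (it in 1:25) {
    mid <- sqrt(lo * hi)
    hm <- hs(mid)
    if (is.na(hm)) break
    if (hm <= h_threshold) hi <- mid else lo <- mid
    if (hi / lo < 1.002) break
  }
  list(gamma_crit = sqrt(lo * hi), track = track)
}
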