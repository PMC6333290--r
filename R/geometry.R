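#' Swimmer configuration
#'
#' Morphology and beat parameters of the virtual monoflagellate. Defaults are
#' the virtual promastigote: a prolate ellipsoidal body with major/minor axes
#' 11 and 3.5 micrometres and a 13 micrometre flagellum beating with the
#' planar travelling wave
#' \deqn{x_2(\xi, t) = A[\sin(2\pi\xi/\lambda + 2\pi f t) - \sin(2\pi f t)],}
#' with amplitude A = 1.8 um, wavelength lambda = 13 um and frequency
#' f = 28 Hz. The wave travels tip-to-base ("puller"); reversing the beat
#' direction gives the morphologically identical pusher.
#'
#' @param body_major_axis full major axis of the body, micrometres.
#' @param body_minor_axis full minor axis, micrometres.
#' @param flagellum_length flagellar arclength L, micrometres.
#' @param flagellum_radius radius of the flagellar tube, micrometres.
#' @param beat_amplitude beat amplitude A, micrometres.
#' @param beat_wavelength beat wavelength lambda, micrometres.
#' @param beat_frequency beat frequency f, Hz.
#' @param beat_direction "puller" (tip-to-base wave) or "pusher" (reversed).
#' @param body_scale dimensionless multiplier applied to both body axes.
#' @return an object of class `swimmer_config`.
#' @export
swimmer_config <- function(body_major_axis = 11, body_minor_axis = 3.5,
                           flagellum_length = 13, flagellum_radius = 0.25,
                           beat_amplitude = 1.8, beat_wavelength = 13,
                           beat_frequency = 28,
                           beat_direction = c("puller", "pusher"),
                           body_scale = 1) {
  beat_direction <- match.arg(beat_direction)
  cfg <- list(body_major_axis = body_major_axis,
              body_minor_axis = body_minor_axis,
              flagellum_length = flagellum_length,
              flagellum_radius = flagellum_radius,
              beat_amplitude = beat_amplitude,
              beat_wavelength = beat_wavelength,
              beat_frequency = beat_frequency,
              beat_direction = beat_direction,
              body_scale = body_scale)
  lens <- unlist(cfg[c("body_major_axis", "body_minor_axis",
                       "flagellum_length", "flagellum_radius",
                       "beat_wavelength", "body_scale")])
  if (any(!is.finite(lens)) || any(lens <= 0))
    stop("all lengths and body_scale must be positive and finite")
  if (beat_frequency <= 0) stop("beat_frequency must be positive")
  if (beat_amplitude < 0) stop("beat_amplitude must be non-negative")
  if (beat_amplitude >= flagellum_length)
    stop("beat_amplitude must be smaller than the flagellum length")
  class(cfg) <- "swimmer_config"
  cfg
}

#' @export
print.swimmer_config <- function(x, ...) {
  cat("swimmer_config:", x$beat_direction, "\n")
  cat(sprintf("  body %.3g x %.3g um (scale %.3g), flagellum L = %.3g um (rho = %.3g um)\n",
              x$body_major_axis, x$body_minor_axis, x$body_scale,
              x$flagellum_length, x$flagellum_radius))
  cat(sprintf("  beat: A = %.3g um, lambda = %.3g um, f = %.3g Hz\n",
              x$beat_amplitude, x$beat_wavelength, x$beat_frequency))
  invisible(x)
}

# wave phase sign: +1 for the tip-to-base puller wave, -1 for the reversed
# (base-to-tip) pusher
.beat_sign <- function(config) if (config$beat_direction == "puller") 1 else -1

# lateral centerline displacement x2(xi, phase) and its xi-derivative
.beat_x2 <- function(config, phase, xi) {
  s <- .beat_sign(config)
  config$beat_amplitude *
    (sin(2 * pi * xi / config$beat_wavelength + s * 2 * pi * phase) -
       sin(s * 2 * pi * phase))
}
.beat_x2p <- function(config, phase, xi) {
  s <- .beat_sign(config)
  config$beat_amplitude * (2 * pi / config$beat_wavelength) *
    cos(2 * pi * xi / config$beat_wavelength + s * 2 * pi * phase)
}

# 5-point Gauss-Legendre nodes/weights on [0, 1]
.gl5x <- c(0.046910077030668, 0.230765344947158, 0.5,
           0.769234655052842, 0.953089922969332)
.gl5w <- c(0.118463442528095, 0.239314335249683, 0.284444444444444,
           0.239314335249683, 0.118463442528095)

# arclength of the centerline from 0 to each element of xi (vectorised),
# composite 5-point Gauss-Legendre with n subintervals per unit of the
# largest xi requested
.arclength <- function(config, phase, xi, n_per = 8) {
  vapply(xi, function(x) {
    if (x <= 0) return(0)
    nint <- max(4L, ceiling(x * n_per))
    h <- x / nint
    a <- h * (seq_len(nint) - 1)
    pts <- outer(a, h * .gl5x, "+")
    w <- rep(h * .gl5w, each = nint)
    sum(w * sqrt(1 + .beat_x2p(config, phase, as.vector(pts))^2))
  }, numeric(1))
}

#' Instantaneous upper parameter bound of the flagellar centerline
#'
#' The centerline is parametrised by xi in `[0, xi_star]`; `xi_star` is the
#' root of arclength(xi) = L, conserving flagellar length over the beat.
#'
#' @param config a [swimmer_config()].
#' @param phase beat phase in `[0, 1)`.
#' @return xi_star in micrometres.
#' @export
xi_star <- function(config, phase) {
  L <- config$flagellum_length
  if (config$beat_amplitude == 0) return(L)
  f <- function(x) .arclength(config, phase, x) - L
  r <- stats::uniroot(f, c(L / 2, L), tol = 1e-13 * L)
  if (abs(f(r$root)) > 1e-7 * L)
    stop(sprintf("xi_star root-finding did not converge (residual %.3g)",
                 f(r$root)))
  r$root
}

#' Flagellar centerline in the swimmer frame
#'
#' @param config a [swimmer_config()].
#' @param phase beat phase in `[0, 1)`.
#' @param xi parameter values, `0 <= xi <= xi_star(config, phase)`.
#' @return matrix with one row (x1, x2, x3) per xi value, micrometres.
#' @export
centerline_point <- function(config, phase, xi) {
  xs <- xi_star(config, phase)
  if (any(xi < -1e-12) || any(xi > xs * (1 + 1e-9)))
    stop("xi out of range [0, xi_star]")
  cbind(x1 = xi, x2 = .beat_x2(config, phase, xi), x3 = 0)
}

# invert the arclength map: xi such that arclength(xi) = s, by Newton
# iteration seeded from a cumulative-arclength grid
.xi_at_arclength <- function(config, phase, s) {
  L <- config$flagellum_length
  if (config$beat_amplitude == 0) return(s)
  ng <- 64L
  xg <- seq(0, L, length.out = ng + 1)
  h <- L / ng
  pts <- outer(xg[-(ng + 1)], h * .gl5x, "+")
  seg <- rowSums(matrix(sqrt(1 + .beat_x2p(config, phase, as.vector(pts))^2),
                        ng, 5) * rep(h * .gl5w, each = ng))
  Lam <- c(0, cumsum(seg))
  vapply(s, function(si) {
    if (si <= 0) return(0)
    k <- findInterval(si, Lam, rightmost.closed = TRUE)
    xi <- xg[k] + (si - Lam[k]) / (Lam[k + 1] - Lam[k]) * h
    for (it in 1:4) {
      res <- Lam[k] + .gl_arc(config, phase, xg[k], xi) - si
      xi <- xi - res / sqrt(1 + .beat_x2p(config, phase, xi)^2)
    }
    xi
  }, numeric(1))
}

# Gauss-Legendre arclength over [a, b] (single panel, 5 points is ample for
# the sub-grid intervals used by .xi_at_arclength)
.gl_arc <- function(config, phase, a, b) {
  h <- b - a
  sum(h * .gl5w * sqrt(1 + .beat_x2p(config, phase, a + h * .gl5x)^2))
}

# --- mesh parameter levels -------------------------------------------------

# refinement levels; level 1 reproduces the typical ~644-element surface.
# Tube azimuth counts are even so the node set is closed under the
# beat-plane half-period mirror (psi -> pi - psi), keeping the discrete
# surface exactly time-mirror symmetric.
.mesh_levels <- list(
  `0` = list(n_c = 6, n_az = 12, n_rings = 7, n_body = 4),
  `1` = list(n_c = 6, n_az = 12, n_rings = 15, n_body = 7),
  `2` = list(n_c = 12, n_az = 24, n_rings = 30, n_body = 14)
)

.mesh_params <- function(config, refinement) {
  p <- .mesh_levels[[as.character(refinement)]]
  if (is.null(p)) stop("refinement must be 0, 1 or 2")
  a <- config$body_major_axis / 2 * config$body_scale
  b <- config$body_minor_axis / 2 * config$body_scale
  rho <- config$flagellum_radius
  p$a <- a
  p$b <- b
  p$rho <- rho
  p$r_hole <- min(0.6, 0.55 * b)
  p$phi0 <- asin(min(p$r_hole / b, 0.8))
  p$s1 <- max(0.8, 1.2 * p$r_hole)   # first tube ring arclength
  p$s_end <- config$flagellum_length - rho
  p
}

# body meridian polar angles, uniform in meridian arclength from phi0 to pi;
# returns n_body ring angles (the pole itself is a fan vertex)
.body_phis <- function(p) {
  ng <- 400
  ph <- seq(p$phi0, pi, length.out = ng + 1)
  ds <- sqrt((p$a * sin(ph))^2 + (p$b * cos(ph))^2)
  cum <- c(0, cumsum((ds[-1] + ds[-(ng + 1)]) / 2 * diff(ph)))
  targ <- cum[ng + 1] * (seq_len(p$n_body) - 1) / p$n_body
  stats::approx(cum, ph, xout = targ)$y
}

# node positions for the fixed material parametrisation at a given phase
.mesh_nodes <- function(config, phase, p, mat) {
  n <- nrow(mat)
  out <- matrix(0, n, 3)
  body <- mat$kind == "body"
  if (any(body)) {
    out[body, 1] <- -p$a + p$a * cos(mat$phi[body])
    out[body, 2] <- p$b * sin(mat$phi[body]) * cos(mat$psi[body])
    out[body, 3] <- p$b * sin(mat$phi[body]) * sin(mat$psi[body])
  }
  pole <- mat$kind == "pole"
  out[pole, 1] <- -2 * p$a
  tube <- mat$kind == "tube"
  tip <- mat$kind == "tip"
  if (any(tube) || any(tip)) {
    svals <- c(mat$s[tube], config$flagellum_length)
    xiv <- .xi_at_arclength(config, phase, svals)
    if (any(tube)) {
      xi <- xiv[seq_len(sum(tube))]
      g <- .beat_x2(config, phase, xi)
      gp <- .beat_x2p(config, phase, xi)
      nu <- sqrt(1 + gp^2)
      # planar-curve normal (-g', 1, 0)/nu and binormal e3
      cpsi <- cos(mat$psi[tube])
      spsi <- sin(mat$psi[tube])
      out[tube, 1] <- xi + p$rho * cpsi * (-gp / nu)
      out[tube, 2] <- g + p$rho * cpsi * (1 / nu)
      out[tube, 3] <- p$rho * spsi
    }
    if (any(tip)) {
      xt <- xiv[length(xiv)]
      out[tip, ] <- rep(c(xt, .beat_x2(config, phase, xt), 0), each = sum(tip))
    }
  }
  out
}

# fixed topology: material table + triangle index matrix
.mesh_topology <- function(config, p) {
  n_c <- p$n_c; n_az <- p$n_az
  phis <- .body_phis(p)
  sr <- seq(p$s1, p$s_end, length.out = p$n_rings)

  mat <- list()
  idx <- 0L
  add <- function(kind, phi = NA, psi = NA, s = NA, n = 1) {
    mat[[length(mat) + 1]] <<- data.frame(kind = kind, phi = phi, psi = psi,
                                          s = s)
    idx <<- idx + n
    idx
  }
  # body rings (ring 1 = hole ring), row-major: ring k, azimuth i
  for (k in seq_len(p$n_body))
    add("body", phi = phis[k], psi = 2 * pi * (seq_len(n_az) - 1) / n_az,
        n = n_az)
  body_id <- function(k, i) (k - 1) * n_az + ((i - 1) %% n_az) + 1
  n_bodyv <- p$n_body * n_az
  # body quad centres
  for (k in seq_len(p$n_body - 1))
    add("body", phi = (phis[k] + phis[k + 1]) / 2,
        psi = 2 * pi * (seq_len(n_az) - 0.5) / n_az, n = n_az)
  bc_id <- function(k, i) n_bodyv + (k - 1) * n_az + ((i - 1) %% n_az) + 1
  n0 <- n_bodyv + (p$n_body - 1) * n_az
  pole_id <- add("pole")
  # tube rings
  for (j in seq_len(p$n_rings))
    add("tube", psi = 2 * pi * (seq_len(n_c) - 1) / n_c, s = sr[j], n = n_c)
  tube_id <- function(j, i) pole_id + (j - 1) * n_c + ((i - 1) %% n_c) + 1
  n1 <- pole_id + p$n_rings * n_c
  # tube quad centres
  for (j in seq_len(p$n_rings - 1))
    add("tube", psi = 2 * pi * (seq_len(n_c) - 0.5) / n_c,
        s = (sr[j] + sr[j + 1]) / 2, n = n_c)
  tc_id <- function(j, i) n1 + (j - 1) * n_c + ((i - 1) %% n_c) + 1
  tip_id <- add("tip")
  mat <- do.call(rbind, mat)

  tri <- list()
  push <- function(a, b, c) tri[[length(tri) + 1]] <<- c(a, b, c)
  # body quads, 4-way split (outward orientation: phi then psi)
  for (k in seq_len(p$n_body - 1)) for (i in seq_len(n_az)) {
    v00 <- body_id(k, i); v10 <- body_id(k + 1, i)
    v11 <- body_id(k + 1, i + 1); v01 <- body_id(k, i + 1)
    cc <- bc_id(k, i)
    push(v00, v10, cc); push(v10, v11, cc)
    push(v11, v01, cc); push(v01, v00, cc)
  }
  # back pole fan
  for (i in seq_len(n_az))
    push(body_id(p$n_body, i), pole_id, body_id(p$n_body, i + 1))
  # zipper band: hole ring (n_az = 2 n_c) to tube ring 1 (n_c)
  for (j in seq_len(n_c)) {
    H <- function(m) body_id(1, ((m - 1) %% n_az) + 1)
    m <- 2 * (j - 1) + 1
    push(H(m), H(m + 1), tube_id(1, j))
    push(H(m + 1), tube_id(1, j + 1), tube_id(1, j))
    push(H(m + 1), H(m + 2), tube_id(1, j + 1))
  }
  # tube quads, 4-way split (outward orientation: psi then s)
  for (j in seq_len(p$n_rings - 1)) for (i in seq_len(n_c)) {
    v00 <- tube_id(j, i); v01 <- tube_id(j, i + 1)
    v11 <- tube_id(j + 1, i + 1); v10 <- tube_id(j + 1, i)
    cc <- tc_id(j, i)
    push(v00, v01, cc); push(v01, v11, cc)
    push(v11, v10, cc); push(v10, v00, cc)
  }
  # tip fan
  for (i in seq_len(n_c))
    push(tube_id(p$n_rings, i), tube_id(p$n_rings, i + 1), tip_id)

  list(material = mat, tris = do.call(rbind, tri))
}

#' Build the triangulated swimmer surface
#'
#' Constructs the watertight body-plus-flagellum surface at a given beat
#' phase, with per-node beat velocities in the swimmer frame obtained by
#' central finite differencing of node positions at fixed material
#' coordinates (arclength fraction along the centerline and azimuth around
#' the tube).
#'
#' @param config a [swimmer_config()].
#' @param phase beat phase in `[0, 1)`.
#' @param refinement 0 (coarse), 1 (default, ~644 elements) or 2 (fine).
#' @param dt_frac central-difference step as a fraction of the beat period.
#' @return an object of class `surface_mesh`: `nodes` (n x 3, micrometres,
#'   swimmer frame), `tris` (m x 3 node indices), `node_velocities`
#'   (n x 3, micrometres per second, swimmer frame), `material`, `config`,
#'   `phase`.
#' @export
build_mesh <- function(config, phase = 0, refinement = 1, dt_frac = 1e-3) {
  p <- .mesh_params(config, refinement)
  topo <- .mesh_topology(config, p)
  nodes <- .mesh_nodes(config, phase, p, topo$material)
  if (config$beat_amplitude == 0) {
    vel <- matrix(0, nrow(nodes), 3)
  } else {
    Tb <- 1 / config$beat_frequency
    np <- .mesh_nodes(config, phase + dt_frac / 2, p, topo$material)
    nm <- .mesh_nodes(config, phase - dt_frac / 2, p, topo$material)
    vel <- (np - nm) / (dt_frac * Tb)
  }
  structure(list(nodes = nodes, tris = topo$tris, node_velocities = vel,
                 material = topo$material, params = p, config = config,
                 phase = phase %% 1, refinement = refinement),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh: %d nodes, %d triangles, phase %.4g\n",
              nrow(x$nodes), nrow(x$tris), x$phase))
  invisible(x)
}

#' Number of triangular elements of a mesh
#' @param mesh a `surface_mesh`.
#' @return integer element count.
#' @export
mesh_element_count <- function(mesh) nrow(mesh$tris)

#' Closed spheroid mesh
#'
#' Stand-alone prolate spheroid (or sphere) surface used for solver
#' verification: Stokes drag, Jeffery rotation rates and wall-load symmetry.
#'
#' @param a,b major and minor semi-axes, micrometres (major axis along x1).
#' @param center 3-vector centre position.
#' @param n_az azimuthal node count.
#' @param n_rows number of latitude rings.
#' @return a `surface_mesh` (zero node velocities).
#' @export
build_spheroid_mesh <- function(a, b, center = c(0, 0, 0), n_az = 12,
                                n_rows = 7) {
  phis <- seq(0, pi, length.out = n_rows + 2)[2:(n_rows + 1)]
  pos <- function(phi, psi)
    cbind(center[1] + a * cos(phi), center[2] + b * sin(phi) * cos(psi),
          center[3] + b * sin(phi) * sin(psi))
  psis <- 2 * pi * (seq_len(n_az) - 1) / n_az
  psic <- 2 * pi * (seq_len(n_az) - 0.5) / n_az
  nodes <- do.call(rbind, lapply(phis, function(ph) pos(ph, psis)))
  id <- function(k, i) (k - 1) * n_az + ((i - 1) %% n_az) + 1
  nv <- n_rows * n_az
  cen <- do.call(rbind, lapply(seq_len(n_rows - 1), function(k)
    pos((phis[k] + phis[k + 1]) / 2, psic)))
  cid <- function(k, i) nv + (k - 1) * n_az + ((i - 1) %% n_az) + 1
  front <- nv + (n_rows - 1) * n_az + 1
  back <- front + 1
  nodes <- rbind(nodes, cen, pos(0, 0), pos(pi, 0))
  tri <- list()
  push <- function(a1, b1, c1) tri[[length(tri) + 1]] <<- c(a1, b1, c1)
  for (i in seq_len(n_az)) push(id(1, i + 1), front, id(1, i))
  for (k in seq_len(n_rows - 1)) for (i in seq_len(n_az)) {
    v00 <- id(k, i); v10 <- id(k + 1, i)
    v11 <- id(k + 1, i + 1); v01 <- id(k, i + 1)
    cc <- cid(k, i)
    push(v00, v10, cc); push(v10, v11, cc)
    push(v11, v01, cc); push(v01, v00, cc)
  }
  for (i in seq_len(n_az)) push(id(n_rows, i), back, id(n_rows, i + 1))
  tris <- do.call(rbind, tri)
  structure(list(nodes = nodes, tris = tris,
                 node_velocities = matrix(0, nrow(nodes), 3),
                 material = data.frame(kind = rep("body", nrow(nodes))),
                 params = list(a = a, b = b), config = NULL, phase = 0),
            class = "surface_mesh")
}

# --- mesh derived quantities ----------------------------------------------

.tri_geom <- function(mesh) {
  v0 <- mesh$nodes[mesh$tris[, 1], , drop = FALSE]
  v1 <- mesh$nodes[mesh$tris[, 2], , drop = FALSE]
  v2 <- mesh$nodes[mesh$tris[, 3], , drop = FALSE]
  e1 <- v1 - v0
  e2 <- v2 - v0
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  area2 <- sqrt(rowSums(cr^2))
  list(centroids = (v0 + v1 + v2) / 3, areas = area2 / 2,
       normals = cr / area2)
}

#' Element areas, centroids and outward normals
#' @param mesh a `surface_mesh`.
#' @return list with `centroids`, `areas`, `normals`.
#' @export
mesh_geometry <- function(mesh) .tri_geom(mesh)

#' Signed enclosed volume (divergence theorem; positive for outward normals)
#' @param mesh a `surface_mesh`.
#' @return volume in cubic micrometres.
#' @export
mesh_volume <- function(mesh) {
  g <- .tri_geom(mesh)
  sum(rowSums(g$centroids * g$normals) * g$areas) / 3
}

#' Watertightness and orientation checks
#'
#' A closed orientable genus-0 surface has every undirected edge shared by
#' exactly two triangles, every directed edge appearing exactly once (the
#' two incident triangles traverse it in opposite directions), and Euler
#' characteristic V - E + F = 2.
#'
#' @param mesh a `surface_mesh`.
#' @return list with `watertight` (logical), `euler` (V - E + F),
#'   `oriented` (logical), `min_area`, `normal_closure` (|sum n dS| / area).
#' @export
mesh_check <- function(mesh) {
  tr <- mesh$tris
  de <- rbind(tr[, 1:2], tr[, 2:3], tr[, c(3, 1)])
  dkey <- paste(de[, 1], de[, 2])
  ukey <- paste(pmin(de[, 1], de[, 2]), pmax(de[, 1], de[, 2]))
  utab <- table(ukey)
  watertight <- all(utab == 2)
  oriented <- !any(duplicated(dkey))
  V <- length(unique(as.vector(tr)))
  E <- length(utab)
  Fc <- nrow(tr)
  g <- .tri_geom(mesh)
  list(watertight = watertight, euler = V - E + Fc, oriented = oriented,
       min_area = min(g$areas),
       normal_closure = sqrt(sum(colSums(g$normals * g$areas)^2)) /
         sum(g$areas))
}

#' Per-node beat velocities at a configuration
#'
#' Finite-difference material velocity of every surface node in the swimmer
#' frame; body nodes are rigid and return zero.
#'
#' @param config a [swimmer_config()].
#' @param phase beat phase.
#' @param dt_frac central-difference step, fraction of a beat period.
#' @param refinement mesh refinement level.
#' @return n x 3 matrix, micrometres per second.
#' @export
beat_surface_velocity <- function(config, phase, dt_frac = 1e-3,
                                  refinement = 1) {
  build_mesh(config, phase, refinement, dt_frac)$node_velocities
}

#' Analytic surface area of a prolate spheroid
#' @param a,b major and minor semi-axes.
#' @return surface area.
#' @export
spheroid_area <- function(a, b) {
  if (abs(a - b) < 1e-14 * a) return(4 * pi * a^2)
  e <- sqrt(1 - (b / a)^2)
  2 * pi * b^2 * (1 + (a / (b * e)) * asin(e))
}

# --- transforms ------------------------------------------------------------

#' Transform a mesh from the swimmer frame to the laboratory frame
#' @param mesh a `surface_mesh` in the swimmer frame.
#' @param rotation 3 x 3 rotation matrix (swimmer to lab).
#' @param translation lab-frame position of the swimmer origin x0.
#' @return a `surface_mesh` in lab coordinates (velocities rotated).
#' @export
transform_mesh <- function(mesh, rotation, translation = c(0, 0, 0)) {
  mesh$nodes <- sweep(mesh$nodes %*% t(rotation), 2, translation, "+")
  mesh$node_velocities <- mesh$node_velocities %*% t(rotation)
  mesh
}

# --- exporters -------------------------------------------------------------

#' Write a mesh as legacy ASCII VTK with the beat velocity as point data
#' @param mesh a `surface_mesh`.
#' @param file output path.
#' @return the path, invisibly.
#' @export
mesh_to_vtk <- function(mesh, file) {
  n <- nrow(mesh$nodes)
  m <- nrow(mesh$tris)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "swimmer surface", "ASCII",
               "DATASET POLYDATA", sprintf("POINTS %d double", n)), con)
  utils::write.table(format(mesh$nodes, digits = 12), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines(sprintf("POLYGONS %d %d", m, 4 * m), con)
  utils::write.table(cbind(3L, mesh$tris - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  writeLines(c(sprintf("POINT_DATA %d", n),
               "VECTORS beat_velocity double"), con)
  utils::write.table(format(mesh$node_velocities, digits = 12), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Write a mesh as ASCII PLY
#' @param mesh a `surface_mesh`.
#' @param file output path.
#' @return the path, invisibly.
#' @export
mesh_to_ply <- function(mesh, file) {
  n <- nrow(mesh$nodes)
  m <- nrow(mesh$tris)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0", sprintf("element vertex %d", n),
               "property double x", "property double y", "property double z",
               "property double vx", "property double vy",
               "property double vz", sprintf("element face %d", m),
               "property list uchar int vertex_indices", "end_header"), con)
  utils::write.table(format(cbind(mesh$nodes, mesh$node_velocities),
                            digits = 12), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  utils::write.table(cbind(3L, mesh$tris - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(file)
}
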