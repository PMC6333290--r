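#' Short-range repulsive wall force model
#'
#' Steric repulsion between the swimmer surface and the plane boundary,
#' given per unit surface area along the outward wall normal as
#' \deqn{f_{wall}(s) = g (\mu/T_d) e^{-s/l} / (1 - e^{-s/l}),}
#' with separation s, dimensionless strength g, decay length l much smaller
#' than the cell scale, and T_d the beat period (the force scales with
#' viscosity over beat period).
#'
#' @param g dimensionless strength.
#' @param l decay length, micrometres.
#' @param enabled logical.
#' @return a `wall_repulsion` object.
#' @export
wall_repulsion <- function(g = 1250, l = 0.2, enabled = TRUE) {
  if (g <= 0 || l <= 0) stop("g and l must be positive")
  structure(list(g = g, l = l, enabled = enabled), class = "wall_repulsion")
}

#' Repulsive force density at separation s
#'
#' @param s separation from the wall, micrometres (must be positive).
#' @param rep a [wall_repulsion()].
#' @param mu dynamic viscosity, Pa s.
#' @param beat_frequency beat frequency f = 1/T_d, Hz.
#' @return force per unit area (Pa) directed along the outward wall normal;
#'   vectorised over `s`.
#' @export
repulsion_density <- function(s, rep, mu = 8.9e-4, beat_frequency = 28) {
  if (any(s <= 0))
    stop("repulsion_density requires positive separation s")
  e <- exp(-s / rep$l)
  rep$g * mu * beat_frequency * e / (1 - e)
}

#' Net repulsive wall load on a swimmer
#'
#' Element-wise quadrature of the repulsive force density over the swimmer
#' surface (wall at x1 = 0), using each element's centroid separation.
#' The returned load is passed to [solve_mobility()] as the external
#' force/torque, so that the hydrodynamic load balances it.
#'
#' @param mesh a `surface_mesh` in lab coordinates (fluid side x1 > 0).
#' @param x0 reference point for the torque.
#' @param rep a [wall_repulsion()].
#' @param mu dynamic viscosity, Pa s.
#' @param beat_frequency beat frequency, Hz.
#' @return list with `force` (pN) and `torque` (pN um) about x0.
#' @export
net_wall_load <- function(mesh, x0, rep, mu = 8.9e-4, beat_frequency = 28) {
  g <- .tri_geom(mesh)
  s <- g$centroids[, 1]
  if (any(s <= 0)) stop("mesh element behind the wall plane")
  dens <- repulsion_density(s, rep, mu, beat_frequency)
  f1 <- dens * g$areas                       # force along +x1 per element
  r <- sweep(g$centroids, 2, x0)
  # torque = r x (f1, 0, 0)
  list(force = c(sum(f1), 0, 0),
       torque = c(0, sum(r[, 3] * f1), -sum(r[, 2] * f1)))
}
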