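#' Free-space Stokeslet (Oseen) tensor
#'
#' Velocity Green's function of three-dimensional Stokes flow:
#' `G_ij = delta_ij/|r| + r_i r_j/|r|^3` with `r = x - x0`, normalised so that
#' a point force F at x0 induces velocity `G F / (8 pi mu)`.
#'
#' @param x field point (3-vector).
#' @param x0 source point (3-vector).
#' @return 3 x 3 matrix.
#' @export
stokeslet <- function(x, x0) {
  if (sum((x - x0)^2) == 0) stop("stokeslet is singular at coincident points")
  stokeslet_cpp(as.numeric(x), as.numeric(x0))
}

#' Free-space stress Green's function
#'
#' `T_ijk = -6 r_i r_j r_k / |r|^5`, the kernel of the double-layer
#' potential. Exposed for verification; the solver uses a single-layer
#' representation only.
#'
#' @param x field point.
#' @param x0 source point.
#' @return 3 x 3 x 3 array.
#' @export
stresslet <- function(x, x0) {
  if (sum((x - x0)^2) == 0) stop("stresslet is singular at coincident points")
  stresslet_cpp(as.numeric(x), as.numeric(x0))
}

#' Blake wall Green's function
#'
#' Image-system velocity kernel enforcing no slip on the plane x1 = 0 (fluid
#' occupies x1 > 0): free-space Stokeslet plus an image Stokeslet, potential
#' dipole and Stokeslet doublet at the mirrored source point. The induced
#' velocity vanishes identically on the wall plane and tends to the
#' free-space Stokeslet as the source recedes from the wall.
#'
#' @param x field point, `x[1] > 0`.
#' @param x0 source point, `x0[1] > 0`.
#' @return 3 x 3 matrix `G` such that a point force F induces
#'   `u = G F / (8 pi mu)` at x.
#' @export
blake_kernel <- function(x, x0) {
  if (x[1] <= 0 || x0[1] <= 0)
    stop("blake_kernel requires both points strictly on the fluid side x1 > 0")
  blake_cpp(as.numeric(x), as.numeric(x0))
}

#' Background flow model
#'
#' Linear shear in the bulk, `u_b = gamma_d (x2, 0, 0)`, or wall-bounded
#' shear `u_b = gamma_d (0, -x1, 0)` vanishing on the no-slip plane x1 = 0;
#' optionally a uniform stream. Viscosity defaults to water at 25 C.
#'
#' @param gamma_d shear rate, 1/s.
#' @param geometry "bulk_shear", "wall_shear" or "quiescent".
#' @param mu dynamic viscosity, Pa s.
#' @param wall_present logical; must be TRUE for wall_shear.
#' @param repulsion optional [wall_repulsion()] model.
#' @param uniform uniform background velocity added to the shear (um/s).
#' @return a `flow_model` object.
#' @export
flow_model <- function(gamma_d = 0,
                       geometry = c("bulk_shear", "wall_shear", "quiescent"),
                       mu = 8.9e-4, wall_present = FALSE, repulsion = NULL,
                       uniform = c(0, 0, 0)) {
  geometry <- match.arg(geometry)
  if (geometry == "wall_shear" && !wall_present)
    stop("wall_shear requires wall_present = TRUE")
  structure(list(gamma_d = gamma_d, geometry = geometry, mu = mu,
                 wall_present = wall_present, repulsion = repulsion,
                 uniform = uniform), class = "flow_model")
}

#' Background velocity field
#' @param flow a [flow_model()].
#' @param x points: 3-vector or n x 3 matrix (lab frame, micrometres).
#' @return velocities in the same shape, micrometres per second.
#' @export
background_velocity <- function(flow, x) {
  xm <- if (is.matrix(x)) x else matrix(x, 1)
  u <- matrix(rep(flow$uniform, each = nrow(xm)), ncol = 3)
  if (flow$geometry == "bulk_shear") {
    u[, 1] <- u[, 1] + flow$gamma_d * xm[, 2]
  } else if (flow$geometry == "wall_shear") {
    u[, 2] <- u[, 2] - flow$gamma_d * xm[, 1]
  }
  if (is.matrix(x)) u else u[1, ]
}

# per-element surface velocity: mean of node values over each triangle
.element_values <- function(mesh, nodal) {
  (nodal[mesh$tris[, 1], , drop = FALSE] +
     nodal[mesh$tris[, 2], , drop = FALSE] +
     nodal[mesh$tris[, 3], , drop = FALSE]) / 3
}

#' Solve the mobility problem
#'
#' First-kind single-layer boundary-element solve for the rigid-body
#' velocities of a force- and torque-balanced swimmer with prescribed beat
#' velocity, in a background flow, optionally above a no-slip wall at
#' x1 = 0 (Blake kernels). The mesh must already be expressed in laboratory
#' coordinates with `node_velocities` holding the lab-frame beat velocity.
#'
#' @param mesh a `surface_mesh` in lab coordinates.
#' @param x0 lab-frame position of the swimmer origin (flagellar attachment).
#' @param flow a [flow_model()].
#' @param external_force,external_torque external load on the swimmer
#'   (for example the repulsive wall load), in viscosity-scaled units of
#'   Pa um^2 (piconewtons) and Pa um^3; the hydrodynamic load balances it.
#' @return list with `U` (um/s), `Omega` (rad/s), `tractions` (per-element
#'   single-layer density, Pa), `residual`.
#' @export
solve_mobility <- function(mesh, x0 = c(0, 0, 0), flow = flow_model(),
                           external_force = c(0, 0, 0),
                           external_torque = c(0, 0, 0)) {
  wall <- isTRUE(flow$wall_present)
  if (wall && any(mesh$nodes[, 1] <= 0))
    stop("mesh penetrates the wall plane x1 = 0")
  g <- .tri_geom(mesh)
  uslip <- .element_values(mesh, mesh$node_velocities)
  ub <- background_velocity(flow, g$centroids)
  sol <- bem_mobility_cpp(mesh$nodes, mesh$tris - 1L, uslip, ub,
                          as.numeric(x0), as.numeric(external_force) / flow$mu,
                          as.numeric(external_torque) / flow$mu, wall)
  list(U = as.numeric(sol$U), Omega = as.numeric(sol$Omega),
       tractions = sol$q * flow$mu, residual = sol$residual)
}

#' Solve a resistance problem
#'
#' Prescribes the full rigid-body surface motion `U + Omega x (x - x0)` plus
#' any beat velocity stored in the mesh, and returns the hydrodynamic force
#' and torque the fluid exerts on the body. Used for drag verification.
#'
#' @param mesh a `surface_mesh` in lab coordinates.
#' @param U,Omega prescribed rigid-body velocities.
#' @param x0 reference point for Omega and torque.
#' @param flow a [flow_model()].
#' @return list with `force` (pN), `torque` (pN um), `tractions` (Pa).
#' @export
solve_resistance <- function(mesh, U = c(0, 0, 0), Omega = c(0, 0, 0),
                             x0 = c(0, 0, 0), flow = flow_model()) {
  wall <- isTRUE(flow$wall_present)
  if (wall && any(mesh$nodes[, 1] <= 0))
    stop("mesh penetrates the wall plane x1 = 0")
  g <- .tri_geom(mesh)
  r <- sweep(g$centroids, 2, x0)
  urb <- matrix(U, nrow(r), 3, byrow = TRUE) +
    cbind(Omega[2] * r[, 3] - Omega[3] * r[, 2],
          Omega[3] * r[, 1] - Omega[1] * r[, 3],
          Omega[1] * r[, 2] - Omega[2] * r[, 1])
  u_el <- urb + .element_values(mesh, mesh$node_velocities)
  ub <- background_velocity(flow, g$centroids)
  sol <- bem_resistance_cpp(mesh$nodes, mesh$tris - 1L, u_el, ub,
                            as.numeric(x0), wall)
  list(force = as.numeric(sol$force) * flow$mu,
       torque = as.numeric(sol$torque) * flow$mu,
       tractions = sol$q * flow$mu)
}

# multi-right-hand-side mobility solve: one assembly/factorisation of the
# boundary-element operator, many background flows / external loads.
# ub_list: list of nt x 3 matrices; fext, text: 3 x nrhs matrices.
.solve_mobility_multi <- function(mesh, x0, ub_list, mu,
                                  fext = NULL, text = NULL, wall = FALSE) {
  nr <- length(ub_list)
  uslip <- .element_values(mesh, mesh$node_velocities)
  if (is.null(fext)) fext <- matrix(0, 3, nr)
  if (is.null(text)) text <- matrix(0, 3, nr)
  ubc <- array(unlist(ub_list), dim = c(nrow(uslip), 3, nr))
  sol <- bem_mobility_multi_cpp(mesh$nodes, mesh$tris - 1L, uslip, ubc,
                                as.numeric(x0), fext / mu, text / mu, wall)
  list(U = sol$U, Omega = sol$Omega)
}
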