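test_that("a force-free sphere is advected with a uniform flow", {
  fl <- flow_model(mu = fx_mu, uniform = c(1.3, -0.4, 2))
  s <- solve_mobility(fx_sphere(), c(0, 0, 0), fl)
  expect_rel_equal(s$U, c(1.3, -0.4, 2), 0.01)
  expect_lt(max(abs(s$Omega)), 1e-8)
  expect_lt(s$residual, 1e-10)
})

test_that("a freely suspended sphere rotates at half the vorticity", {
  fl <- flow_model(gamma_d = 2, geometry = "bulk_shear", mu = fx_mu)
  s <- solve_mobility(fx_sphere(), c(0, 0, 0), fl)
  expect_rel_equal(s$Omega[3], -1, 0.01)   # vorticity of u = (g x2,0,0) is -g
  expect_lt(max(abs(s$Omega[1:2])), 1e-4)
})

test_that("resistance solve reproduces the Stokes drag law", {
  res <- solve_resistance(fx_sphere(), U = c(1, 0, 0),
                          flow = flow_model(mu = fx_mu))
  expect_rel_equal(-res$force[1], 6 * pi * fx_mu * 1, 0.02)
  expect_lt(max(abs(res$force[2:3])) / abs(res$force[1]), 1e-6)
})

test_that("sphere drag error decreases monotonically with refinement", {
  errs <- vapply(list(c(8, 5), c(12, 7), c(16, 9)), function(nn) {
    m <- build_spheroid_mesh(1, 1, n_az = nn[1], n_rows = nn[2])
    r <- solve_resistance(m, U = c(1, 0, 0), flow = flow_model(mu = fx_mu))
    abs(-r$force[1] / (6 * pi * fx_mu) - 1)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("passive prolate spheroid follows Jeffery's rotation rate", {
  r <- 3
  sp <- build_spheroid_mesh(3, 1, n_az = 12, n_rows = 9)
  for (th in c(0, pi / 6, pi / 2, 2.5, 4)) {
    ml <- transform_mesh(sp, promaswim:::.rot_z(th))
    s <- solve_mobility(ml, c(0, 0, 0),
                        flow_model(gamma_d = 1, mu = fx_mu))
    expect_rel_equal(-s$Omega[3], jeffery_rate(th, r, 1), 0.02)
  }
})

test_that("tractions integrate to the supplied external load", {
  fl <- flow_model(mu = fx_mu)
  fext <- c(2e-3, -1e-3, 5e-4)
  text <- c(0, 3e-3, -1e-3)
  s <- solve_mobility(fx_sphere(), c(0, 0, 0), fl, fext, text)
  g <- mesh_geometry(fx_sphere())
  F <- colSums(s$tractions * g$areas)
  r <- g$centroids
  Tq <- colSums(cbind(r[, 2] * s$tractions[, 3] - r[, 3] * s$tractions[, 2],
                      r[, 3] * s$tractions[, 1] - r[, 1] * s$tractions[, 3],
                      r[, 1] * s$tractions[, 2] - r[, 2] * s$tractions[, 1]) *
                  g$areas)
  expect_rel_equal(F, fext, 1e-8)
  expect_rel_equal(Tq, text, 1e-8)
})

test_that("rigid-body velocities are affine in the shear rate", {
  m <- build_mesh(fx_config(), 0.15, refinement = 0)
  sol <- lapply(c(0, 1, 2), function(g)
    solve_mobility(m, c(0, 0, 0), flow_model(g, "bulk_shear", fx_mu)))
  lin <- function(f) {
    v0 <- f(sol[[1]]); v1 <- f(sol[[2]]); v2 <- f(sol[[3]])
    max(abs(v2 - 2 * v1 + v0)) / max(abs(v1), 1e-12)
  }
  expect_lt(lin(function(s) s$U), 1e-6)
  expect_lt(lin(function(s) s$Omega), 1e-6)
})

test_that("wall solution approaches the free-space solution far away", {
  m <- build_mesh(fx_config(), 0.3, refinement = 0)
  free <- solve_mobility(m, c(0, 0, 0),
                         flow_model(geometry = "quiescent", mu = fx_mu))
  far <- c(2e4, 0, 0)   # about one thousand body lengths from the wall
  mw <- transform_mesh(m, diag(3), far)
  wallfl <- flow_model(geometry = "quiescent", mu = fx_mu,
                       wall_present = TRUE)
  ws <- solve_mobility(mw, far, wallfl)
  expect_rel_equal(ws$U, free$U, 1e-3)
})

test_that("pusher and puller are exact time reversals in free space", {
  cfgp <- fx_config()
  cfgr <- swimmer_config(beat_direction = "pusher")
  fl <- flow_model(geometry = "quiescent", mu = fx_mu)
  Up <- rowMeans(sapply((0:7) / 8, function(p)
    solve_mobility(build_mesh(cfgp, p, 0), c(0, 0, 0), fl)$U))
  Ur <- rowMeans(sapply((0:7) / 8, function(p)
    solve_mobility(build_mesh(cfgr, p, 0), c(0, 0, 0), fl)$U))
  expect_lt(abs(Ur[1] + Up[1]) / abs(Up[1]), 1e-6)
})

test_that("wall-penetrating meshes are rejected", {
  m <- transform_mesh(build_mesh(fx_config(), 0, 0), diag(3), c(1, 0, 0))
  expect_error(
    solve_mobility(m, c(1, 0, 0),
                   flow_model(1, "wall_shear", fx_mu, wall_present = TRUE)),
    "penetrates")
})
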