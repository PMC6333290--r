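test_that("repulsion density has the stated form and limits", {
  rep <- wall_repulsion()
  f <- 28
  # direct substitution at one decay length
  expect_rel_equal(repulsion_density(0.2, rep, fx_mu, f),
                   1250 * fx_mu * f * exp(-1) / (1 - exp(-1)), 1e-12)
  # exponential decay to zero far away
  expect_lt(repulsion_density(10, rep, fx_mu, f),
            1e-12 * repulsion_density(0.2, rep, fx_mu, f))
  # strictly monotone decreasing on (0, inf)
  s <- exp(seq(log(1e-3), log(5), length.out = 400))
  expect_true(all(diff(repulsion_density(s, rep, fx_mu, f)) < 0))
  expect_error(repulsion_density(-0.1, rep), "positive")
  expect_error(wall_repulsion(g = -1), "positive")
})

test_that("net wall load decays, points away from the wall, and balances", {
  rep <- wall_repulsion()
  m <- build_mesh(fx_config(), 0.2, refinement = 0)
  near_h <- 4.0
  mnear <- transform_mesh(m, promaswim:::.rot_z(pi / 2), c(near_h, 0, 0))
  near <- net_wall_load(mnear, c(near_h, 0, 0), rep, fx_mu, 28)
  expect_gt(near$force[1], 0)
  mfar <- transform_mesh(m, promaswim:::.rot_z(pi / 2), c(100, 0, 0))
  far <- net_wall_load(mfar, c(100, 0, 0), rep, fx_mu, 28)
  expect_lt(abs(far$force[1]), 1e-12 * near$force[1])
})

test_that("wall load torque vanishes for a wall-parallel spheroid", {
  rep <- wall_repulsion()
  # major axis parallel to the wall at height 2.2
  sp <- transform_mesh(build_spheroid_mesh(5.5, 1.75, n_az = 16,
                                           n_rows = 11),
                       promaswim:::.rot_z(pi / 2), c(2.2, 0, 0))
  load <- net_wall_load(sp, c(2.2, 0, 0), rep, fx_mu, 28)
  # fore-aft and mirror symmetry: no torque about any axis
  expect_lt(max(abs(load$torque)), 1e-8 * load$force[1] * 5.5)
  expect_equal(load$force[2:3], c(0, 0), tolerance = 1e-12)
})

test_that("net wall load is continuous in the swimmer state", {
  rep <- wall_repulsion()
  m <- build_mesh(fx_config(), 0.2, refinement = 0)
  hs <- seq(3.8, 4.3, length.out = 21)
  fz <- vapply(hs, function(h) {
    ml <- transform_mesh(m, promaswim:::.rot_z(pi / 2), c(h, 0, 0))
    net_wall_load(ml, c(h, 0, 0), rep, fx_mu, 28)$force[1]
  }, numeric(1))
  expect_true(all(diff(fz) < 0))
  # relative jumps between adjacent samples stay bounded (smooth decay)
  expect_lt(max(abs(diff(log(fz)))), 1.6 * max(abs(diff(hs))) / rep$l)
})

test_that("repulsion keeps a near-wall swimmer far from the 2 nm halt", {
  cfg <- fx_config()
  rep <- wall_repulsion()
  flow <- flow_model(1, "wall_shear", fx_mu, wall_present = TRUE,
                     repulsion = rep)
  sup <- promaswim:::.planar_support(cfg, 0)
  th0 <- 4.6
  h0 <- sup(th0) + 0.35    # clearance about one third of a micrometre
  st <- planar_state(th0, h0)
  tr <- simulate_swimmer(st, 0.12, cfg, flow, dt = 1 / (28 * 40),
                         refinement = 0)
  expect_identical(tr$halt_reason, "completed")
  expect_gt(min(tr$states$clearance, na.rm = TRUE), 0.05)
})
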