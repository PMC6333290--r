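test_that("centerline obeys the prescribed planar beat", {
  cfg <- fx_config()
  # attachment point is pinned to the body at every phase
  for (p in c(0, 0.21, 0.5, 0.83))
    expect_equal(centerline_point(cfg, p, 0), cbind(x1 = 0, x2 = 0, x3 = 0),
                 tolerance = 1e-14)
  # quarter-wavelength point at phase 0 reaches the full amplitude
  expect_equal(centerline_point(cfg, 0, 13 / 4)[2], 1.8 * sin(pi / 2),
               tolerance = 1e-12)
  # shape is exactly periodic in phase
  xi <- seq(0, 10, length.out = 7)
  expect_equal(centerline_point(cfg, 0.37, xi),
               centerline_point(cfg, 1.37, xi), tolerance = 1e-12)
  expect_error(centerline_point(cfg, 0, 20), "out of range")
})

test_that("xi_star conserves flagellar arclength at every phase", {
  cfg <- fx_config()
  # straight flagellum: parameter bound equals the length
  cfg0 <- swimmer_config(beat_amplitude = 1e-12)
  cfg0$beat_amplitude <- 0
  expect_equal(xi_star(cfg0, 0.3), 13)
  # curved: strictly shorter parameter range than arclength
  phases <- (0:39) / 40
  xs <- vapply(phases, function(p) xi_star(cfg, p), numeric(1))
  expect_true(all(xs < 13))
  # independent oracle: fine trapezoidal quadrature of the arclength
  for (p in phases) {
    x <- xi_star(cfg, p)
    xi <- seq(0, x, length.out = 20001)
    sl <- sqrt(1 + promaswim:::.beat_x2p(cfg, p, xi)^2)
    arc <- sum((sl[-1] + sl[-20001]) / 2 * diff(xi))
    expect_lt(abs(arc - 13) / 13, 1e-6)
  }
})

test_that("swimmer surface is watertight, oriented and genus zero", {
  cfg <- fx_config()
  for (lev in 0:2) for (p in c(0, 0.37)) {
    m <- build_mesh(cfg, p, refinement = lev)
    ck <- mesh_check(m)
    expect_true(ck$watertight)
    expect_true(ck$oriented)
    expect_identical(ck$euler, 2L)
    expect_gt(ck$min_area, 0)
    expect_lt(ck$normal_closure, 1e-12)
    expect_gt(mesh_volume(m), 0)
  }
})

test_that("default refinement reproduces the typical element count", {
  m <- build_mesh(fx_config(), 0, refinement = 1)
  expect_lt(abs(mesh_element_count(m) - 644) / 644, 0.05)
})

test_that("straight-beat body sub-mesh area matches the analytic spheroid", {
  cfg <- swimmer_config()
  cfg$beat_amplitude <- 0
  m <- build_mesh(cfg, 0, refinement = 2)
  body_nodes <- which(m$material$kind %in% c("body", "pole"))
  keep <- apply(matrix(m$tris %in% body_nodes, ncol = 3), 1, all)
  g <- mesh_geometry(m)
  area <- sum(g$areas[keep])
  # analytic spheroid area minus the polar cap removed for the flagellum
  a <- 5.5; b <- 1.75
  phi0 <- m$params$phi0
  phis <- seq(0, phi0, length.out = 2001)
  ds <- sqrt((a * sin(phis))^2 + (b * cos(phis))^2)
  cap <- sum(2 * pi * b * sin(phis) * ds * c(diff(phis) / 2, 0) +
               2 * pi * b * sin(phis) * ds * c(0, diff(phis) / 2))
  expect_lt(abs(area - (spheroid_area(a, b) - cap)) /
              spheroid_area(a, b), 0.02)
})

test_that("beat surface velocities are material and second-order accurate", {
  cfg <- fx_config()
  # no beat: static shape
  cfg0 <- cfg; cfg0$beat_amplitude <- 0
  expect_equal(max(abs(beat_surface_velocity(cfg0, 0.4, refinement = 0))), 0)
  # body nodes rigid at every phase
  for (p in c(0.1, 0.6)) {
    m <- build_mesh(cfg, p, refinement = 0)
    body <- m$material$kind %in% c("body", "pole")
    expect_equal(max(abs(m$node_velocities[body, ])), 0)
    expect_gt(max(abs(m$node_velocities[!body, ])), 10)
  }
  # time average of material velocities over a closed beat vanishes
  vbar <- Reduce(`+`, lapply((0:39) / 40, function(p)
    build_mesh(cfg, p, refinement = 0)$node_velocities)) / 40
  expect_lt(max(abs(vbar)), 1e-4 * 1.8 * 2 * pi * 28)
  # Richardson: central difference converges at second order in dt_frac
  v1 <- beat_surface_velocity(cfg, 0.3, dt_frac = 4e-3, refinement = 0)
  v2 <- beat_surface_velocity(cfg, 0.3, dt_frac = 2e-3, refinement = 0)
  v3 <- beat_surface_velocity(cfg, 0.3, dt_frac = 1e-3, refinement = 0)
  r <- max(abs(v1 - v2)) / max(abs(v2 - v3))
  expect_gt(r, 3.3)
  expect_lt(r, 4.7)
})

test_that("spheroid meshes are watertight with correct volume", {
  m <- fx_sphere()
  ck <- mesh_check(m)
  expect_true(ck$watertight && ck$oriented)
  expect_identical(ck$euler, 2L)
  expect_rel_equal(mesh_volume(m), 4 / 3 * pi, 0.05)
  m2 <- build_spheroid_mesh(3, 1, n_az = 12, n_rows = 9)
  expect_rel_equal(mesh_volume(m2), 4 / 3 * pi * 3, 0.05)
})

test_that("mesh exporters write valid text formats", {
  m <- build_mesh(fx_config(), 0, refinement = 0)
  fv <- tempfile(fileext = ".vtk")
  fp <- tempfile(fileext = ".ply")
  mesh_to_vtk(m, fv)
  mesh_to_ply(m, fp)
  lv <- readLines(fv)
  expect_identical(lv[1], "# vtk DataFile Version 3.0")
  expect_true(any(grepl("^POINTS", lv)))
  expect_true(any(grepl("^VECTORS beat_velocity", lv)))
  lp <- readLines(fp)
  expect_identical(lp[1], "ply")
  expect_identical(sum(lp == "end_header"), 1L)
  unlink(c(fv, fp))
})

test_that("invalid configurations are rejected", {
  expect_error(swimmer_config(beat_frequency = -1), "positive")
  expect_error(swimmer_config(body_minor_axis = 0), "positive")
  expect_error(swimmer_config(beat_amplitude = 20), "smaller")
})
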