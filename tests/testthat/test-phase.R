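test_that("phase average of a passive body equals the single-phase solve", {
  cfg <- fx_config()
  cfg$beat_amplitude <- 0
  fl <- flow_model(1, "bulk_shear", fx_mu)
  one <- solve_mobility(build_mesh(cfg, 0, 0), c(0, 0, 0), fl)
  avg <- phase_average(cfg, swimmer_state(), fl, n_phases = 3,
                       refinement = 0)
  expect_rel_equal(avg$U, one$U, 1e-9)
  expect_rel_equal(avg$Omega, one$Omega, 1e-9)
})

test_that("phase averaging is frame covariant", {
  # rotating the frozen configuration rotates the averaged velocities
  cfg <- fx_config()
  fl0 <- flow_model(geometry = "quiescent", mu = fx_mu)
  th <- 0.7
  a0 <- phase_average(cfg, swimmer_state(), fl0, n_phases = 4,
                      refinement = 0)
  a1 <- phase_average(cfg, planar_state(th), fl0, n_phases = 4,
                      refinement = 0)
  R <- promaswim:::.rot_z(th)
  expect_rel_equal(a1$U, as.numeric(R %*% a0$U), 1e-8)
})

test_that("bulk field reproduces direct phase averages and gamma affinity", {
  cfg <- fx_config()
  bf <- fx_bulk_field()
  th <- bf$theta[4]
  for (g in c(0.5, 2)) {
    direct <- phase_average(cfg, planar_state(th),
                            flow_model(g, "bulk_shear", fx_mu),
                            n_phases = 8, refinement = 0)
    expect_rel_equal(bulk_angular_rate(bf, th, g), -direct$Omega[3], 1e-6)
    expect_rel_equal(bulk_velocity(bf, th, g), direct$U, 1e-6)
  }
})

test_that("promastigote tumbles with positive rate at unit shear", {
  bf <- fx_bulk_field()
  th <- seq(0, 2 * pi, length.out = 181)
  expect_true(all(bulk_angular_rate(bf, th, 1) > 0))
})

test_that("rotation period quadrature matches the Jeffery closed form", {
  # pure-mathematics oracle: integrate d(theta)/rate for the analytic rate
  for (r in c(1, 3)) {
    Tq <- stats::integrate(function(th) 1 / jeffery_rate(th, r, 1), 0,
                           2 * pi, rel.tol = 1e-10)$value
    expect_rel_equal(Tq, jeffery_period(r, 1), 1e-8)
  }
  expect_equal(jeffery_period(1, 2), 4 * pi / 2, tolerance = 1e-12)
  expect_equal(jeffery_period(3, 1), 2 * pi * (3 + 1 / 3),
               tolerance = 1e-12)
})

test_that("jeffery orbit solves the orbit equation with the right period", {
  r <- 5.49
  tt <- seq(0, 30, by = 0.01)
  th <- jeffery_orbit(tt, r, 1, 0.3)
  # finite-difference rate vs closed form
  mid <- (th[-1] + th[-length(th)]) / 2
  expect_rel_equal(diff(th) / 0.01, jeffery_rate(mid, r, 1), 1e-3)
  Td <- jeffery_period(r, 1)
  expect_rel_equal(jeffery_orbit(Td, r, 1, 0.3) - 0.3, 2 * pi, 1e-9)
})

test_that("the aspect-ratio fit inverts synthetic Jeffery periods", {
  gam <- c(0.2, 0.5, 1, 2)
  per <- data.frame(gamma_d = gam, T_d = jeffery_period(3, gam))
  fit <- fit_jeffery_ratio(per)
  expect_lt(abs(fit$r - 3), 1e-10)
  # the r -> 1/r symmetry resolves to the r >= 1 branch
  per2 <- data.frame(gamma_d = gam, T_d = jeffery_period(1 / 3, gam))
  expect_lt(abs(fit_jeffery_ratio(per2)$r - 3), 1e-10)
  expect_error(fit_jeffery_ratio(data.frame(gamma_d = 1, T_d = 1)),
               "minimum")
})

test_that("saddle machinery recovers an analytic saddle", {
  toy <- fx_toy_wall_field()
  s <- find_saddle(toy, 1)
  expect_true(s$found)
  expect_identical(s$type, "saddle")
  expect_equal(s$theta, 1, tolerance = 1e-3)
  expect_equal(s$h, 5, tolerance = 1e-3)
  # analytic Jacobian [[-1, 0.5], [0.3, 0.5]]
  evs <- sort(Re(eigen(matrix(c(-1, 0.3, 0.5, 0.5), 2))$values))
  expect_equal(sort(Re(s$eigenvalues)), evs, tolerance = 1e-2)
  # gamma-affine storage: doubling gamma doubles the field
  expect_rel_equal(wall_rates(toy, 2, 7, 2)[1:2],
                   2 * wall_rates(toy, 2, 7, 1)[1:2], 1e-9)
})

test_that("separatrix of the analytic saddle separates the two fates", {
  toy <- fx_toy_wall_field()
  s <- find_saddle(toy, 1)
  sep <- compute_separatrix(toy, s, 1, t_max = 60)
  expect_true(all(c("theta", "h", "branch") %in% names(sep)))
  expect_gt(nrow(sep), 10)
  # the stable manifold passes through the saddle neighbourhood
  d <- sqrt((sep$theta %% (2 * pi) - s$theta)^2 + (sep$h - s$h)^2)
  expect_lt(min(d), 0.05)
  # points displaced along the unstable directions reach opposite fates
  lo <- classify_wall_fate(toy, 1, s$theta + 0.15, s$h - 0.8,
                           t_max = 120, collision_clearance = 1.2,
                           h_escape = 11)
  hi <- classify_wall_fate(toy, 1, s$theta - 0.15, s$h + 0.8,
                           t_max = 120, collision_clearance = 1.2,
                           h_escape = 11)
  expect_identical(as.character(lo), "collision")
  expect_identical(as.character(hi), "escape")
})

test_that("swim-speed rescaling acts only on the active components", {
  bf <- fx_bulk_field()
  bf2 <- scale_swim_speed(bf, 0.1)
  expect_rel_equal(bf2$Uswim, 0.1 * bf$Uswim, 1e-12)
  expect_equal(bf2$Oshear, bf$Oshear)
  expect_equal(bf2$config$beat_frequency, bf$config$beat_frequency * 0.1)
  toy <- fx_toy_wall_field()
  toy2 <- scale_swim_speed(toy, 2)
  expect_equal(toy2$Tsh, toy$Tsh)
  # rescaled interpolant still evaluates
  expect_true(all(is.finite(wall_rates(toy2, 1.3, 6, 1))))
})
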