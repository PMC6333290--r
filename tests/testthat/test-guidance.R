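test_that("shear schedules validate and evaluate piecewise", {
  sch <- shear_schedule(c(0, 1, 3), c(1, -1, 1))
  expect_equal(schedule_rate(sch, c(0, 0.5, 1, 2.9, 3, 10)),
               c(1, 1, -1, -1, 1, 1))
  expect_error(shear_schedule(c(0, 0), c(1, 1)), "increasing")
  expect_error(shear_schedule(c(0, 1), c(1, Inf)), "finite")
})

test_that("orientation samplers are seeded, correct and Jeffery-weighted", {
  # determinism under a fixed seed
  expect_identical(sample_orientations(50, "uniform", seed = 7),
                   sample_orientations(50, "uniform", seed = 7))
  # uniform sampler: Kolmogorov distance of the empirical CDF
  u <- sample_orientations(10000, "uniform", seed = 1)
  ks <- max(abs(sort(u) / (2 * pi) - (seq_along(u) - 0.5) / length(u)))
  expect_lt(ks, 0.02)
  # a sphere rotates uniformly, so its residence density is flat
  j1 <- sample_orientations(10000, "jeffery", r = 1, seed = 2)
  ks1 <- max(abs(sort(j1) / (2 * pi) - (seq_along(j1) - 0.5) / length(j1)))
  expect_lt(ks1, 0.02)
  # elongated swimmer: residence peaks at the flow-aligned orientations
  j <- sample_orientations(20000, "jeffery", r = 5.49, seed = 3)
  near_aligned <- mean(abs(((j + pi / 2) %% pi) - pi / 2) < 0.3)
  expect_gt(near_aligned, 3 * (2 * 0.3 / pi))
})

test_that("ensembles are reproducible and quiescent swimmers go straight", {
  bf <- fx_bulk_field()
  e1 <- ensemble_endpoints(bf, 12, duration = 1, gamma_d = 1, seed = 5)
  e2 <- ensemble_endpoints(bf, 12, duration = 1, gamma_d = 1, seed = 5)
  expect_identical(e1, e2)
  # no flow, aligned swimmer: endpoint is speed x duration along x1
  speed <- sqrt(sum(bf$Uswim^2))
  e0 <- ensemble_endpoints(bf, 1, duration = 0.5, gamma_d = 0, seed = 1)
  expect_rel_equal(sqrt(e0$x1^2 + e0$x2^2), speed * 0.5, 0.01)
})

test_that("jeffery-weighted ensembles disperse mostly along the flow", {
  bf <- fx_bulk_field()
  e <- ensemble_endpoints(bf, 80, duration = 2, gamma_d = 1,
                          mode = "jeffery", seed = 11)
  expect_gt(stats::var(e$x1) / stats::var(e$x2), 1)
})

test_that("straight-line guidance schedules reverse at half periods", {
  fit <- structure(list(r = 5.49), class = "jeffery_fit")
  Td <- jeffery_period(5.49, 1)
  sch <- plan_schedule(fit, 1, duration = 3 * Td)
  expect_equal(sch$times[2], Td / 2, tolerance = 1e-12)
  expect_equal(diff(sch$times)[-1], rep(Td / 2, length(sch$times) - 2),
               tolerance = 1e-9)
  expect_equal(unique(abs(sch$rates)), 1)
  expect_true(all(diff(sign(sch$rates)) != 0))
  # reversing the target direction flips every rate
  rev <- plan_schedule(fit, 1, duration = 3 * Td, direction = -1)
  expect_equal(rev$rates, -sch$rates)
})

test_that("reduced guided paths are periodic lobes, mirrored under sign
           flip", {
  bf <- fx_bulk_field()
  Td <- rotation_period(bf, 1)
  fit <- fit_jeffery_ratio(data.frame(gamma_d = 1, T_d = Td))
  sch <- plan_schedule(fit, 1, duration = 2.2 * Td)
  path <- reduced_guided_path(bf, sch, 2 * Td, dt_out = Td / 200)
  # one full schedule period advances along x1 and returns to the start
  # orientation: displacement over [0, Td] repeats over [Td, 2 Td]
  at <- function(tq, col) stats::approx(path$t, path[[col]], tq)$y
  d1 <- c(at(Td, "x1") - at(0, "x1"), at(Td, "x2") - at(0, "x2"))
  d2 <- c(at(2 * Td, "x1") - at(Td, "x1"), at(2 * Td, "x2") - at(Td, "x2"))
  # repetition is approximate: the reversal time comes from the fitted
  # Jeffery period, which differs slightly from the field's own period
  expect_rel_equal(d2, d1, 0.15)
  # mirrored schedule gives the mirrored path about the flow axis
  schm <- shear_schedule(sch$times, -sch$rates)
  pm <- reduced_guided_path(bf, schm, 2 * Td, dt_out = Td / 200)
  scale <- max(abs(path$x2)) + max(abs(path$x1))
  expect_lt(max(abs(pm$x2 + path$x2)) / scale, 0.05)
})

test_that("the phase-averaged prediction tracks the full simulation", {
  bf <- fx_bulk_field()
  # quiescent schedule over five whole beats: both paths are straight and
  # the phase-averaged speed reproduces the stepped net displacement
  sch <- shear_schedule(0, 0)
  res <- simulate_guided(bf, sch, 5 / 28, config = fx_config(),
                         dt = 1 / (28 * 30), refinement = 0, mu = fx_mu)
  expect_lt(res$relative_discrepancy, 0.02)
  expect_gt(res$path_length, 2)
})

test_that("behavior switching relabels configurations between the mirrored
           separatrices", {
  toy <- fx_toy_wall_field()
  # under gamma = +1 the toy system sends this low-h state to collision;
  # reversing the flow in time lifts it away from the boundary
  sw <- wall_behavior_switch(toy, 1.15, 4.0, gamma_d = 1,
                             reversal_time = 0.4, t_max = 80)
  expect_identical(sw$before, "collision")
  expect_true(sw$after %in% c("escape", "undetermined"))
  expect_lt(sw$at_reversal["h"], 4.0)
  # a configuration far above every structure keeps the escape label
  hi <- wall_behavior_switch(toy, 4, 10.5, gamma_d = 1,
                             reversal_time = 0.2, t_max = 80)
  expect_identical(hi$before, "escape")
})
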