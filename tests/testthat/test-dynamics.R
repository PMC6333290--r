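test_that("background flows evaluate the stated linear shears", {
  bulk <- flow_model(2, "bulk_shear")
  expect_equal(background_velocity(bulk, c(0, 0, 0)), c(0, 0, 0))
  expect_equal(background_velocity(bulk, c(5, 3, -1)), c(6, 0, 0))
  wall <- flow_model(2, "wall_shear", wall_present = TRUE)
  expect_equal(background_velocity(wall, c(0, 7, 2)), c(0, 0, 0))
  expect_equal(background_velocity(wall, c(4, 0, 0)), c(0, -8, 0))
  # linear in the shear rate
  x <- c(1.3, -2, 0.7)
  expect_equal(background_velocity(flow_model(4, "bulk_shear"), x),
               2 * background_velocity(bulk, x))
  expect_error(flow_model(1, "wall_shear", wall_present = FALSE), "requires")
})

test_that("Heun stepping is exact for steady rigid rotation and second
           order for unsteady rates", {
  # constant angular velocity: quaternion exponential update is exact
  rf <- function(s) list(U = c(0, 0, 0), Omega = c(0, 0, 1.3))
  st <- swimmer_state()
  for (k in 1:50) st <- step_heun(st, 0.1, rates_fn = rf)
  ang <- 1.3 * 5
  expect_equal(quat_to_rot(st$quat),
               matrix(c(cos(ang), -sin(ang), 0, sin(ang), cos(ang), 0,
                        0, 0, 1), 3, 3, byrow = TRUE), tolerance = 1e-10)
  # time-dependent rotation rate: global error contracts by ~4 per halving
  rf2 <- function(s) list(U = c(0, 0, 0), Omega = c(0, 0, sin(s$t)))
  run <- function(dt) {
    st <- swimmer_state()
    for (k in seq_len(round(2 / dt))) st <- step_heun(st, dt, rates_fn = rf2)
    # exact rotation angle is integral of sin = 1 - cos(2)
    acos(max(min(quat_to_rot(st$quat)[1, 1], 1), -1)) - (1 - cos(2))
  }
  e1 <- abs(run(0.02)); e2 <- abs(run(0.01))
  expect_gt(e1 / e2, 3.3)
  expect_lt(e1 / e2, 4.7)
})

test_that("quaternion norm is preserved over ten thousand steps", {
  rf <- function(s) list(U = c(0, 0, 0),
                         Omega = c(0.3 * sin(s$t), 0.2, cos(0.7 * s$t)))
  st <- swimmer_state()
  for (k in 1:10000) st <- step_heun(st, 1e-3, rates_fn = rf)
  expect_lt(abs(sqrt(sum(st$quat^2)) - 1), 1e-10)
})

test_that("without beat or flow the swimmer is stationary", {
  cfg <- fx_config()
  cfg$beat_amplitude <- 0
  s <- solve_mobility(build_mesh(cfg, 0, 0), c(0, 0, 0),
                      flow_model(geometry = "quiescent", mu = fx_mu))
  expect_lt(max(abs(s$U)), 1e-10)
  expect_lt(max(abs(s$Omega)), 1e-10)
})

test_that("a uniform background stream adds exactly to the swim velocity", {
  cfg <- fx_config()
  m <- build_mesh(cfg, 0.4, 0)
  base <- solve_mobility(m, c(0, 0, 0),
                         flow_model(geometry = "quiescent", mu = fx_mu))
  U0 <- c(3.2, -1.1, 0.6)
  adv <- solve_mobility(m, c(0, 0, 0),
                        flow_model(geometry = "quiescent", mu = fx_mu,
                                   uniform = U0))
  expect_rel_equal(adv$U - base$U, U0, 1e-8)
  expect_lt(max(abs(adv$Omega - base$Omega)) / max(abs(base$Omega)), 1e-7)
})

test_that("planar beat in the shear plane keeps the dynamics planar", {
  cfg <- fx_config()
  fl <- flow_model(1, "bulk_shear", fx_mu)
  st <- planar_state(0.6)
  out <- 0; inp <- 0
  for (k in 1:8) {
    st <- step_heun(st, 1 / (28 * 10), cfg, fl, refinement = 0)
    U <- attr(st, "U"); Om <- attr(st, "Omega")
    out <- max(out, abs(U[3]), abs(Om[1]), abs(Om[2]))
    inp <- max(inp, abs(U[1]), abs(U[2]), abs(Om[3]))
  }
  expect_lt(out / inp, 1e-6)
  expect_lt(max(abs(st$x0[3]), abs(st$quat[2]), abs(st$quat[3])), 1e-8)
})

test_that("a wall-bound trajectory halts at the collision threshold", {
  cfg <- fx_config()
  fl <- flow_model(1, "wall_shear", fx_mu, wall_present = TRUE)
  sup <- promaswim:::.planar_support(cfg, 0)
  th0 <- 2.1               # pointing obliquely into the wall
  st <- planar_state(th0, sup(th0) + 0.12)
  tr <- simulate_swimmer(st, 0.6, cfg, fl, dt = 1 / (28 * 40),
                         refinement = 0)
  expect_identical(tr$halt_reason, "wall_collision")
  n <- nrow(tr$states)
  expect_lte(tr$states$clearance[n], 2e-3)
  expect_true(all(diff(tr$states$t) > 0))
})
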