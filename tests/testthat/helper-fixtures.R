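# shared fixtures, built once per test run and memoised
.fx <- new.env()

fx <- function(name, builder) {
  if (!exists(name, envir = .fx)) assign(name, builder(), envir = .fx)
  get(name, envir = .fx)
}

fx_config <- function() fx("config", function() swimmer_config())

fx_sphere <- function() fx("sphere", function()
  build_spheroid_mesh(1, 1, n_az = 12, n_rows = 7))

fx_mu <- 8.9e-4

# coarse bulk phase field of the promastigote (orientation sweep)
fx_bulk_field <- function() fx("bulk_field", function()
  bulk_phase_field(fx_config(), n_theta = 12, n_phases = 8, refinement = 0))

# analytic toy wall field with a saddle at (theta, h) = (1, 5), Jacobian
# [[-1, 0.5], [0.3, 0.5]] (real eigenvalues of opposite sign, and the h
# direction runs away so fates diverge):
#   thetadot = gamma * [-sin(theta - 1) + 0.5 (h - 5)]
#   hdot     = gamma * [0.3 sin(theta - 1) + 0.5 (h - 5)]
# entirely gamma-linear so the affine storage is exercised; support = 0
fx_toy_wall_field <- function() fx("toy_wall", function() {
  theta <- 2 * pi * (0:23) / 24
  h <- seq(1, 12, length.out = 14)
  Tsh <- outer(theta, h, function(th, hh) -sin(th - 1) + 0.5 * (hh - 5))
  Hsh <- outer(theta, h, function(th, hh) 0.3 * sin(th - 1) +
                 0.5 * (hh - 5))
  zero <- matrix(0, length(theta), length(h))
  f <- structure(list(theta = theta, h = h, T0 = zero, Tsh = Tsh,
                      H0 = zero, Hsh = Hsh, Y0 = zero, Ysh = zero,
                      valid = matrix(TRUE, length(theta), length(h)),
                      support = function(th) rep(0, length(th)),
                      n_phases = 1, refinement = 0,
                      config = swimmer_config()),
                 class = "wall_phase_field")
  f$interp <- promaswim:::.wall_interp(f)
  f
})

expect_rel_equal <- function(object, expected, tol) {
  expect_lt(max(abs(object - expected)) / max(abs(expected)), tol)
}
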