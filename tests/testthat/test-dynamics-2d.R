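test_that("2D velocity symmetry nulls are exact and oracles agree", {
  # flat field, centred bead: both components exactly zero
  f <- make_field_2d(matrix(1, 101, 101), L = 10)
  v <- bead_velocity_2d(f, 5, 5, 1)
  expect_identical(unname(v), c(0, 0))

  # field mirror-symmetric about the bead's x-line: v_y exactly zero
  set.seed(13)
  prof <- runif(101, 0.5, 1)
  f2 <- make_field_2d(matrix(prof, 101, 101), L = 10)  # constant along y
  v2 <- bead_velocity_2d(f2, 5, 5, 1)
  expect_identical(unname(v2[2]), 0)

  # naive double-loop Simpson oracle, off-node bead
  f3 <- make_field_2d(matrix(runif(61^2, 0.2, 1), 61, 61), L = 6)
  got <- bead_velocity_2d(f3, 2.31, 3.77, 1.4)
  want <- naive_velocity_2d(f3, 2.31, 3.77, 1.4)
  expect_equal(unname(got), want, tolerance = 1e-12)

  # half-plane: forward pull only
  f4 <- make_field_2d(matrix(0, 101, 101), L = 10)
  f4$values[f4$x > 5, ] <- 1
  v4 <- bead_velocity_2d(f4, 5, 5, 1)
  expect_gt(v4[1], 0)
  expect_identical(unname(v4[2]), 0)
})

test_that("2D force on a y-constant field matches the closed-form y-integral", {
  # inner integral over y of exp(-rho^2/2)/(1+rho^2) is (pi/s) e^(s^2/2) erfc(s/sqrt(2))
  f <- init_para_field_2d(1, 0, 24, 0.05, 1)
  prof <- 1 / (1 + exp(-(f$x - 12)))
  f$values <- matrix(prof, f$n, f$n)
  v <- bead_velocity_2d(f, 12, 12, 1)
  inner <- function(ux) {
    s <- sqrt(1 + ux^2)
    (pi / s) * exp(s^2 / 2) * pracma::erfc(s / sqrt(2))
  }
  want <- integrate(function(u) exp(-u^2 / 2) * u / (1 + exp(-u)) * inner(u),
                    -10, 10, rel.tol = 1e-10)$value
  expect_equal(unname(v[1]), want, tolerance = 1e-6)
  expect_identical(unname(v[2]), 0)
})

test_that("2D removal step agrees with the compiled loop and depletes radially", {
  f <- init_para_field_2d(1, 0.05, 6, 0.1, seed = 17)
  params <- dimensionless_params(A0 = 1, c = 0.5, L = 6)
  nm <- numerics_config(dx = f$dx, dtau = 0.01, tau_max = 0.01)
  x0 <- f$x[parabead:::center_index(f$n)]
  stepped <- step_2d(f, bead_state(x0, y_p = x0), params, nm)
  res <- parabead:::cpp_simulate_2d(f$values, f$dx, x0, x0, 1, 0.5, 0.01, 1L, 0L,
                                    matrix(0, 1, 1), 0, 0, 0, integer(0))
  expect_equal(res$a_final, stepped$field$values, tolerance = 1e-15)
  expect_true(all(stepped$field$values <= f$values))
})

test_that("2D simulation: exact zero-noise null, directed motion and wake", {
  # symmetric start never moves
  tr0 <- simulate_2d(default_config(dims = 2), L = 6, dx = 0.1, delta_a = 0,
                     tau_max = 3)
  expect_identical(max(abs(tr0$x_p - tr0$x_start)), 0)
  expect_identical(max(abs(tr0$y_p - tr0$y_start)), 0)

  # noisy start: symmetry breaks, bead carves a depleted wake
  tr <- simulate_2d(default_config(dims = 2), L = 12, dx = 0.1, tau_max = 15,
                    snapshot_tau = c(1.5, 15), seed = 2)
  n <- length(tr$tau)
  disp <- sqrt((tr$x_p[n] - tr$x_start)^2 + (tr$y_p[n] - tr$y_start)^2)
  expect_gt(disp, 1)
  expect_length(tr$snapshots, 2)
  # after 150 steps the removal dimple is already visible at the start point
  snap1 <- tr$snapshots[[1]]
  i0 <- parabead:::center_index(tr$field$n)
  expect_lt(snap1[i0, i0], 0.35)
  # the late field is depleted along the path near the start
  expect_lt(min(tr$field$values), 0.02)
})

test_that("2D rebinding keeps the bead moving and turning inside the box", {
  cfg <- default_config(mode = "rebinding", dims = 2, L = 10, dx = 0.1,
                        tau_max = 45, phi = 0.95, k_r = 1.75)
  tr <- simulate_2d(cfg, seed = 3)
  n <- length(tr$tau)
  expect_true(all(tr$x_p >= 0 & tr$x_p <= 10 & tr$y_p >= 0 & tr$y_p <= 10))
  spd <- sqrt(tr$v_x^2 + tr$v_y^2)
  # once moving, the bead never halts (speeds stay well above stall scale)
  moving <- tr$tau > 20
  expect_gt(min(spd[moving]), 0.05)
  # direction changes: the heading spans a wide arc over the run
  heading <- atan2(tr$v_y[moving], tr$v_x[moving])
  expect_gt(diff(range(heading)), 1)
  # mass conservation with the area-normalized buffer
  mass_end <- trapz_mass(tr$field) + 100 * tail(tr$a_b, 1)
  expect_equal(mass_end, 100 * 0.95, tolerance = 1e-6)
})
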