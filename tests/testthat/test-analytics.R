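test_that("co-moving front has the closed-form limits and monotone shape", {
  tw <- comoving_profile_1d(1.0, 0.5, seq(-30, 30, by = 0.01))
  expect_equal(tail(tw$profile, 1), 1, tolerance = 1e-8)
  expect_equal(tw$profile[1], exp(-0.5 * sqrt(2 * pi)), tolerance = 1e-8)
  expect_equal(tw$wake_floor, 0.2855, tolerance = 1e-3)
  expect_true(all(diff(tw$profile) >= 0))
  # strictly increasing wherever the removal tail is above double precision
  mid <- tw$xi > -3.5 & tw$xi < 3
  expect_true(all(diff(tw$profile[mid]) > 0))
  expect_error(comoving_profile_1d(0, 0.5), "v <= 0")

  # independent check: integrate the co-moving ODE numerically (deSolve)
  rhs <- function(xi, a, p) list(exp(-xi^2 / (2 * p$c^2)) / p$v * a)
  sol <- deSolve::ode(y = c(a = 1), times = seq(10, -10, by = -0.1),
                      func = rhs, parms = list(v = 1, c = 0.5),
                      rtol = 1e-10, atol = 1e-12)
  ode_a <- rev(sol[, "a"])
  closed <- comoving_profile_1d(1, 0.5, seq(-10, 10, by = 0.1))$profile
  expect_equal(closed, unname(ode_a), tolerance = 1e-6)
})

test_that("self-consistent 1D speed behaves physically across c and A0", {
  sol <- self_consistent_speed_1d(1, 0.5)
  expect_true(sol$converged)
  expect_gt(sol$v_star, 0)
  expect_lt(abs(sol$residual), 1e-8)

  # c -> 0: nothing is removed, the gradient contrast and the speed die off
  vs_small <- sapply(c(1e-4, 0.01, 0.1), function(c)
    self_consistent_speed_1d(1, c)$v_star)
  expect_true(all(diff(vs_small) > 0))
  expect_lt(vs_small[1], 0.02)
  # far enough down, the force cannot sustain the drag: stalled branch
  stalled <- self_consistent_speed_1d(1, 1e-8)
  expect_identical(stalled$v_star, 0)
  expect_true(stalled$converged)

  # interior speed maximum in c
  opt <- find_optimal_c(1, dims = 1)
  expect_gt(opt$v_max, self_consistent_speed_1d(1, 0.1)$v_star)
  expect_gt(opt$v_max, self_consistent_speed_1d(1, 0.9)$v_star)
  expect_equal(self_consistent_speed_1d(1, opt$c_max)$v_star, opt$v_max,
               tolerance = 1e-6)
  # the optimum moves with A0, and curves are ordered by A0
  opt5 <- find_optimal_c(0.5, dims = 1)
  expect_gt(abs(opt$c_max - opt5$c_max), 0.01)
  expect_gt(opt$v_max, opt5$v_max)

  # monotone in A0 at fixed c
  vs <- sapply(c(0.25, 0.5, 1, 1.5), function(a) self_consistent_speed_1d(a, 0.5)$v_star)
  expect_true(all(diff(vs) > 0))
})

test_that("2D front reduces to 1D on axis and the transverse force vanishes", {
  p2 <- comoving_profile_2d(1, 0.5, seq(-8, 8, by = 0.05), seq(-8, 8, by = 0.05))
  # far off-axis the surface is untouched
  expect_equal(unname(p2$profile[, 1]), rep(1, length(p2$x)), tolerance = 1e-8)
  # the y = 0 slice is the 1D front
  j0 <- which(p2$y == 0)
  p1 <- comoving_profile_1d(1, 0.5, p2$x)
  expect_equal(unname(p2$profile[, j0]), p1$profile, tolerance = 1e-12)

  sol2 <- self_consistent_speed_2d(1, 0.5)
  expect_true(sol2$converged)
  expect_lt(abs(sol2$f_y), 1e-10)
  expect_lt(abs(sol2$residual), 1e-8)
})

test_that("1D and 2D speeds cross near the wake-width argument", {
  v1_02 <- self_consistent_speed_1d(1, 0.2)$v_star
  v2_02 <- self_consistent_speed_2d(1, 0.2)$v_star
  v1_05 <- self_consistent_speed_1d(1, 0.5)$v_star
  v2_05 <- self_consistent_speed_2d(1, 0.5)$v_star
  expect_gt(v1_02, v2_02)   # thin wake: 1D faster
  expect_gt(v2_05, v1_05)   # wide wake: 2D faster

  cc <- find_crossover_c(1)
  expect_gt(cc, 0.2)
  expect_lt(cc, 0.5)
  # the sign of the difference flips across the root
  dv <- function(c) self_consistent_speed_1d(1, c)$v_star -
    self_consistent_speed_2d(1, c)$v_star
  expect_gt(dv(cc - 0.05), 0)
  expect_lt(dv(cc + 0.05), 0)
})

test_that("speed_curve tabulates both dimensions", {
  sc <- speed_curve(1, c(0.3, 0.5), dims = c(1, 2))
  expect_named(sc, c("c", "v1d", "v2d"))
  expect_equal(sc$v1d[2], self_consistent_speed_1d(1, 0.5)$v_star,
               tolerance = 1e-8)
})
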