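test_that("removal kernel has the right peak, width and validation", {
  f <- make_field(rep(1, 1001), L = 10)
  r <- removal_rate(f, 5, c = 0.5)
  expect_equal(r[f$x == 5], 1.0)
  # Gaussian half-maximum at |x - x_p| = c*sqrt(2 log 2)
  half <- approx(f$x, r, xout = 5 + 0.5 * sqrt(2 * log(2)))$y
  expect_equal(half, 0.5, tolerance = 1e-4)
  expect_equal(removal_rate(f, 5, 0.5), naive_removal_1d(f, 5, 0.5),
               tolerance = 1e-14)
  expect_error(removal_rate(f, 5, c = 0), "positive")
  expect_error(removal_rate(f, 11, c = 0.5), "outside")
})

test_that("force quadrature matches closed forms and brute-force loops", {
  # flat field, centred bead: odd integrand, exactly zero
  f <- make_field(rep(1, 501), L = 10)
  expect_identical(bead_speed(f, f$x[251], 1), 0)

  # half-plane field: v = (e^(1/2)/2) * E1(1/2)
  fh <- init_para_field(1, 0, 40, 0.01, 1)
  fh$values[fh$x < 20] <- 0
  expect_equal(bead_speed(fh, 20, 1), exp(0.5) / 2 * pracma::expint_E1(0.5),
               tolerance = 1e-4)

  # point mass at x_p + 1: single-node kernel evaluation
  fp <- make_field(rep(0, 501), L = 10)
  j <- 301  # x = 6, bead at 5
  fp$values[j] <- 1 / fp$dx
  w <- simpson_w_oracle(fp$n, fp$dx)
  u <- fp$x[j] - 5
  expect_equal(bead_speed(fp, 5, 2),
               2 * w[j] * exp(-u^2 / 2) * u / (1 + u^2) / fp$dx,
               tolerance = 1e-13)

  # arbitrary noisy field, off-node bead: naive-loop Simpson oracle
  set.seed(8)
  fr <- make_field(runif(51, 0.2, 1), L = 5)
  for (xp in c(2.5, 1.234, 4.87)) {
    expect_equal(bead_speed(fr, xp, 1.3), naive_speed_1d(fr, xp, 1.3),
                 tolerance = 1e-13)
  }
})

test_that("base Euler step depletes monotonically and converges first order", {
  set.seed(2)
  f <- make_field(1 + 0.3 * sin(2 * pi * seq(0, 1, length.out = 201)), L = 10)
  params <- dimensionless_params(A0 = 1, c = 0.5, L = 10)
  nm <- numerics_config(dx = f$dx, dtau = 0.01, tau_max = 1)
  st <- list(field = f, bead = bead_state(4.4))
  for (k in 1:50) {
    st2 <- step_base(st$field, st$bead, params, nm)
    expect_true(all(st2$field$values <= st$field$values))
    st <- st2
  }
  expect_true(all(st$field$values >= 0))

  # halving dtau halves the global Euler error (first-order convergence)
  run <- function(dtau, nsteps) {
    nm <- numerics_config(dx = f$dx, dtau = dtau, tau_max = 1)
    st <- list(field = f, bead = bead_state(4.4))
    for (k in seq_len(nsteps)) st <- step_base(st$field, st$bead, params, nm)
    st$bead$x_p
  }
  x1 <- run(0.04, 50)
  x2 <- run(0.02, 100)
  x3 <- run(0.01, 200)
  ratio <- abs(x1 - x2) / abs(x2 - x3)
  expect_gt(ratio, 1.5)
  expect_lt(ratio, 3)
})

test_that("static-bead decay follows exp(-tau) and the R step matches the C++ loop", {
  # zero noise: bead never moves, the centre node sees the full removal rate
  tr <- simulate_1d(default_config(), L = 20, delta_a = 0, tau_max = 1,
                    seed = 1)
  centre <- tr$field$values[which.min(abs(tr$field$x - tr$x_start))]
  # first-order Euler bias at dtau = 0.01 is ~dtau/2 relative
  expect_equal(centre, exp(-1), tolerance = 7e-3)
  tr2 <- simulate_1d(default_config(), L = 20, delta_a = 0, tau_max = 1,
                     dtau = 0.001, seed = 1)
  centre2 <- tr2$field$values[which.min(abs(tr2$field$x - tr2$x_start))]
  expect_lt(abs(centre2 - exp(-1)), abs(centre - exp(-1)) / 5)

  # a single R-level step equals the first step of the compiled loop
  f <- init_para_field(1, 0.1, 10, 0.05, seed = 6)
  params <- dimensionless_params(A0 = 1, c = 0.5, L = 10)
  nm <- numerics_config(dx = f$dx, dtau = 0.01, tau_max = 0.01)
  x0 <- f$x[parabead:::center_index(f$n)]
  stepped <- step_base(f, bead_state(x0), params, nm)
  res <- parabead:::cpp_simulate_1d(f$values, f$dx, x0, 1, 0.5, 0.01, 1L, 0L,
                                    numeric(0), 0, 0, 0, 0, integer(0), 0)
  expect_equal(res$a_final, stepped$field$values, tolerance = 1e-15)
  expect_equal(res$x_p[2], stepped$bead$x_p, tolerance = 1e-15)
})

test_that("zero-noise symmetry null holds exactly over long runs", {
  tr <- simulate_1d(default_config(), L = 20, delta_a = 0, tau_max = 20,
                    seed = 1)
  expect_identical(max(abs(tr$x_p - tr$x_start)), 0)
  expect_identical(max(abs(tr$v)), 0)
})

test_that("noisy base runs lag, then move at constant speed", {
  tr <- simulate_1d(default_config(), L = 40, tau_max = 120, stop_margin = 3,
                    seed = 21)
  fs <- fit_speed(tr)
  expect_false(fs$stalled)
  expect_gt(fs$lag_time, 0)
  expect_gt(fs$speed, 0.1)
  expect_gt(fs$r_squared, 0.999)
  # depletion: the field is nowhere above its initial bound
  expect_lte(max(tr$field$values), 1.05)
  # a wake exists behind the travelled path
  expect_lt(min(tr$field$values), 0.05)
})
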