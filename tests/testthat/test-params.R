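test_that("dedimensionalization reduces to A0 and c and round-trips", {
  # identity case: all scales 1
  phys <- physical_params(gamma0 = 1, F0 = 1, R = 1, sigma_r = 0.25,
                          sigma_f = 1, a0 = 1, beta = 1)
  dp <- dedimensionalize(phys)
  expect_equal(dp$A0, 1.0)
  expect_equal(dp$c, 0.25)

  # Stokes drag from viscosity
  phys2 <- physical_params(gamma0 = 2, F0 = 3, R = 1, sigma_r = 0.3,
                           sigma_f = 0.9, a0 = 0.5, eta = 1)
  expect_equal(phys2$beta, 6 * pi)

  # measured ranges give c = 0.25, inside the quoted 0.2-0.4 window
  phys3 <- physical_params(gamma0 = 1, F0 = 1, R = 0.5, sigma_r = 0.225,
                           sigma_f = 0.9, a0 = 1, eta = 0.001)
  dp3 <- dedimensionalize(phys3)
  expect_equal(dp3$c, 0.25)
  expect_gt(dp3$c, 0.2)
  expect_lt(dp3$c, 0.4)

  # round-trip recovers the dimensionful inputs to machine precision
  set.seed(42)
  for (i in 1:10) {
    v <- exp(runif(6, -1, 1))
    ph <- physical_params(gamma0 = v[1], F0 = v[2], R = v[3],
                          sigma_r = 0.2 * v[4], sigma_f = v[4], a0 = v[5],
                          eta = v[6])
    back <- redimensionalize(dedimensionalize(ph), gamma0 = ph$gamma0,
                             R = ph$R, a0 = ph$a0, sigma_f = ph$sigma_f,
                             eta = ph$eta)
    expect_equal(back$F0, ph$F0, tolerance = 1e-12)
    expect_equal(back$sigma_r, ph$sigma_r, tolerance = 1e-12)
  }

  expect_error(physical_params(gamma0 = -1, F0 = 1, R = 1, sigma_r = 1,
                               sigma_f = 1, a0 = 1, beta = 1), "positive")
  expect_warning(dimensionless_params(c = 1.4), "unphysical")
  expect_error(dimensionless_params(A0 = 0), "A0")
})

test_that("force-range estimate reproduces the in vitro worked example", {
  est <- estimate_force_range(4800, 5, 400, sigma_r = 0.225)
  expect_equal(est$required_parA_raw, 960)
  expect_equal(est$required_parA, 1000)
  expect_equal(est$area_um2, 2.5)
  expect_equal(est$sigma_f_um, sqrt(2.5 / pi), tolerance = 1e-12)
  expect_equal(est$sigma_f_um, 0.9, tolerance = 0.02)
  expect_error(estimate_force_range(surface_density = 0), "density")
})

test_that("noisy field initialization is bounded, seeded and grid-true", {
  # zero noise: exactly flat
  f0 <- init_para_field(1, 0, 10, 0.1, seed = 1)
  expect_true(all(f0$values == 1))

  # reference grid: L = 70, dx = 0.02 has 3501 nodes including both ends
  f <- init_para_field(1, 0.1, 70, 0.02, seed = 7)
  expect_identical(f$n, 3501L)
  expect_identical(length(f$values), 3501L)
  expect_equal(f$x[1], 0)
  expect_equal(f$x[f$n], 70)

  # uniform-noise bounds always hold; mean approaches the target
  for (seed in 1:5) {
    g <- init_para_field(2, 0.5, 20, 0.05, seed = seed)
    expect_gte(min(g$values), 1.5)
    expect_lte(max(g$values), 2.5)
  }
  expect_equal(mean(f$values), 1, tolerance = 0.005)

  # reproducibility contract
  expect_identical(init_para_field(1, 0.1, 10, 0.1, seed = 3)$values,
                   init_para_field(1, 0.1, 10, 0.1, seed = 3)$values)
  expect_false(identical(init_para_field(1, 0.1, 10, 0.1, seed = 3)$values,
                         init_para_field(1, 0.1, 10, 0.1, seed = 4)$values))

  # field construction must not disturb the caller's RNG stream
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(init_para_field(1, 0.1, 10, 0.1, seed = 3))
  expect_identical(runif(1), before)

  expect_error(init_para_field(1, 1.5, 10, 0.1), "negative")
})

test_that("binding sites, buffer and rate parameters validate their domains", {
  s <- init_binding_sites(1, 0.05, 20, 0.1, seed = 2)
  expect_gte(min(s$values), 0.95)
  expect_lte(max(s$values), 1.05)
  expect_identical(init_binding_sites(1, 0.05, 20, 0.1, 5)$values,
                   init_binding_sites(1, 0.05, 20, 0.1, 5)$values)
  expect_true(all(init_binding_sites(1, 0, 20, 0.1)$values == 1))
  expect_error(init_binding_sites(1, 2, 20, 0.1), "negative")

  b <- buffer_state(1.1, 1)
  expect_equal(b$phi, 1.1)
  expect_error(buffer_state(-0.1), "non-negative")
  expect_error(rebinding_params(-1, 0), "non-negative")
  expect_error(diffusion_params(-0.5), "non-negative")

  f2 <- init_para_field_2d(1, 0.05, 5, 0.1, seed = 1)
  expect_identical(dim(f2$values), c(51L, 51L))
  expect_gte(min(f2$values), 0.95)
  expect_lte(max(f2$values), 1.05)
})
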