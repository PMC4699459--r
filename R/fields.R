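#' Seeded noisy initial ParA field (1D)
#'
#' Draws the surface ParA concentration at every grid node independently and
#' uniformly from [mean - delta_a, mean + delta_a]. This initial spatial
#' noise is the only stochastic element of the model; it is what breaks the
#' left-right symmetry around the bead and lets a gradient form.
#'
#' @param mean mean initial concentration (dimensionless).
#' @param delta_a uniform-noise half-width, 0 <= delta_a <= mean.
#' @param L domain length (bead radii); `dx` grid spacing.
#' @param dx grid spacing.
#' @param seed integer PRNG seed; the same seed reproduces the field exactly.
#' @return A `para_field` object: list with `x` (nodes), `values`, `dx`, `L`.
#' @export
init_para_field <- function(mean = 1, delta_a = 0.05, L = 70, dx = 0.02,
                            seed = 1) {
  if (delta_a < 0) stop("delta_a must be non-negative")
  if (delta_a > mean) stop("delta_a > mean would allow negative concentrations")
  g <- para_grid(L, dx)
  values <- if (delta_a == 0) {
    rep(mean, g$n)
  } else {
    with_seed(seed, runif(g$n, mean - delta_a, mean + delta_a))
  }
  structure(list(x = g$x, values = values, dx = g$dx, L = g$L, n = g$n,
                 mean = mean, delta_a = delta_a, seed = seed),
            class = "para_field")
}

#' Seeded noisy binding-site field (1D)
#'
#' Concentration d(x) of DNA binding sites for ParA, uniform noise of
#' half-width `delta_d` about the mean `D0`. Used by the rebinding and
#' surface-diffusion variants, where d(x) caps the bound ParA and its
#' spatial noise seeds the symmetry breaking.
#'
#' @param D0 mean site concentration; `delta_d` noise half-width,
#'   0 <= delta_d <= D0.
#' @param delta_d uniform-noise half-width.
#' @inheritParams init_para_field
#' @return A `binding_sites` object with the same grid layout as
#'   [init_para_field()].
#' @export
init_binding_sites <- function(D0 = 1, delta_d = 0.05, L = 70, dx = 0.02,
                               seed = 1) {
  if (delta_d < 0) stop("delta_d must be non-negative")
  if (delta_d > D0) stop("delta_d > D0 would allow negative site concentrations")
  g <- para_grid(L, dx)
  values <- if (delta_d == 0) {
    rep(D0, g$n)
  } else {
    with_seed(seed, runif(g$n, D0 - delta_d, D0 + delta_d))
  }
  structure(list(x = g$x, values = values, dx = g$dx, L = g$L, n = g$n,
                 D0 = D0, delta_d = delta_d, seed = seed),
            class = c("binding_sites", "para_field"))
}

#' Noisy initial ParA field on a square 2D grid
#'
#' @inheritParams init_para_field
#' @return A `para_field_2d` object: `x`, `y` node vectors and a `values`
#'   matrix (rows index x, columns index y).
#' @export
init_para_field_2d <- function(mean = 1, delta_a = 0.05, L = 20, dx = 0.05,
                               seed = 1) {
  if (delta_a < 0) stop("delta_a must be non-negative")
  if (delta_a > mean) stop("delta_a > mean would allow negative concentrations")
  g <- para_grid(L, dx)
  values <- if (delta_a == 0) {
    matrix(mean, g$n, g$n)
  } else {
    with_seed(seed, matrix(runif(g$n^2, mean - delta_a, mean + delta_a), g$n, g$n))
  }
  structure(list(x = g$x, y = g$x, values = values, dx = g$dx, L = g$L,
                 n = g$n, mean = mean, delta_a = delta_a, seed = seed),
            class = "para_field_2d")
}

#' Noisy binding-site field on a square 2D grid
#'
#' @inheritParams init_binding_sites
#' @inheritParams init_para_field_2d
#' @return A `binding_sites_2d` object.
#' @export
init_binding_sites_2d <- function(D0 = 1, delta_d = 0.05, L = 20, dx = 0.05,
                                  seed = 1) {
  if (delta_d < 0) stop("delta_d must be non-negative")
  if (delta_d > D0) stop("delta_d > D0 would allow negative site concentrations")
  g <- para_grid(L, dx)
  values <- if (delta_d == 0) {
    matrix(D0, g$n, g$n)
  } else {
    with_seed(seed, matrix(runif(g$n^2, D0 - delta_d, D0 + delta_d), g$n, g$n))
  }
  structure(list(x = g$x, y = g$x, values = values, dx = g$dx, L = g$L,
                 n = g$n, D0 = D0, delta_d = delta_d, seed = seed),
            class = c("binding_sites_2d", "para_field_2d"))
}

#' Well-mixed buffer state for the rebinding model
#'
#' Free ParA in the buffer is spatially uniform (diffusion in solution is
#' fast compared to surface kinetics). The saturation ratio phi = A_s/D0
#' splits the dynamics into an undersaturated (phi < 1, persistent
#' acceleration possible) and a saturated (phi > 1, constant speed or stall)
#' regime.
#'
#' @param A_s initial buffer ParA concentration a_b(0).
#' @param D0 mean binding-site concentration, used for phi = A_s/D0.
#' @return A `buffer_state` object with fields `a_b`, `A_s`, `phi`.
#' @export
buffer_state <- function(A_s, D0 = 1) {
  if (A_s < 0) stop("buffer ParA must be non-negative")
  if (D0 <= 0) stop("D0 must be positive")
  structure(list(a_b = A_s, A_s = A_s, phi = A_s / D0, D0 = D0),
            class = "buffer_state")
}

#' Rebinding rate parameters
#'
#' @param k_r non-cooperative rebinding rate (per unit buffer ParA per free
#'   site); `k_c` cooperative rate, weighting rebinding by the local bound
#'   ParA concentration.
#' @param k_c cooperative rebinding rate.
#' @return A `rebinding_params` object.
#' @export
rebinding_params <- function(k_r = 0.25, k_c = 0) {
  if (k_r < 0 || k_c < 0) stop("rebinding rates must be non-negative")
  structure(list(k_r = k_r, k_c = k_c), class = "rebinding_params")
}

#' Surface-diffusion parameter
#'
#' @param kappa dimensionless ParA surface diffusion coefficient, >= 0.
#' @return A `diffusion_params` object.
#' @export
diffusion_params <- function(kappa = 0.1) {
  if (kappa < 0) stop("kappa must be non-negative")
  structure(list(kappa = kappa), class = "diffusion_params")
}

#' Bead state
#'
#' @param x_p bead position (bead radii); `y_p` second coordinate in 2D.
#' @param v instantaneous speed.
#' @param y_p optional y position (2D).
#' @return A `bead_state` object.
#' @export
bead_state <- function(x_p, v = 0, y_p = NULL) {
  structure(list(x_p = x_p, y_p = y_p, v = v), class = "bead_state")
}

#' @export
print.para_field <- function(x, ...) {
  cat(sprintf("ParA field: %d nodes on [0, %g], dx = %g\n", x$n, x$L, x$dx))
  cat(sprintf("  values in [%.4g, %.4g], mean %.4g\n",
              min(x$values), max(x$values), mean(x$values)))
  invisible(x)
}

#' @export
print.para_field_2d <- function(x, ...) {
  cat(sprintf("2D ParA field: %d x %d nodes on [0, %g]^2, dx = %g\n",
              x$n, x$n, x$L, x$dx))
  cat(sprintf("  values in [%.4g, %.4g], mean %.4g\n",
              min(x$values), max(x$values), mean(x$values)))
  invisible(x)
}

# integral of a field over the domain by Simpson's rule
field_mass <- function(field) {
  w <- simpson_weights(field$n, field$dx)
  if (is.matrix(field$values)) {
    as.numeric(t(w) %*% field$values %*% w)
  } else {
    sum(w * field$values)
  }
}
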