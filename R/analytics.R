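# Traveling-wave steady-state theory: in the frame xi = x - v*tau co-moving
# with a bead at constant speed v, the removal equation integrates to a
# closed-form ParA front; balancing the force integral over that front
# against the drag gives a one-variable equation for the self-consistent
# speed v*.

# integral_xi^inf exp(-s^2/(2 c^2)) ds, by the complementary normal CDF
gauss_tail <- function(xi, c) {
  c * sqrt(2 * pi) * pnorm(xi / c, lower.tail = FALSE)
}

#' Co-moving steady-state ParA profile (1D)
#'
#' For a bead moving at constant speed v > 0, the removal dynamics in the
#' co-moving coordinate xi = x - v*tau reduce to -v a' = -exp(-xi^2/(2c^2)) a
#' with a(+inf) = 1, giving
#' a(xi) = exp(-(1/v) * integral_xi^inf exp(-s^2/(2 c^2)) ds).
#' The profile is a monotone front: fully recovered ParA far ahead of the
#' bead, a depleted wake floor exp(-c*sqrt(2*pi)/v) far behind.
#'
#' @param v assumed constant bead speed, > 0.
#' @param c removal-to-force range ratio, > 0.
#' @param xi_grid co-moving coordinates at which to evaluate the profile.
#' @return A `traveling_wave` object: list with `xi`, `profile`, `v`, `c`,
#'   and the closed-form `wake_floor`.
#' @export
comoving_profile_1d <- function(v, c, xi_grid = seq(-10, 10, by = 0.01)) {
  if (v <= 0) stop("no traveling frame for v <= 0")
  if (c <= 0) stop("c must be positive")
  profile <- exp(-gauss_tail(xi_grid, c) / v)
  structure(list(xi = xi_grid, profile = profile, v = v, c = c,
                 wake_floor = exp(-c * sqrt(2 * pi) / v)),
            class = "traveling_wave")
}

# net force functional on the 1D traveling front (adaptive quadrature on the
# kernel support)
force_on_front_1d <- function(v, c, A0, reach = 10) {
  f <- function(xi) {
    exp(-0.5 * xi^2) * xi / (1 + xi^2) * exp(-gauss_tail(xi, c) / v)
  }
  A0 * integrate(f, -reach, reach, rel.tol = 1e-10, abs.tol = 1e-12,
                 subdivisions = 500L)$value
}

#' Self-consistent steady-state speed (1D)
#'
#' Solves v = A0 * integral exp(-xi^2/2) xi/(1+xi^2) a(xi; v, c) dxi for the
#' positive root by bracketing and Brent's method. v = 0 always solves the
#' balance trivially; when the force at the lower bracket cannot sustain the
#' drag, the stalled branch v* = 0 is reported (converged, not an error).
#'
#' @param A0 dimensionless force scale, > 0.
#' @param c removal-to-force range ratio, > 0.
#' @param bracket search interval for the positive root.
#' @param tol root tolerance.
#' @return A `speed_solution`: list with `v_star`, `A0`, `c`, `dims`,
#'   `converged`, `residual`.
#' @export
self_consistent_speed_1d <- function(A0, c, bracket = c(1e-3, 10),
                                     tol = 1e-10) {
  stopifnot(A0 > 0, c > 0)
  g <- function(v) force_on_front_1d(v, c, A0) - v
  g_lo <- g(bracket[1])
  if (g_lo <= 0) {
    return(structure(list(v_star = 0, A0 = A0, c = c, dims = 1L,
                          converged = TRUE, residual = 0),
                     class = "speed_solution"))
  }
  g_hi <- g(bracket[2])
  if (g_hi >= 0) {
    stop("force exceeds drag at the upper bracket: no balanced speed below ",
         bracket[2])
  }
  root <- uniroot(g, bracket, tol = tol)
  structure(list(v_star = root$root, A0 = A0, c = c, dims = 1L,
                 converged = TRUE, residual = root$f.root),
            class = "speed_solution")
}

#' Co-moving steady-state ParA profile (2D)
#'
#' For a bead moving along x at constant speed v, each lateral line y = const
#' integrates independently: the removal history along the bead's straight
#' passage gives
#' a(x, y) = exp(-(1/v) * exp(-y^2/(2c^2)) * integral_x^inf exp(-u^2/(2c^2)) du).
#' The y = 0 slice is the 1D front; far off-axis the surface is untouched.
#'
#' @inheritParams comoving_profile_1d
#' @param x_grid,y_grid coordinates (bead at the origin, motion along +x).
#' @return List with `x`, `y` and the profile matrix (rows index x).
#' @export
comoving_profile_2d <- function(v, c, x_grid = seq(-10, 10, by = 0.05),
                                y_grid = seq(-10, 10, by = 0.05)) {
  if (v <= 0) stop("no traveling frame for v <= 0")
  if (c <= 0) stop("c must be positive")
  ix <- gauss_tail(x_grid, c)
  ey <- exp(-y_grid^2 / (2 * c^2))
  profile <- exp(-outer(ix, ey) / v)
  list(x = x_grid, y = y_grid, profile = profile, v = v, c = c)
}

# Simpson-grid force functional on the 2D front. Returns a function of v
# (the expensive c-dependent factors are precomputed once per c).
make_force_2d <- function(c, A0, reach = 12, h = 0.04) {
  g <- seq(-reach, reach, by = h)
  if (length(g) %% 2 == 0) g <- seq(-reach, reach, length.out = length(g) + 1)
  w <- simpson_weights(length(g), g[2] - g[1])
  ix <- gauss_tail(g, c)
  ey <- exp(-g^2 / (2 * c^2))
  E <- outer(ix, ey)                      # removal history exponent * v
  rho2 <- outer(g^2, g^2, `+`)
  Kx <- exp(-rho2 / 2) * (g / (1 + rho2)) # x-odd force kernel (rows = x)
  W <- outer(w, w)
  WKx <- W * Kx
  WKy <- W * t(Kx)                        # y-odd kernel for the f_y check
  list(
    fx = function(v) A0 * sum(WKx * exp(-E / v)),
    fy = function(v) A0 * sum(WKy * exp(-E / v))
  )
}

#' Self-consistent steady-state speed (2D)
#'
#' As [self_consistent_speed_1d()] with the 2D co-moving profile and vector
#' force kernel; the transverse force component vanishes by symmetry (and is
#' returned as a diagnostic).
#'
#' @inheritParams self_consistent_speed_1d
#' @param h Simpson grid spacing for the 2D force quadrature.
#' @return A `speed_solution` with an extra `f_y` residual field.
#' @export
self_consistent_speed_2d <- function(A0, c, bracket = c(1e-3, 10),
                                     tol = 1e-10, h = 0.04) {
  stopifnot(A0 > 0, c > 0)
  ff <- make_force_2d(c, A0, h = h)
  g <- function(v) ff$fx(v) - v
  g_lo <- g(bracket[1])
  if (g_lo <= 0) {
    return(structure(list(v_star = 0, A0 = A0, c = c, dims = 2L,
                          converged = TRUE, residual = 0, f_y = 0),
                     class = "speed_solution"))
  }
  if (g(bracket[2]) >= 0) {
    stop("force exceeds drag at the upper bracket: no balanced speed below ",
         bracket[2])
  }
  root <- uniroot(g, bracket, tol = tol)
  structure(list(v_star = root$root, A0 = A0, c = c, dims = 2L,
                 converged = TRUE, residual = root$f.root,
                 f_y = ff$fy(root$root)),
            class = "speed_solution")
}

#' Kernel ratio at which 1D and 2D steady speeds cross
#'
#' Below the crossover the thin 2D wake leaves ParA behind the bead pulling
#' it backward and the 1D geometry is faster; above it the 2D bead outruns
#' its 1D counterpart. Located as the root of v*_1D(c) - v*_2D(c).
#'
#' @param A0 dimensionless force scale.
#' @param interval search interval in c.
#' @param tol root tolerance in c.
#' @return The crossover c, or `NA` (with a message) if the speed difference
#'   does not change sign on the interval.
#' @export
find_crossover_c <- function(A0 = 1, interval = c(0.1, 0.8), tol = 1e-4) {
  dv <- function(c) {
    self_consistent_speed_1d(A0, c)$v_star - self_consistent_speed_2d(A0, c)$v_star
  }
  lo <- dv(interval[1])
  hi <- dv(interval[2])
  if (sign(lo) == sign(hi)) {
    message("no 1D/2D speed crossover inside (", interval[1], ", ",
            interval[2], ")")
    return(NA_real_)
  }
  uniroot(dv, interval, tol = tol)$root
}

#' Kernel ratio maximizing the steady-state speed
#'
#' The speed vanishes as c -> 0 (nothing is removed, no gradient) and falls
#' again as c -> 1 (removal reaches as far as the force, flattening the
#' gradient), so v*(c) has an interior maximum that shifts with A0.
#'
#' @param A0 dimensionless force scale.
#' @param dims 1 or 2.
#' @param interval search interval in c.
#' @return List with `c_max` and `v_max`.
#' @export
find_optimal_c <- function(A0 = 1, dims = 1, interval = c(0.05, 1)) {
  vfun <- if (dims == 2) {
    function(c) self_consistent_speed_2d(A0, c)$v_star
  } else {
    function(c) self_consistent_speed_1d(A0, c)$v_star
  }
  opt <- optimize(vfun, interval, maximum = TRUE, tol = 1e-4)
  if (opt$objective <= 0) stop("speed curve is flat on the interval")
  list(c_max = opt$maximum, v_max = opt$objective)
}

#' Analytic speed curves v*(c) in 1D and 2D
#'
#' @param A0 dimensionless force scale.
#' @param c_values kernel ratios to evaluate.
#' @param dims which dimensions to compute (subset of `c(1, 2)`).
#' @return A data frame with columns `c`, and `v1d` / `v2d` as requested.
#' @export
speed_curve <- function(A0 = 1, c_values = seq(0.1, 1, by = 0.05),
                        dims = c(1, 2)) {
  out <- data.frame(c = c_values)
  if (1 %in% dims) {
    out$v1d <- vapply(c_values, function(c) self_consistent_speed_1d(A0, c)$v_star,
                      numeric(1))
  }
  if (2 %in% dims) {
    out$v2d <- vapply(c_values, function(c) self_consistent_speed_2d(A0, c)$v_star,
                      numeric(1))
  }
  out
}

#' @export
print.speed_solution <- function(x, ...) {
  cat(sprintf("%dD self-consistent speed: v* = %.6g (A0 = %g, c = %g)\n",
              x$dims, x$v_star, x$A0, x$c))
  if (x$v_star == 0) cat("  stalled branch: force cannot sustain motion\n")
  invisible(x)
}

#' @export
print.traveling_wave <- function(x, ...) {
  cat(sprintf("Co-moving ParA front: v = %g, c = %g, wake floor %.4g\n",
              x$v, x$c, x$wake_floor))
  invisible(x)
}
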