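#' 2D chemotactic bead velocity
#'
#' Tensor-product Simpson quadrature of the vector force kernel
#' exp(-rho^2/2) * (x - x_p, y - y_p) / (1 + rho^2) * a(x, y), with rho the
#' Euclidean distance to the bead. Contributions are summed in mirror pairs
#' along the odd direction of each component, so symmetric fields give exact
#' zero components.
#'
#' @param field a `para_field_2d`.
#' @param x_p,y_p bead position inside the domain.
#' @param A0 dimensionless force scale.
#' @return Numeric vector `c(v_x, v_y)`.
#' @export
bead_velocity_2d <- function(field, x_p, y_p, A0) {
  if (x_p < 0 || x_p > field$L || y_p < 0 || y_p > field$L) {
    stop("bead position outside the domain")
  }
  v <- cpp_velocity_2d(field$values, field$dx, x_p, y_p, A0)
  c(v_x = v[1], v_y = v[2])
}

#' One Euler step of the 2D removal dynamics
#'
#' Removal kernel exp(-rho^2/(2 c^2)) with Euclidean distance rho to the
#' bead; velocity evaluated on the pre-update field, bead clamped to the
#' domain box.
#'
#' @inheritParams bead_velocity_2d
#' @param bead a [bead_state()] with `x_p` and `y_p`.
#' @param params [dimensionless_params()]; `numerics` [numerics_config()].
#' @param numerics numerics settings.
#' @return List with updated `field` and `bead`.
#' @export
step_2d <- function(field, bead, params, numerics) {
  v <- bead_velocity_2d(field, bead$x_p, bead$y_p, params$A0)
  # offsets via index arithmetic, consistent with the C++ kernels
  off <- function(nodes, p) {
    j0 <- min(max(round(p / field$dx), 0), field$n - 1)
    (seq_along(nodes) - 1 - j0) * field$dx - (p - j0 * field$dx)
  }
  ux <- off(field$x, bead$x_p)
  uy <- off(field$y, bead$y_p)
  gx <- exp(-ux^2 / (2 * params$c^2))
  gy <- exp(-uy^2 / (2 * params$c^2))
  field$values <- pmax(field$values - numerics$dtau * (outer(gx, gy) * field$values), 0)
  x_new <- min(max(bead$x_p + numerics$dtau * v[1], 0), field$L)
  y_new <- min(max(bead$y_p + numerics$dtau * v[2], 0), field$L)
  list(field = field, bead = bead_state(x_new, sqrt(sum(v^2)), y_p = y_new))
}

#' Simulate the 2D bead-ParA dynamics
#'
#' As [simulate_1d()] on a square \[0, L\]^2 grid, for `"base"` and
#' `"rebinding"` modes. The bead starts at the centre node; with rebinding,
#' the released ParA dilutes over the area L^2. At domain boundaries the
#' bead is confined to the box; with rebinding it turns back into
#' ParA-rich regions rather than halting.
#'
#' @inheritParams simulate_1d
#' @return A `para_trajectory` with `x_p`, `y_p`, `v_x`, `v_y` series and
#'   field snapshot matrices at the requested times.
#' @export
simulate_2d <- function(run_config = default_config(dims = 2), ...) {
  config <- resolve_config(run_config, ...)
  mode <- match.arg(config$mode, c("base", "rebinding"))
  validate_config(config)

  sites <- NULL
  ab0 <- 0
  if (mode == "base") {
    field <- init_para_field_2d(config$mean_a, config$delta_a, config$L,
                                config$dx, config$seed)
  } else {
    sites <- init_binding_sites_2d(config$D0, config$delta_d, config$L,
                                   config$dx, config$seed)
    eq <- equilibrate_surface_2d(sites,
                                 buffer_state(config$phi * config$D0, config$D0),
                                 rebinding_params(config$k_r, config$k_c))
    field <- eq$field
    ab0 <- eq$buffer$a_b
  }

  nsteps <- ceiling(config$tau_max / config$dtau)
  snap_steps <- if (length(config$snapshot_tau)) {
    as.integer(round(config$snapshot_tau / config$dtau))
  } else {
    integer(0)
  }
  i0 <- center_index(field$n)
  x0 <- field$x[i0]
  res <- cpp_simulate_2d(field$values, field$dx, x0, x0, config$A0, config$c,
                         config$dtau, nsteps,
                         match(mode, c("base", "rebinding")) - 1L,
                         if (is.null(sites)) matrix(0, 1, 1) else sites$values,
                         ab0, config$k_r, config$k_c, snap_steps)
  if (res$n_clamped > 0) {
    warning("Euler update clamped ", res$n_clamped, " negative node value(s) at 0")
  }
  field$values <- res$a_final
  structure(list(tau = res$tau, x_p = res$x_p, y_p = res$y_p,
                 v_x = res$v_x, v_y = res$v_y,
                 a_b = if (mode == "rebinding") res$a_b else NULL,
                 field = field, sites = sites,
                 snapshots = res$snapshots, snapshot_tau = res$snapshot_tau,
                 x_start = x0, y_start = x0,
                 boundary_hit = FALSE, n_clamped = res$n_clamped,
                 mode = mode, dims = 2L, config = config),
            class = "para_trajectory")
}

# 2D analogue of equilibrate_surface (shared kinetics, area-normalized buffer)
equilibrate_surface_2d <- function(sites, buffer, rb, tol = 1e-8,
                                   max_steps = 1e6) {
  if (rb$k_r == 0 && rb$k_c == 0) {
    stop("nothing can bind: both rebinding rates are zero")
  }
  d <- sites$values
  w <- simpson_weights(sites$n, sites$dx)
  W <- outer(w, w)
  a <- matrix(0, sites$n, sites$n)
  ab <- buffer$a_b
  dtau_eq <- min(0.5, 0.2 / (ab * (rb$k_r + rb$k_c * max(d)) + 1e-12))
  for (k in seq_len(max_steps)) {
    reb <- ab * (d - a) * (rb$k_r + rb$k_c * a)
    if (max(abs(reb)) < tol) {
      field <- structure(list(x = sites$x, y = sites$y, values = a,
                              dx = sites$dx, L = sites$L, n = sites$n),
                         class = "para_field_2d")
      buffer$a_b <- ab
      return(list(field = field, buffer = buffer, steps = k - 1))
    }
    a <- pmin(a + dtau_eq * reb, d)
    ab <- ab - dtau_eq * sum(W * reb) / sites$L^2
    if (ab < 0) ab <- 0
  }
  stop("surface equilibration did not converge within the step cap")
}
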