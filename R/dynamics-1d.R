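#' Numerical integration settings
#'
#' @param dx grid spacing (dimensionless length). Must resolve the removal
#'   kernel: dx <= c/5 is enforced where c is known.
#' @param dtau explicit-Euler time step; capped at 0.1 for stability of the
#'   removal update (the removal factor per step is dtau at the kernel peak).
#' @param tau_max simulation horizon (dimensionless time).
#' @param seed integer PRNG seed for the initial fields.
#' @param speed_fit_window fraction of the trajectory tail used when fitting
#'   the steady speed.
#' @param stall_displacement total displacement (bead radii) below which a
#'   run counts as "no motion".
#' @param lag_threshold fraction of the tail-mean speed that defines motion
#'   onset when locating the lag time.
#' @param stop_margin distance from a domain edge at which integration stops
#'   early (0 disables; used by speed-fitting sweeps to avoid edge effects).
#' @return A `numerics_config` object.
#' @export
numerics_config <- function(dx = 0.02, dtau = 0.01, tau_max = 100, seed = 1,
                            speed_fit_window = 0.5, stall_displacement = 1,
                            lag_threshold = 0.1, stop_margin = 0) {
  if (dx <= 0) stop("dx must be positive")
  if (dtau <= 0) stop("dtau must be positive")
  if (dtau > 0.1) stop("dtau > 0.1 is unstable for the explicit Euler update")
  if (speed_fit_window <= 0 || speed_fit_window > 1) {
    stop("speed_fit_window must be in (0, 1]")
  }
  structure(list(dx = dx, dtau = dtau, tau_max = tau_max, seed = seed,
                 speed_fit_window = speed_fit_window,
                 stall_displacement = stall_displacement,
                 lag_threshold = lag_threshold, stop_margin = stop_margin),
            class = "numerics_config")
}

#' Per-node ParA removal rate
#'
#' Gaussian removal kernel of range c centred on the bead times the local
#' ParA concentration: exp(-(x - x_p)^2/(2 c^2)) * a(x).
#'
#' @param field a `para_field`; `x_p` bead position inside the domain;
#'   `c` kernel range ratio (> 0).
#' @param x_p bead position.
#' @param c removal-to-force range ratio.
#' @return Numeric vector of removal rates per node.
#' @export
removal_rate <- function(field, x_p, c) {
  if (c <= 0) stop("c must be positive")
  if (x_p < 0 || x_p > field$L) stop("bead position outside [0, L]")
  cpp_removal_rate(field$values, field$dx, x_p, c)
}

#' Chemotactic bead speed from the force integral
#'
#' Simpson's-rule quadrature over the whole domain of
#' A0 * exp(-(x-x_p)^2/2) * (x-x_p)/(1+(x-x_p)^2) * a(x).
#' Node contributions mirror-symmetric about the bead are summed in pairs, so
#' a field exactly symmetric about an on-node bead yields speed 0 exactly.
#'
#' @inheritParams removal_rate
#' @param A0 dimensionless force scale.
#' @return Scalar speed v = dx_p/dtau.
#' @export
bead_speed <- function(field, x_p, A0) {
  if (field$n %% 2 == 0) stop("force quadrature needs an even interval count")
  cpp_bead_speed(field$values, field$dx, x_p, A0)
}

#' One Euler step of the base (removal-only) dynamics
#'
#' The speed is evaluated on the pre-update field, then field and bead are
#' advanced simultaneously; a is clamped at 0 (with a warning) if the Euler
#' update overshoots, and the bead is clamped to \[0, L\] at the edges.
#'
#' @param field `para_field`; `bead` a [bead_state()].
#' @param bead bead state.
#' @param params [dimensionless_params()]; `numerics` [numerics_config()].
#' @param numerics numerics settings.
#' @return List with updated `field` and `bead`.
#' @export
step_base <- function(field, bead, params, numerics) {
  v <- bead_speed(field, bead$x_p, params$A0)
  rates <- removal_rate(field, bead$x_p, params$c)
  new_vals <- field$values - numerics$dtau * rates
  if (any(new_vals < 0)) {
    warning("Euler removal overshoot: clamping ", sum(new_vals < 0),
            " node(s) at zero")
    new_vals <- pmax(new_vals, 0)
  }
  field$values <- new_vals
  x_new <- min(max(bead$x_p + numerics$dtau * v, 0), field$L)
  list(field = field, bead = bead_state(x_new, v))
}

#' One Euler step with rebinding from a well-mixed buffer
#'
#' The surface gains a_b*(d - a)*(k_r + k_c*a) and loses the removal term;
#' the buffer balances both integrals divided by L, so the discrete total
#' ParA, integral(a) dx + L*a_b, is conserved to machine precision.
#'
#' @inheritParams step_base
#' @param buffer a [buffer_state()]; `sites` a [init_binding_sites()] field;
#'   `rb` a [rebinding_params()].
#' @param sites binding-site field.
#' @param rb rebinding rates.
#' @return List with updated `field`, `bead`, `buffer`.
#' @export
step_rebinding <- function(field, bead, buffer, sites, rb, params, numerics) {
  a <- field$values
  d <- sites$values
  if (length(a) != length(d)) stop("ParA and binding-site fields must share a grid")
  if (any(a > d + 1e-9)) stop("bound ParA exceeds binding sites on input")
  if (buffer$a_b < 0) stop("buffer ParA must be non-negative")
  rem <- removal_rate(field, bead$x_p, params$c)
  reb <- buffer$a_b * (d - a) * (rb$k_r + rb$k_c * a)
  new_vals <- a + numerics$dtau * (reb - rem)
  if (any(new_vals > d + 1e-9)) {
    sugg <- 1 / (buffer$a_b * (rb$k_r + rb$k_c * max(d)))
    stop(sprintf("dtau too large to preserve a <= d; use dtau below %g", sugg))
  }
  v <- bead_speed(field, bead$x_p, params$A0)
  w <- simpson_weights(field$n, field$dx)
  buffer$a_b <- buffer$a_b +
    numerics$dtau * (sum(w * rem) - sum(w * reb)) / field$L
  field$values <- pmax(new_vals, 0)
  x_new <- min(max(bead$x_p + numerics$dtau * v, 0), field$L)
  list(field = field, bead = bead_state(x_new, v), buffer = buffer)
}

#' One Euler step with saturating ParA surface diffusion
#'
#' Adds kappa * \[d * a'' - a * d''\] to the removal dynamics, with
#' central-difference second derivatives and zero-flux (mirrored-ghost)
#' boundaries. Because binding sites cap the local ParA, the flux vanishes
#' identically whenever a is proportional to d; the spatial noise of d(x)
#' keeps feeding the concentration noise that starts the bead moving.
#'
#' @inheritParams step_rebinding
#' @param dp a [diffusion_params()].
#' @return List with updated `field` and `bead`.
#' @export
step_diffusion <- function(field, bead, sites, dp, params, numerics) {
  a <- field$values
  d <- sites$values
  if (length(a) != length(d)) stop("ParA and binding-site fields must share a grid")
  if (any(a > d + 1e-9)) stop("bound ParA exceeds binding sites on input")
  h2 <- field$dx^2
  cfl <- dp$kappa * max(d) * numerics$dtau / h2
  if (cfl > 0.5) {
    stop(sprintf("diffusion step unstable: kappa*max(d)*dtau/dx^2 = %g > 0.5", cfl))
  }
  lap <- function(z) {
    n <- length(z)
    (c(z[2], z[-n]) - 2 * z + c(z[-1], z[n - 1])) / h2
  }
  rem <- removal_rate(field, bead$x_p, params$c)
  v <- bead_speed(field, bead$x_p, params$A0)
  diff_term <- dp$kappa * (d * lap(a) - a * lap(d))
  field$values <- pmax(a + numerics$dtau * (diff_term - rem), 0)
  x_new <- min(max(bead$x_p + numerics$dtau * v, 0), field$L)
  list(field = field, bead = bead_state(x_new, v))
}

#' Equilibrate the surface with the buffer before introducing the bead
#'
#' Integrates the rebinding-only kinetics from an empty surface (a = 0,
#' a_b = A_s) until the maximum pointwise rate of change drops below `tol`.
#' In the saturated regime (phi > 1) the surface fills to d(x) with buffer
#' ParA left over; undersaturated (phi < 1), the buffer empties and the
#' surface holds essentially all ParA, a ~ phi * d(x).
#'
#' @param sites binding-site field; `buffer` initial [buffer_state()];
#'   `rb` [rebinding_params()].
#' @inheritParams step_rebinding
#' @param tol convergence threshold on max |da/dtau|.
#' @param max_steps step cap before declaring non-convergence.
#' @return List with the equilibrated `field` (a `para_field`) and `buffer`.
#' @export
equilibrate_surface <- function(sites, buffer, rb, tol = 1e-8,
                                max_steps = 1e6) {
  if (rb$k_r == 0 && rb$k_c == 0) {
    stop("nothing can bind: both rebinding rates are zero")
  }
  d <- sites$values
  w <- simpson_weights(sites$n, sites$dx)
  a <- numeric(sites$n)
  ab <- buffer$a_b
  # stable step for the linearized binding rate
  dtau_eq <- min(0.5, 0.2 / (ab * (rb$k_r + rb$k_c * max(d)) + 1e-12))
  for (k in seq_len(max_steps)) {
    reb <- ab * (d - a) * (rb$k_r + rb$k_c * a)
    if (max(abs(reb)) < tol) {
      field <- structure(list(x = sites$x, values = a, dx = sites$dx,
                              L = sites$L, n = sites$n),
                         class = "para_field")
      buffer$a_b <- ab
      return(list(field = field, buffer = buffer, steps = k - 1))
    }
    a <- pmin(a + dtau_eq * reb, d)
    ab <- ab - dtau_eq * sum(w * reb) / sites$L
    if (ab < 0) ab <- 0
  }
  stop("surface equilibration did not converge within the step cap")
}

#' Simulate the 1D bead-ParA dynamics
#'
#' Integrates the coupled field/bead equations with explicit Euler steps and
#' Simpson force quadrature. The bead starts at the domain centre node,
#' mirroring the experimental placement of the bead on a fresh surface.
#' Modes: `"base"` (removal only), `"rebinding"` (well-mixed buffer,
#' equilibrated before the bead is introduced), `"diffusion"` (saturating
#' surface diffusion, surface initialized at phi * d(x)).
#'
#' @param run_config a configuration list as returned by [default_config()] /
#'   [load_config()]; individual entries can be overridden via `...`.
#' @param ... named config overrides (e.g. `A0 = 0.5`, `tau_max = 50`).
#' @return A `para_trajectory`: list with `tau`, `x_p`, `v`, optional `a_b`
#'   buffer series, the final field, requested snapshots, the resolved
#'   config, and flags (`boundary_hit`, `n_clamped`).
#' @export
simulate_1d <- function(run_config = default_config(), ...) {
  config <- resolve_config(run_config, ...)
  mode <- match.arg(config$mode, c("base", "rebinding", "diffusion"))
  validate_config(config)
  if (mode == "diffusion") {
    # keep the explicit diffusion update stable for any kappa by shrinking
    # the step to kappa*max(d)*dtau/dx^2 <= 0.4
    cfl_dtau <- 0.4 * config$dx^2 / (config$kappa * (config$D0 + config$delta_d) + 1e-300)
    if (config$dtau > cfl_dtau) {
      message(sprintf("reducing dtau to %g for diffusion stability", cfl_dtau))
      config$dtau <- cfl_dtau
    }
  }

  g <- para_grid(config$L, config$dx)
  sites <- NULL
  ab0 <- 0
  if (mode == "base") {
    field <- init_para_field(config$mean_a, config$delta_a, config$L,
                             config$dx, config$seed)
  } else {
    sites <- init_binding_sites(config$D0, config$delta_d, config$L,
                                config$dx, config$seed)
    if (mode == "rebinding") {
      eq <- equilibrate_surface(sites, buffer_state(config$phi * config$D0, config$D0),
                                rebinding_params(config$k_r, config$k_c))
      field <- eq$field
      ab0 <- eq$buffer$a_b
    } else {
      field <- structure(list(x = sites$x, values = config$phi * sites$values,
                              dx = sites$dx, L = sites$L, n = sites$n),
                         class = "para_field")
    }
  }

  nsteps <- ceiling(config$tau_max / config$dtau)
  snap_steps <- if (length(config$snapshot_tau)) {
    as.integer(round(config$snapshot_tau / config$dtau))
  } else {
    integer(0)
  }
  x0 <- field$x[center_index(field$n)]
  res <- cpp_simulate_1d(field$values, field$dx, x0, config$A0, config$c,
                         config$dtau, nsteps,
                         match(mode, c("base", "rebinding", "diffusion")) - 1L,
                         if (is.null(sites)) numeric(0) else sites$values,
                         ab0, config$k_r, config$k_c, config$kappa,
                         snap_steps, config$stop_margin)
  if (res$n_clamped > 0) {
    warning("Euler update clamped ", res$n_clamped, " negative node value(s) at 0")
  }
  field$values <- res$a_final
  structure(list(tau = res$tau, x_p = res$x_p, v = res$v,
                 a_b = if (mode == "rebinding") res$a_b else NULL,
                 field = field, sites = sites,
                 snapshots = res$snapshots, snapshot_tau = res$snapshot_tau,
                 x_start = x0, boundary_hit = res$boundary_hit,
                 n_clamped = res$n_clamped, mode = mode, dims = 1L,
                 config = config),
            class = "para_trajectory")
}

#' @export
print.para_trajectory <- function(x, ...) {
  n <- length(x$tau)
  disp <- if (x$dims == 2L) {
    sqrt((x$x_p[n] - x$x_start)^2 + (x$y_p[n] - x$y_start)^2)
  } else {
    abs(x$x_p[n] - x$x_start)
  }
  cat(sprintf("%dD %s-mode trajectory: %d samples to tau = %g\n",
              x$dims, x$mode, n, x$tau[n]))
  cat(sprintf("  net displacement %.4g, final speed %.4g%s\n",
              disp,
              if (x$dims == 2L) sqrt(x$v_x[n]^2 + x$v_y[n]^2) else abs(x$v[n]),
              if (isTRUE(x$boundary_hit)) " (stopped near boundary)" else ""))
  invisible(x)
}
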