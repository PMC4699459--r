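#' Fit the steady speed and lag time of a trajectory
#'
#' The lag is the first time at which the instantaneous speed exceeds
#' `lag_threshold` times the tail-window mean speed; the steady speed is the
#' slope of a linear least-squares fit to position over the trailing
#' `speed_fit_window` fraction of samples. A bead whose total displacement
#' stays below `stall_displacement` is flagged stalled with speed 0 and lag
#' equal to the final time.
#'
#' @param traj a `para_trajectory` (or any list with `tau`, `x_p` and
#'   optionally `v`); 2D trajectories are fitted on the path length.
#' @param speed_fit_window fraction of trailing samples fitted (default from
#'   the trajectory's config, else 0.5).
#' @param lag_threshold motion-onset threshold as a fraction of the tail
#'   mean speed (default from config, else 0.1).
#' @param stall_displacement displacement defining "no motion" (default from
#'   config, else 1 bead radius).
#' @return A `speed_fit`: list with `lag_time`, `speed`, `r_squared`,
#'   `stalled`, `tail_mean_speed`.
#' @export
fit_speed <- function(traj, speed_fit_window = NULL, lag_threshold = NULL,
                      stall_displacement = NULL) {
  cfg <- traj$config %||% list()
  speed_fit_window <- speed_fit_window %||% cfg$speed_fit_window %||% 0.5
  lag_threshold <- lag_threshold %||% cfg$lag_threshold %||% 0.1
  stall_displacement <- stall_displacement %||% cfg$stall_displacement %||% 1

  tau <- traj$tau
  n <- length(tau)
  if (n < 100) stop("trajectory too short to fit (need >= 100 samples)")
  if (!is.null(traj$y_p)) {
    dx <- diff(traj$x_p)
    dy <- diff(traj$y_p)
    pos <- c(0, cumsum(sqrt(dx^2 + dy^2)))   # path length
    spd <- sqrt(traj$v_x^2 + traj$v_y^2)
  } else {
    pos <- traj$x_p - traj$x_p[1]
    spd <- if (!is.null(traj$v)) abs(traj$v) else c(0, abs(diff(traj$x_p)) / diff(tau))
  }

  displacement <- max(abs(pos))
  tail_idx <- seq.int(max(1L, floor(n * (1 - speed_fit_window)) + 1L), n)
  tail_mean <- mean(spd[tail_idx])

  if (displacement < stall_displacement) {
    return(structure(list(lag_time = tau[n], speed = 0, r_squared = NA_real_,
                          stalled = TRUE, tail_mean_speed = tail_mean),
                     class = "speed_fit"))
  }

  onset <- which(spd > lag_threshold * tail_mean)
  lag_time <- if (length(onset)) tau[onset[1]] else tau[n]
  fit <- lm(pos[tail_idx] ~ tau[tail_idx])
  slope <- abs(unname(coef(fit)[2]))
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((pos[tail_idx] - mean(pos[tail_idx]))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  structure(list(lag_time = lag_time, speed = slope, r_squared = r2,
                 stalled = FALSE, tail_mean_speed = tail_mean),
            class = "speed_fit")
}

#' Fit the undersaturated acceleration law v0 L / (L - v0 tau)
#'
#' In the strongly undersaturated regime (phi << 1) every released ParA
#' rebinds ahead of the bead, and the speed grows hyperbolically with a
#' single parameter v0 (the speed extrapolated to motion onset). Time is
#' measured from the fitted lag onset, since the law presumes motion from
#' tau = 0; samples where the predicted pole v0*tau -> L is approached are
#' truncated with a warning.
#'
#' @param traj trajectory (see [fit_speed()]); speeds must be available.
#' @param L domain length used in the law (defaults to the config's L).
#' @param lag_time motion onset; `NULL` uses the [fit_speed()] estimate, 0
#'   fits the series as-is (synthetic series generated from the law).
#' @return An `accel_fit`: list with `v0`, `L`, `r_squared`, `n_used`.
#' @export
fit_acceleration <- function(traj, L = NULL, lag_time = NULL) {
  cfg <- traj$config %||% list()
  L <- L %||% cfg$L
  if (is.null(L)) stop("supply the domain length L")
  if (is.null(lag_time)) lag_time <- fit_speed(traj)$lag_time
  spd <- if (!is.null(traj$v)) abs(traj$v) else abs(traj$v_x)
  keep <- traj$tau >= lag_time & spd > 0
  tau <- traj$tau[keep] - lag_time
  v <- spd[keep]
  if (length(v) < 10) stop("too few moving samples for the acceleration fit")

  v0_start <- max(v[1], 1e-4)
  # guard the pole: drop samples an nls iterate could push past tau = L/v0
  vmax_bound <- 0.999 * L / max(tau[tau > 0])
  if (any(v >= vmax_bound) || v0_start * max(tau) >= L) {
    warning("speed series approaches the v0*tau = L pole; truncating")
    cut <- which(v >= vmax_bound)[1]
    if (!is.na(cut) && cut > 10) {
      tau <- tau[seq_len(cut - 1)]
      v <- v[seq_len(cut - 1)]
    }
  }
  df <- data.frame(tau = tau, v = v)
  fit <- nls(v ~ v0 * L / (L - v0 * tau), data = df,
             start = list(v0 = v0_start),
             control = nls.control(maxiter = 200, warnOnly = TRUE, scaleOffset = 1))
  v0 <- abs(unname(coef(fit)["v0"]))
  pred <- predict(fit)
  ss_res <- sum((v - pred)^2)
  ss_tot <- sum((v - mean(v))^2)
  structure(list(v0 = v0, L = L,
                 r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
                 n_used = length(v), lag_time = lag_time),
            class = "accel_fit")
}

#' Saturation ratio at which the bead fails to start
#'
#' In the saturated regime (phi > 1) leftover buffer ParA refills the wake;
#' above a boundary phi_stop the bead never commences motion. Located by
#' bisection on phi, calling a run stalled when its total displacement stays
#' below the configured `stall_displacement` by `tau_max`.
#'
#' @param k_r,k_c rebinding rates.
#' @param base_config rebinding-mode configuration shared by all probe runs
#'   (same seed, hence same binding-site field).
#' @param phi_hi upper search bound; if the bead still moves there the
#'   boundary is reported open (`Inf` with a message).
#' @param tol bisection tolerance on phi.
#' @return The stall boundary phi_stop (or `Inf` if open).
#' @export
find_phi_stop <- function(k_r, k_c = 0, base_config = NULL, phi_hi = 3,
                          tol = 0.01) {
  if (k_r <= 0 && k_c <= 0) stop("need a positive rebinding rate")
  cfg <- base_config %||% default_config(mode = "rebinding", L = 20,
                                         tau_max = 200)
  cfg$mode <- "rebinding"
  cfg$k_r <- k_r
  cfg$k_c <- k_c
  stalled_at <- function(phi) {
    traj <- simulate_1d(cfg, phi = phi)
    max(abs(traj$x_p - traj$x_p[1])) < cfg$stall_displacement
  }
  lo <- 1.01
  if (stalled_at(lo)) return(lo)
  if (!stalled_at(phi_hi)) {
    message("bead still moves at phi = ", phi_hi, ": stall boundary open")
    return(Inf)
  }
  hi <- phi_hi
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (stalled_at(mid)) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' Fit the stall-boundary law phi_stop(k_r) = 1/(k_r * Delta_tau) + 1
#'
#' The wake takes a time ~Delta_tau to refill; the bead starts only if it
#' escapes before that. Fitting the measured boundary against the law yields
#' the refill timescale.
#'
#' @param phi_stop_curve data frame with columns `k_r` and `phi_stop`
#'   (>= 4 rows).
#' @return A `phi_stop_fit`: list with `delta_tau`, `r_squared`, `fitted`.
#' @export
fit_delta_tau <- function(phi_stop_curve) {
  stopifnot(is.data.frame(phi_stop_curve),
            all(c("k_r", "phi_stop") %in% names(phi_stop_curve)))
  kr <- phi_stop_curve$k_r
  ps <- phi_stop_curve$phi_stop
  if (length(kr) < 4) stop("need phi_stop at >= 4 rebinding rates")
  if (!is.unsorted(ps[order(kr)])) {
    warning("phi_stop does not decrease with k_r: 1/(k_r*Delta_tau)+1 may not apply")
  }
  z <- 1 / kr
  y <- ps - 1
  inv_dt <- sum(y * z) / sum(z^2)          # linear LS start (no intercept)
  fit <- nls(ps ~ 1 / (kr * dt) + 1, data = data.frame(kr = kr, ps = ps),
             start = list(dt = 1 / inv_dt),
             control = nls.control(maxiter = 200, warnOnly = TRUE, scaleOffset = 1))
  dt <- unname(coef(fit)["dt"])
  pred <- predict(fit)
  ss_res <- sum((ps - pred)^2)
  ss_tot <- sum((ps - mean(ps))^2)
  structure(list(delta_tau = dt,
                 r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
                 fitted = pred),
            class = "phi_stop_fit")
}

#' Replicate sweep of a model parameter
#'
#' Runs `n_replicates` seeded simulations at each parameter value, fits the
#' steady speed of each, and summarizes mean and standard error per value.
#' Replicate seeds are derived deterministically from the base seed so a
#' sweep is reproducible replicate-by-replicate.
#'
#' @param parameter one of `"A0"`, `"c"`, `"delta_a"`, `"k_r"`, `"k_c"`,
#'   `"phi"`, `"kappa"`.
#' @param values parameter values to sweep.
#' @param base_config configuration shared by all runs (its `mode` decides
#'   which dynamics run).
#' @param n_replicates replicate simulations per value.
#' @param seed base seed; replicate i of value j runs with
#'   seed + (j-1)*n_replicates + (i-1).
#' @param paired_seeds reuse the same replicate seeds (seed + i - 1) at every
#'   parameter value, pairing the ensembles — appropriate when comparing
#'   means across values of a noise parameter such as `delta_a`.
#' @return A `sweep_result` data frame: `value`, `mean_speed`, `sd_speed`,
#'   `stderr`, `n`, `n_stalled`, `n_failed`.
#' @export
sweep_parameter <- function(parameter, values, base_config = NULL,
                            n_replicates = 20, seed = NULL,
                            paired_seeds = FALSE) {
  parameter <- match.arg(parameter,
                         c("A0", "c", "delta_a", "k_r", "k_c", "phi", "kappa"))
  cfg <- base_config %||% default_config()
  seed <- seed %||% cfg$seed
  rows <- lapply(seq_along(values), function(j) {
    speeds <- rep(NA_real_, n_replicates)
    stalled <- logical(n_replicates)
    for (i in seq_len(n_replicates)) {
      run_cfg <- cfg
      run_cfg[[parameter]] <- values[j]
      run_cfg$seed <- if (paired_seeds) {
        seed + (i - 1L)
      } else {
        seed + (j - 1L) * n_replicates + (i - 1L)
      }
      res <- tryCatch({
        traj <- if (identical(cfg$dims, 2) || identical(cfg$dims, 2L)) {
          simulate_2d(run_cfg)
        } else {
          simulate_1d(run_cfg)
        }
        fit_speed(traj)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        warning("replicate ", i, " at ", parameter, " = ", values[j],
                " failed: ", conditionMessage(res))
      } else {
        speeds[i] <- res$speed
        stalled[i] <- res$stalled
      }
    }
    ok <- !is.na(speeds)
    data.frame(value = values[j],
               mean_speed = mean(speeds[ok]),
               sd_speed = sd(speeds[ok]),
               stderr = sd(speeds[ok]) / sqrt(sum(ok)),
               n = sum(ok),
               n_stalled = sum(stalled[ok]),
               n_failed = sum(!ok))
  })
  out <- do.call(rbind, rows)
  attr(out, "parameter") <- parameter
  class(out) <- c("sweep_result", "data.frame")
  out
}

#' @export
print.speed_fit <- function(x, ...) {
  if (x$stalled) {
    cat(sprintf("Stalled: no net motion (lag/horizon %g)\n", x$lag_time))
  } else {
    cat(sprintf("Steady speed %.5g (lag %.3g, tail fit R^2 = %.5f)\n",
                x$speed, x$lag_time, x$r_squared))
  }
  invisible(x)
}

#' @export
print.accel_fit <- function(x, ...) {
  cat(sprintf("Acceleration law fit: v0 = %.5g (L = %g, R^2 = %.4f, n = %d)\n",
              x$v0, x$L, x$r_squared, x$n_used))
  invisible(x)
}

#' @export
print.phi_stop_fit <- function(x, ...) {
  cat(sprintf("Stall-boundary fit: Delta_tau = %.4g (R^2 = %.4f)\n",
              x$delta_tau, x$r_squared))
  invisible(x)
}
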