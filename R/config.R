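#' Default simulation configuration
#'
#' Flat key-value configuration covering every model, numerics and analysis
#' knob. Defaults follow the reference 1D setup (L = 70, dx = 0.02,
#' dtau = 0.01, mean ParA 1 with 5% uniform noise, A0 = 1, c = 0.5); the 2D
#' default domain is smaller (L = 20, dx = 0.05) to keep runs desk-scale.
#'
#' @param mode `"base"`, `"rebinding"` or `"diffusion"`.
#' @param dims 1 or 2.
#' @param ... overrides of individual keys.
#' @return A named list of class `para_config`.
#' @export
default_config <- function(mode = "base", dims = 1, ...) {
  cfg <- list(
    mode = mode,
    dims = dims,
    # model
    A0 = 1.0,
    c = 0.5,
    L = if (dims == 2) 20 else 70,
    mean_a = 1.0,
    delta_a = 0.05,
    # rebinding / diffusion
    D0 = 1.0,
    delta_d = 0.05,
    phi = 0.5,
    k_r = 0.25,
    k_c = 0.0,
    kappa = 0.1,
    # numerics
    dx = if (dims == 2) 0.05 else if (mode == "diffusion") 0.1 else 0.02,
    dtau = 0.01,
    tau_max = 100,
    seed = 1,
    snapshot_tau = numeric(0),
    stop_margin = 0,
    # trajectory analysis
    speed_fit_window = 0.5,
    stall_displacement = 1,
    lag_threshold = 0.1
  )
  cfg <- resolve_config(cfg, ...)
  class(cfg) <- c("para_config", "list")
  cfg
}

# merge overrides into a config, rejecting unknown keys
resolve_config <- function(run_config, ...) {
  overrides <- list(...)
  if (!length(overrides)) return(run_config)
  unknown <- setdiff(names(overrides), names(default_config()))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  out <- modifyList(run_config, overrides)
  class(out) <- class(run_config)
  out
}

#' Validate a configuration
#'
#' Checks every invariant the model requires (positivity, noise bounded by
#' the mean, the removal kernel resolved by the grid, Euler step bounds,
#' diffusion stability) and reports all violations at once.
#'
#' @param config a configuration list.
#' @return The config, invisibly, if valid; otherwise an error itemizing
#'   every violated rule.
#' @export
validate_config <- function(config) {
  problems <- character(0)
  p <- function(msg) problems <<- c(problems, msg)
  cfg <- config

  if (!cfg$mode %in% c("base", "rebinding", "diffusion")) {
    p("mode must be base, rebinding or diffusion")
  }
  if (!cfg$dims %in% c(1, 2)) p("dims must be 1 or 2")
  if (cfg$dims == 2 && identical(cfg$mode, "diffusion")) {
    p("surface diffusion is implemented for the 1D model only")
  }
  if (cfg$A0 <= 0) p("A0 must be positive")
  if (cfg$c <= 0) p("c must be positive")
  if (cfg$L <= 0) p("L must be positive")
  if (cfg$mean_a <= 0) p("mean_a must be positive")
  if (cfg$delta_a < 0 || cfg$delta_a > cfg$mean_a) {
    p("delta_a must lie in [0, mean_a]")
  }
  if (cfg$D0 <= 0) p("D0 must be positive")
  if (cfg$delta_d < 0 || cfg$delta_d > cfg$D0) p("delta_d must lie in [0, D0]")
  if (cfg$phi < 0) p("phi must be non-negative")
  if (cfg$k_r < 0 || cfg$k_c < 0) p("rebinding rates must be non-negative")
  if (cfg$kappa < 0) p("kappa must be non-negative")
  if (cfg$dx <= 0) p("dx must be positive")
  if (cfg$dx > cfg$c / 5) {
    p(sprintf("dx = %g under-resolves the removal kernel: need dx <= c/5 = %g",
              cfg$dx, cfg$c / 5))
  }
  if (cfg$dtau <= 0) p("dtau must be positive")
  if (cfg$dtau > 0.1) p("dtau must not exceed 0.1 (explicit Euler stability)")
  if (cfg$tau_max <= 0) p("tau_max must be positive")
  if (cfg$speed_fit_window <= 0 || cfg$speed_fit_window > 1) {
    p("speed_fit_window must be in (0, 1]")
  }
  if (cfg$stall_displacement <= 0) p("stall_displacement must be positive")

  if (length(problems)) {
    stop("invalid configuration:\n", paste(" -", problems, collapse = "\n"))
  }
  invisible(config)
}

#' Load a configuration from a YAML file
#'
#' Unknown keys are an itemized error; missing keys take their defaults; the
#' merged config is validated before being returned. An empty file yields
#' the full default (base 1D) configuration.
#'
#' @param path YAML file of flat key-value pairs.
#' @return A validated `para_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  defaults <- default_config(mode = user$mode %||% "base",
                             dims = user$dims %||% 1)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stop("unknown config key(s) in ", path, ": ", paste(unknown, collapse = ", "))
  }
  cfg <- modifyList(defaults, user)
  # YAML reads whole numbers as integers and empty sequences as lists;
  # normalize every numeric key to double so round trips are lossless
  for (k in names(cfg)) {
    if (is.numeric(defaults[[k]])) cfg[[k]] <- as.numeric(unlist(cfg[[k]]))
  }
  cfg$snapshot_tau <- as.numeric(unlist(cfg$snapshot_tau))
  class(cfg) <- c("para_config", "list")
  validate_config(cfg)
  cfg
}

#' Save a configuration to a YAML file
#'
#' @param config a configuration list; `path` destination file.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  cfg <- unclass(config)
  cfg$snapshot_tau <- as.numeric(cfg$snapshot_tau)
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}
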