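#' Dimensionless model parameters
#'
#' The model collapses all physical constants into two control parameters:
#' `A0`, the dimensionless force scale (F0*a0/(beta*R)), and `c`, the ratio
#' sigma_r/sigma_f of the ParA-removal range to the ParA-ParB force range.
#' Lengths are in units of the bead radius R, times in units of the inverse
#' removal rate 1/gamma0.
#'
#' @param A0 dimensionless force scale, > 0.
#' @param c removal-to-force range ratio, > 0. Values above 1 are physically
#'   implausible (ParA cannot be removed from beyond the force reach) and
#'   trigger a warning.
#' @param L domain length in bead radii, > 0.
#' @param delta_a half-width of the uniform noise on the initial ParA
#'   concentration; must lie in [0, mean concentration].
#' @param mean_a mean initial ParA concentration (dimensionless), used to
#'   bound `delta_a`.
#' @return An object of class `dimensionless_params`.
#' @export
dimensionless_params <- function(A0 = 1, c = 0.5, L = 70, delta_a = 0.05,
                                 mean_a = 1) {
  stopifnot(is.numeric(A0), length(A0) == 1, is.numeric(c), length(c) == 1)
  if (A0 <= 0) stop("A0 must be positive")
  if (c <= 0) stop("c must be positive")
  if (c > 1) warning("c > 1: removal range exceeds force range, unphysical")
  if (L <= 0) stop("L must be positive")
  if (delta_a < 0) stop("delta_a must be non-negative")
  if (delta_a > mean_a) stop("delta_a exceeds mean concentration: would allow negative ParA")
  structure(list(A0 = A0, c = c, L = L, delta_a = delta_a, mean_a = mean_a),
            class = "dimensionless_params")
}

#' Physical (dimensionful) model parameters
#'
#' Holds the dimensionful constants of the reaction-advection model: the ParA
#' removal rate gamma0, the force scale F0 per unit ParA*ParB, the drag
#' coefficient beta (Stokes drag 6*pi*eta*R when built from viscosity and
#' bead radius), the two Gaussian ranges sigma_r (removal) and sigma_f
#' (force), and the ParA concentration scale a0. Use consistent units; only
#' ratios enter the dimensionless model.
#'
#' @param gamma0 ParA removal rate (1/time).
#' @param F0 force scale per unit ParA*ParB.
#' @param R bead radius (length).
#' @param sigma_r removal range (length).
#' @param sigma_f force range (length).
#' @param a0 ParA concentration scale.
#' @param beta drag coefficient (force*time/length); computed as 6*pi*eta*R
#'   when omitted and `eta` is given.
#' @param eta buffer viscosity; used only to build `beta`.
#' @return An object of class `physical_params`.
#' @export
physical_params <- function(gamma0, F0, R, sigma_r, sigma_f, a0,
                            beta = NULL, eta = NULL) {
  if (is.null(beta)) {
    if (is.null(eta)) stop("supply either beta or eta")
    beta <- 6 * pi * eta * R
  }
  vals <- c(gamma0 = gamma0, F0 = F0, R = R, sigma_r = sigma_r,
            sigma_f = sigma_f, a0 = a0, beta = beta)
  bad <- names(vals)[!is.finite(vals) | vals <= 0]
  if (length(bad)) {
    stop("physical parameters must be strictly positive: ", paste(bad, collapse = ", "))
  }
  structure(c(as.list(vals), list(eta = eta)), class = "physical_params")
}

#' Reduce physical parameters to the dimensionless model
#'
#' Applies the rescaling X -> R*x, t -> tau/gamma0, Am -> a0*a, under which
#' the dynamics depend only on A0 = F0*a0/(beta*R) and c = sigma_r/sigma_f.
#'
#' @param phys a [physical_params()] object.
#' @param domain_length physical length of the DNA-coated surface; converted
#'   to L = domain_length/R. Defaults to 70 bead radii.
#' @param delta_a dimensionless initial-noise half-width carried through.
#' @return A [dimensionless_params()] object; the conversion scales are kept
#'   in attributes `length_scale` (R) and `time_scale` (1/gamma0).
#' @export
dedimensionalize <- function(phys, domain_length = NULL, delta_a = 0.05) {
  stopifnot(inherits(phys, "physical_params"))
  L <- if (is.null(domain_length)) 70 else domain_length / phys$R
  dp <- dimensionless_params(
    A0 = phys$F0 * phys$a0 / (phys$beta * phys$R),
    c = phys$sigma_r / phys$sigma_f,
    L = L,
    delta_a = delta_a
  )
  attr(dp, "length_scale") <- phys$R
  attr(dp, "time_scale") <- 1 / phys$gamma0
  dp
}

#' Recover physical parameters from dimensionless ones
#'
#' Inverts [dedimensionalize()] given the scales that the reduction divides
#' out. Round-tripping a `physical_params` object recovers F0 and sigma_r to
#' machine precision.
#'
#' @param dp a [dimensionless_params()] object.
#' @param R bead radius; `gamma0` removal rate; `a0` concentration scale;
#'   `sigma_f` force range. `beta` or `eta` as in [physical_params()].
#' @inheritParams physical_params
#' @return A [physical_params()] object.
#' @export
redimensionalize <- function(dp, gamma0, R, a0, sigma_f, beta = NULL, eta = NULL) {
  stopifnot(inherits(dp, "dimensionless_params"))
  if (is.null(beta)) {
    if (is.null(eta)) stop("supply either beta or eta")
    beta <- 6 * pi * eta * R
  }
  physical_params(gamma0 = gamma0,
                  F0 = dp$A0 * beta * R / a0,
                  R = R,
                  sigma_r = dp$c * sigma_f,
                  sigma_f = sigma_f,
                  a0 = a0,
                  beta = beta,
                  eta = eta)
}

#' Estimate the effective force range from bead and surface composition
#'
#' Back-of-envelope estimate used to place the in vitro system inside the
#' model's parameter range: a bead carrying `n_parB` ParB molecules needs to
#' contact roughly `n_parB / parB_to_parA_ratio` surface ParA molecules to
#' move; at a given ParA surface density those cover a disc whose radius is
#' taken as the effective force range sigma_f.
#'
#' @param n_parB number of ParB molecules on the bead able to reach the
#'   surface (in vitro estimate ~4800).
#' @param parB_to_parA_ratio ParB:ParA ratio required for motion (~5).
#' @param surface_density ParA molecules per square micron on the surface
#'   (~400).
#' @param sigma_r measured removal range in microns (~0.225), used for the
#'   derived ratio c.
#' @return A list with the raw and one-significant-figure ParA requirement,
#'   the covered area (um^2), the disc-radius force range sigma_f (um), and
#'   the implied c = sigma_r/sigma_f.
#' @export
estimate_force_range <- function(n_parB = 4800, parB_to_parA_ratio = 5,
                                 surface_density = 400, sigma_r = 0.225) {
  if (n_parB <= 0 || parB_to_parA_ratio <= 0) stop("counts and ratio must be positive")
  if (surface_density <= 0) stop("surface density must be positive")
  raw <- n_parB / parB_to_parA_ratio
  required <- signif(raw, 1)
  area <- required / surface_density
  sigma_f <- sqrt(area / pi)
  list(required_parA_raw = raw,
       required_parA = required,
       area_um2 = area,
       sigma_f_um = sigma_f,
       c = sigma_r / sigma_f)
}

#' @export
print.dimensionless_params <- function(x, ...) {
  cat("Dimensionless ParA-ParB parameters\n")
  cat(sprintf("  A0 = %g  c = %g  L = %g  delta_a = %g (mean a = %g)\n",
              x$A0, x$c, x$L, x$delta_a, x$mean_a))
  invisible(x)
}

#' @export
print.physical_params <- function(x, ...) {
  cat("Physical ParA-ParB parameters\n")
  cat(sprintf("  gamma0 = %g  F0 = %g  R = %g  beta = %g\n",
              x$gamma0, x$F0, x$R, x$beta))
  cat(sprintf("  sigma_r = %g  sigma_f = %g  a0 = %g\n",
              x$sigma_r, x$sigma_f, x$a0))
  invisible(x)
}
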