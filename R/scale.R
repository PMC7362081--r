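#' Scale-model constants
#'
#' Bundles the constants of the multifractal scale description: the
#' scale-transition coefficient `lam` (length^2/time), the scale resolution
#' `dt` (dimensionless), the specific time `tau0` (hours), the width `alpha`
#' of the initial Gaussian position distribution (length) and the initial
#' velocity `v0` (length/time). These are external choices of the scale
#' description, not fitted quantities; the defaults make the nondimensional
#' time equal to the time in hours and the fractality map
#' \eqn{\sigma = \lambda\, dt^{2/f(\alpha) - 1}} well defined (`dt != 1`).
#'
#' @param lam scale-transition coefficient, > 0.
#' @param dt scale resolution, > 0 and != 1.
#' @param tau0 specific time used to nondimensionalize time, > 0.
#' @param alpha Gaussian width parameter, > 0.
#' @param v0 initial velocity.
#' @return An object of class `"scale_config"` (a named list).
#' @export
scale_config <- function(lam = 1, dt = 0.1, tau0 = 1, alpha = 1, v0 = 1) {
  stopifnot(is.numeric(lam), length(lam) == 1L, lam > 0,
            is.numeric(dt), length(dt) == 1L, dt > 0,
            is.numeric(tau0), length(tau0) == 1L, tau0 > 0,
            is.numeric(alpha), length(alpha) == 1L, alpha > 0,
            is.numeric(v0), length(v0) == 1L)
  if (dt == 1) stop("'dt' must differ from 1: the exponent of the scale-fractality relation is unidentifiable at dt = 1")
  structure(list(lam = lam, dt = dt, tau0 = tau0, alpha = alpha, v0 = v0),
            class = "scale_config")
}

#' Diffusion-like scale coefficient from the fractality degree
#'
#' Evaluates the scale-fractality relation
#' \eqn{\sigma = \lambda \, (dt)^{2/f(\alpha) - 1}} mapping the effective
#' fractal dimension \eqn{f(\alpha)} of the motion curves to the
#' diffusion-like coefficient \eqn{\sigma} of the hydrodynamic fields.
#' At \eqn{f(\alpha) = 2} (Peano-like curves) the exponent vanishes and
#' \eqn{\sigma = \lambda} regardless of the resolution.
#'
#' @param lam scale-transition coefficient, >= 0 (0 gives sigma = 0).
#' @param dt scale resolution, > 0.
#' @param f_alpha singularity-spectrum value (effective fractal dimension), > 0.
#' @return sigma, the diffusion-like coefficient (length^2/time), >= 0.
#' @seealso [fractality_from_sigma()] for the inverse map.
#' @export
#' @examples
#' sigma_from_scale(3, 0.1, 2)   # exponent vanishes -> 3
#' sigma_from_scale(1, 0.1, 1)   # exponent 1 -> 0.1
sigma_from_scale <- function(lam, dt, f_alpha) {
  stopifnot(is.numeric(lam), is.numeric(dt), is.numeric(f_alpha))
  if (any(lam < 0)) stop("'lam' must be >= 0")
  if (any(dt <= 0)) stop("'dt' must be > 0")
  if (any(f_alpha <= 0)) stop("'f_alpha' must be > 0")
  lam * dt^(2 / f_alpha - 1)
}

#' Fractality degree from the diffusion-like coefficient
#'
#' Inverts the scale-fractality relation: solves
#' \eqn{\sigma = \lambda \, (dt)^{2/f - 1}} for the effective fractal
#' dimension \eqn{f}. Requires `dt != 1` (the exponent is unidentifiable
#' there) and a positive ratio `sigma/lam`.
#'
#' @param sigma diffusion-like coefficient, > 0.
#' @param lam scale-transition coefficient, > 0.
#' @param dt scale resolution, > 0 and != 1.
#' @return f_alpha such that [sigma_from_scale()] round-trips to `sigma`.
#' @export
#' @examples
#' fractality_from_sigma(3, 3, 0.1)    # 2
#' fractality_from_sigma(0.1, 1, 0.1)  # 1
fractality_from_sigma <- function(sigma, lam, dt) {
  stopifnot(is.numeric(sigma), is.numeric(lam), is.numeric(dt))
  if (any(dt <= 0)) stop("'dt' must be > 0")
  if (any(dt == 1)) stop("'dt' must differ from 1: exponent unidentifiable")
  if (any(lam <= 0)) stop("'lam' must be > 0")
  if (any(sigma <= 0)) stop("'sigma' must be > 0 (sigma/lam must be positive)")
  f <- 2 / (1 + log(sigma / lam) / log(dt))
  if (any(!is.finite(f)) || any(f <= 0))
    stop("sigma/lam outside the representable range for this (lam, dt): implied f(alpha) is not positive")
  f
}

#' Dimensional hydrodynamic parameters
#'
#' @param v0 initial velocity (length/time); must be nonzero so the width
#'   parameter phi of the nondimensional form is defined.
#' @param alpha Gaussian position-distribution width (length), > 0.
#' @param sigma diffusion-like scale coefficient (length^2/time), >= 0.
#' @param tau0 specific time (time), > 0.
#' @return An object of class `"hydro_params"`.
#' @export
hydro_params <- function(v0 = 1, alpha = 1, sigma = 0, tau0 = 1) {
  stopifnot(is.numeric(v0), length(v0) == 1L,
            is.numeric(alpha), length(alpha) == 1L, alpha > 0,
            is.numeric(sigma), length(sigma) == 1L, sigma >= 0,
            is.numeric(tau0), length(tau0) == 1L, tau0 > 0)
  structure(list(v0 = v0, alpha = alpha, sigma = sigma, tau0 = tau0),
            class = "hydro_params")
}

#' Nondimensionalize the hydrodynamic parameters
#'
#' Maps the dimensional parameters to the two shape parameters of the
#' nondimensional fields: the fractality-degree parameter
#' \eqn{\mu = \sigma \tau_0 / \alpha^2} and the width parameter
#' \eqn{\phi = \alpha / (V_0 \tau_0)}. Space and time map as
#' \eqn{\xi = x/(V_0\tau_0)}, \eqn{\eta = t/\tau_0}.
#'
#' @param h a [hydro_params()] object.
#' @return A list with elements `mu` (>= 0) and `phi` (> 0).
#' @export
#' @examples
#' nondimensionalize(hydro_params(v0 = 2, alpha = 1, sigma = 1, tau0 = 1))
nondimensionalize <- function(h) {
  stopifnot(inherits(h, "hydro_params"))
  if (h$v0 == 0) stop("'v0' must be nonzero: phi = alpha/(v0*tau0) is undefined")
  list(mu = h$sigma * h$tau0 / h$alpha^2,
       phi = h$alpha / (h$v0 * h$tau0))
}

# Map (x, t) -> (xi, eta); inverse of nondim_coords_inv.
nondim_coords <- function(x, t, h) {
  list(xi = x / (h$v0 * h$tau0), eta = t / h$tau0)
}

nondim_coords_inv <- function(xi, eta, h) {
  list(x = xi * h$v0 * h$tau0, t = eta * h$tau0)
}
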