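# Saturating exp: clips the argument at +/-700 before exponentiation so that
# extreme nondimensional coordinates saturate instead of overflowing.
exp_clip <- function(z) exp(pmin(pmax(z, -700), 700))

#' Nondimensional velocity field
#'
#' Closed-form nondimensional velocity of the multifractal hydrodynamic
#' model, \eqn{\bar V(\mu,\xi,\eta) = (1 + \mu^2\xi\eta)/(1 + \mu^2\eta^2)}.
#' It satisfies the initial condition \eqn{\bar V(\xi, 0) = 1} and the
#' comoving boundary condition \eqn{\bar V(\xi = \eta, \eta) = 1}.
#'
#' @param mu fractality-degree parameter, >= 0.
#' @param xi nondimensional position coordinate.
#' @param eta nondimensional time, >= 0.
#' @return Dimensionless velocity values (recycled to the common length).
#' @export
#' @examples
#' velocity_field(1, xi = 2, eta = 1)  # 1.5
velocity_field <- function(mu, xi, eta) {
  stopifnot(is.numeric(mu), is.numeric(xi), is.numeric(eta))
  if (any(mu < 0)) stop("'mu' must be >= 0")
  if (any(eta < 0)) stop("'eta' must be >= 0")
  (1 + mu^2 * xi * eta) / (1 + mu^2 * eta^2)
}

#' Nondimensional density field
#'
#' Closed-form nondimensional state density of the multifractal hydrodynamic
#' model,
#' \deqn{\bar\rho(\mu,\phi,\xi,\eta) = (1+\mu^2\eta^2)^{-1/2}
#'   \exp\!\left[-\frac{(\xi-\eta)^2}{\phi^2(1+\mu^2\eta^2)}\right],}
#' a Gaussian pulse translating at unit nondimensional speed while spreading
#' at a rate controlled by the fractality-degree parameter `mu`. Values lie
#' in (0, 1]; at `mu = 0` the pulse translates rigidly without spreading.
#'
#' @param mu fractality-degree parameter, >= 0.
#' @param phi width parameter, > 0.
#' @param xi nondimensional position coordinate.
#' @param eta nondimensional time, >= 0.
#' @return Dimensionless density values in (0, 1].
#' @export
#' @examples
#' density_field(0, 1, xi = 2, eta = 1)  # exp(-1)
density_field <- function(mu, phi, xi, eta) {
  stopifnot(is.numeric(mu), is.numeric(phi), is.numeric(xi), is.numeric(eta))
  if (any(mu < 0)) stop("'mu' must be >= 0")
  if (any(phi <= 0)) stop("'phi' must be > 0")
  if (any(eta < 0)) stop("'eta' must be >= 0")
  a <- 1 + mu^2 * eta^2
  a^(-0.5) * exp_clip(-(xi - eta)^2 / (phi^2 * a))
}

#' Dimensional velocity field
#'
#' Closed-form dimensional velocity
#' \eqn{V_D(x,t) = [V_0\alpha^2 + (\sigma/\alpha)^2 x t] /
#'      [\alpha^2 + (\sigma/\alpha)^2 t^2]}.
#' Equals `v0` everywhere at `t = 0` and along the comoving line
#' `x = v0 t` for all `t`; consistent with [velocity_field()] after
#' nondimensionalization.
#'
#' @param x position (length).
#' @param t time, >= 0.
#' @param h a [hydro_params()] object.
#' @return Velocity values (length/time).
#' @export
dimensional_velocity <- function(x, t, h) {
  stopifnot(inherits(h, "hydro_params"), is.numeric(x), is.numeric(t))
  if (any(t < 0)) stop("'t' must be >= 0")
  r2 <- (h$sigma / h$alpha)^2
  (h$v0 * h$alpha^2 + r2 * x * t) / (h$alpha^2 + r2 * t^2)
}

#' Dimensional density field
#'
#' Closed-form dimensional state density
#' \deqn{\rho(x,t) = \pi^{-1/2}\,[\alpha^2 + (\sigma/\alpha)^2 t^2]^{-1/2}
#'   \exp\!\left[-\frac{(x - V_0 t)^2}{\alpha^2 + (\sigma/\alpha)^2 t^2}\right],}
#' a normalized Gaussian (unit integral over x for every t) that starts as
#' the initial condition \eqn{\rho(x,0) = (\sqrt{\pi}\alpha)^{-1}
#' \exp[-(x/\alpha)^2]} and spreads with the squared width
#' \eqn{\alpha^2 + (\sigma/\alpha)^2 t^2}.
#'
#' @param x position (length).
#' @param t time, >= 0.
#' @param h a [hydro_params()] object.
#' @return Density values (1/length).
#' @export
dimensional_density <- function(x, t, h) {
  stopifnot(inherits(h, "hydro_params"), is.numeric(x), is.numeric(t))
  if (any(t < 0)) stop("'t' must be >= 0")
  s2 <- h$alpha^2 + (h$sigma / h$alpha)^2 * t^2
  pi^(-0.5) * s2^(-0.5) * exp_clip(-(x - h$v0 * t)^2 / s2)
}

#' Release-law parameters
#'
#' Parameters of the nondimensional mass-release law: the two shape
#' parameters `mu` and `phi` of the density field, the releasable
#' nondimensional mass `m0_bar` (the asymptotic released fraction), and the
#' fixed observation coordinate `xi_obs` at which the local density
#' depletion is read (default 0, the initial density peak, i.e. the matrix).
#'
#' @param mu fractality-degree parameter, >= 0.
#' @param phi width parameter, > 0.
#' @param m0_bar nondimensional releasable mass, > 0.
#' @param xi_obs nondimensional observation coordinate (default 0).
#' @return An object of class `"release_model_params"`.
#' @export
release_model_params <- function(mu, phi, m0_bar, xi_obs = 0) {
  stopifnot(is.numeric(mu), length(mu) == 1L, mu >= 0,
            is.numeric(phi), length(phi) == 1L, phi > 0,
            is.numeric(m0_bar), length(m0_bar) == 1L, m0_bar > 0,
            is.numeric(xi_obs), length(xi_obs) == 1L)
  structure(list(mu = mu, phi = phi, m0_bar = m0_bar, xi_obs = xi_obs),
            class = "release_model_params")
}

# d rho_bar / d eta at fixed xi, closed form. With A = 1 + mu^2 eta^2:
#   d/deta [A^{-1/2} e^{-E}] = rho_bar * (-mu^2 eta / A - dE/deta),
#   dE/deta = -2(xi-eta)/(phi^2 A) - 2 mu^2 eta (xi-eta)^2 / (phi^2 A^2).
density_field_deta <- function(mu, phi, xi, eta) {
  a <- 1 + mu^2 * eta^2
  rho <- density_field(mu, phi, xi, eta)
  de <- -2 * (xi - eta) / (phi^2 * a) - 2 * mu^2 * eta * (xi - eta)^2 / (phi^2 * a^2)
  rho * (-mu^2 * eta / a - de)
}

#' Nondimensional mass-release rate
#'
#' The release law states that the released mass grows as the local state
#' density is depleted: \eqn{d\bar M/d\eta = -\bar m_0 \,
#' \partial\bar\rho(\mu,\phi,\xi_{obs},\eta)/\partial\eta}, evaluated with
#' the closed-form derivative of the density field at the fixed observation
#' coordinate `xi_obs`. For `xi_obs = 0` the rate is nonnegative for all
#' `eta >= 0` and vanishes at `eta = 0`.
#'
#' @param p a [release_model_params()] object.
#' @param eta nondimensional time, >= 0 (vectorized).
#' @return Dimensionless release rate values.
#' @export
#' @examples
#' p <- release_model_params(mu = 0, phi = 1, m0_bar = 1)
#' mass_release_rate(p, 1)  # 2 * exp(-1)
mass_release_rate <- function(p, eta) {
  stopifnot(inherits(p, "release_model_params"), is.numeric(eta))
  if (any(eta < 0)) stop("'eta' must be >= 0")
  -p$m0_bar * density_field_deta(p$mu, p$phi, p$xi_obs, eta)
}

#' Nondimensional cumulative release
#'
#' Antiderivative of the mass-release law with the release-fraction
#' convention: the cumulative released mass is the relative depletion of the
#' local density,
#' \deqn{\bar M(\eta) = \bar m_0\,
#'   \frac{\bar\rho(\xi_{obs},0) - \bar\rho(\xi_{obs},\eta)}{\bar\rho(\xi_{obs},0)},}
#' so that \eqn{\bar M(0) = 0}, \eqn{\bar M} is nondecreasing for
#' `xi_obs = 0`, and \eqn{\bar M \to \bar m_0} as \eqn{\eta\to\infty}:
#' `m0_bar` is directly the asymptotic released fraction.
#'
#' @param p a [release_model_params()] object.
#' @param eta nondimensional time, >= 0 (vectorized).
#' @return Dimensionless cumulative released mass values in [0, m0_bar).
#' @export
#' @examples
#' p <- release_model_params(mu = 0, phi = 1, m0_bar = 1)
#' cumulative_release(p, 1)  # 1 - exp(-1)
cumulative_release <- function(p, eta) {
  stopifnot(inherits(p, "release_model_params"), is.numeric(eta))
  if (any(eta < 0)) stop("'eta' must be >= 0")
  rho0 <- density_field(p$mu, p$phi, p$xi_obs, 0)
  p$m0_bar * (rho0 - density_field(p$mu, p$phi, p$xi_obs, eta)) / rho0
}
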