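test_that("nondimensional velocity satisfies initial and comoving conditions", {
  for (mu in c(0, 0.7, 2)) {
    for (eta in c(0, 0.5, 1, 7)) {
      expect_equal(velocity_field(mu, xi = eta, eta = eta), 1)
    }
    expect_equal(velocity_field(mu, xi = 3, eta = 0), 1)
  }
  expect_equal(velocity_field(1, xi = 2, eta = 1), 1.5)
})

test_that("nondimensional density has unit peak and the stated closed form", {
  expect_equal(density_field(0.3, 0.8, xi = 0, eta = 0), 1)
  expect_equal(density_field(0, 1, xi = 2, eta = 1), exp(-1))
  # comoving point xi = eta: only the spreading prefactor remains
  expect_equal(density_field(1, 1, xi = 2, eta = 2), 1 / sqrt(5))
  expect_error(density_field(1, 0, 0, 0), "phi")
  expect_error(density_field(1, 1, 0, -1), "eta")
})

test_that("dimensional density is normalized and matches its initial condition", {
  expect_equal(dimensional_density(0, 0, hydro_params(1, 1, 1, 1)),
               pi^(-1 / 2))
  h <- hydro_params(v0 = 1, alpha = 1, sigma = 1, tau0 = 1)
  expect_equal(
    dimensional_density(5 * h$v0, 5, h),
    pi^(-1 / 2) * (h$alpha^2 + (h$sigma / h$alpha)^2 * 25)^(-1 / 2))
  # mass conservation across a parameter grid and times (split the
  # integral at the moving peak so quadrature never misses the pulse)
  for (v0 in c(0.5, 1)) for (alpha in c(0.7, 1.3)) for (sigma in c(0, 0.4, 1)) {
    h <- hydro_params(v0, alpha, sigma, 1)
    for (t in c(0, 1, 5, 20)) {
      f <- function(x) dimensional_density(x, t, h)
      q <- stats::integrate(f, -Inf, v0 * t, rel.tol = 1e-10)$value +
        stats::integrate(f, v0 * t, Inf, rel.tol = 1e-10)$value
      expect_equal(q, 1, tolerance = 1e-8)
    }
  }
  # vanishing tails
  h <- hydro_params(1, 1, 0.5, 1)
  expect_lt(dimensional_density(1e3, 2, h), 1e-300)
})

test_that("dimensional velocity matches boundary conditions and nondimensional form", {
  h <- hydro_params(v0 = 1.3, alpha = 0.9, sigma = 0.6, tau0 = 2)
  xs <- seq(-4, 8, length.out = 10)
  expect_equal(dimensional_velocity(xs, 0, h), rep(h$v0, 10))
  ts <- seq(0, 10, length.out = 10)
  expect_equal(dimensional_velocity(h$v0 * ts, ts, h), rep(h$v0, 10))
  # consistency with the nondimensional field on a 10 x 10 grid
  nd <- nondimensionalize(h)
  for (x in xs) for (t in ts) {
    co <- mfrelease:::nondim_coords(x, t, h)
    expect_equal(dimensional_velocity(x, t, h),
                 h$v0 * velocity_field(nd$mu, co$xi, co$eta),
                 tolerance = 1e-12)
  }
})

test_that("dimensional and nondimensional densities agree through the scaling", {
  h <- hydro_params(v0 = 1.3, alpha = 0.9, sigma = 0.6, tau0 = 2)
  nd <- nondimensionalize(h)
  for (x in c(-2, 0, 1, 5)) for (t in c(0, 0.7, 3, 9)) {
    co <- mfrelease:::nondim_coords(x, t, h)
    expect_equal(sqrt(pi) * h$alpha * dimensional_density(x, t, h),
                 density_field(nd$mu, nd$phi, co$xi, co$eta),
                 tolerance = 1e-12)
  }
})

test_that("mu = 0 degenerates to a rigidly translating Gaussian", {
  h <- hydro_params(v0 = 2, alpha = 1.1, sigma = 0, tau0 = 1)
  xs <- seq(-3, 3, by = 0.5)
  rho0 <- dimensional_density(xs, 0, h)
  for (t in c(1, 4, 15)) {
    expect_equal(dimensional_density(xs + h$v0 * t, t, h), rho0,
                 tolerance = 1e-14)
    expect_equal(dimensional_velocity(xs, t, h), rep(h$v0, length(xs)))
  }
})

test_that("mass-release rate matches the analytic derivative of the density", {
  p <- release_model_params(mu = 0, phi = 1, m0_bar = 1)
  expect_equal(mass_release_rate(p, 0), 0)
  expect_equal(mass_release_rate(p, 1), 2 * exp(-1))
  # against a centered difference of the density field on an eta grid
  for (mu in c(0, 0.5, 2)) {
    p <- release_model_params(mu = mu, phi = 0.8, m0_bar = 0.7, xi_obs = 0.3)
    etas <- seq(0.01, 5, length.out = 40)
    hh <- 1e-6
    fd <- -(p$m0_bar) *
      (density_field(mu, p$phi, p$xi_obs, etas + hh) -
       density_field(mu, p$phi, p$xi_obs, etas - hh)) / (2 * hh)
    expect_equal(mass_release_rate(p, etas), fd, tolerance = 1e-6)
  }
})

test_that("cumulative release starts at zero, saturates at m0_bar, and is monotone", {
  p <- release_model_params(mu = 0, phi = 1, m0_bar = 1)
  expect_equal(cumulative_release(p, 0), 0)
  expect_equal(cumulative_release(p, 1), 1 - exp(-1))
  p2 <- release_model_params(mu = 1, phi = 1, m0_bar = 1)
  expect_equal(cumulative_release(p2, 1e6), 1, tolerance = 1e-5)
  for (mu in c(0, 0.3, 2)) {
    p <- release_model_params(mu = mu, phi = 1.2, m0_bar = 0.9)
    m <- cumulative_release(p, seq(0, 50, length.out = 400))
    expect_true(all(diff(m) >= -1e-14))
    expect_true(all(m <= p$m0_bar + 1e-12))
  }
})

test_that("cumulative release differentiates back to the mass-release rate", {
  for (mu in c(0, 0.8)) {
    p <- release_model_params(mu = mu, phi = 1, m0_bar = 0.6, xi_obs = 0.2)
    rho0 <- density_field(p$mu, p$phi, p$xi_obs, 0)
    etas <- seq(0.1, 4, length.out = 25)
    hh <- 1e-7
    dnum <- (cumulative_release(p, etas + hh) -
             cumulative_release(p, etas - hh)) / (2 * hh)
    expect_equal(dnum, mass_release_rate(p, etas) / rho0, tolerance = 1e-8)
  }
})
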