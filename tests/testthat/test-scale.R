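test_that("scale-fractality relation evaluates its closed form", {
  # zero coefficient and vanishing exponent
  expect_equal(sigma_from_scale(0, 0.1, 2), 0)
  expect_equal(sigma_from_scale(3, 0.1, 2), 3)
  # exponent (2/1) - 1 = 1
  expect_equal(sigma_from_scale(1, 0.1, 1), 0.1)
  expect_error(sigma_from_scale(-1, 0.1, 1), "lam")
  expect_error(sigma_from_scale(1, 0, 1), "dt")
  expect_error(sigma_from_scale(1, 0.1, 0), "f_alpha")
})

test_that("fractality inversion round-trips across fractal dimensions", {
  expect_equal(fractality_from_sigma(3, 3, 0.1), 2)
  expect_equal(fractality_from_sigma(0.1, 1, 0.1), 1)
  for (f in c(0.5, 1, 1.5, 2, 3)) {
    for (lam in c(0.5, 1, 2)) {
      for (dt in c(0.05, 0.1, 0.5)) {
        sig <- sigma_from_scale(lam, dt, f)
        expect_equal(fractality_from_sigma(sig, lam, dt), f, tolerance = 1e-10)
      }
    }
  }
})

test_that("fractality inversion rejects unidentifiable or out-of-domain input", {
  expect_error(fractality_from_sigma(1, 1, 1), "unidentifiable")
  expect_error(fractality_from_sigma(0, 1, 0.1), "sigma")
  expect_error(fractality_from_sigma(-2, 1, 0.1), "sigma")
  # implied f(alpha) <= 0: sigma/lam on the wrong side of the dt^(-1) pole
  expect_error(fractality_from_sigma(100, 1, 0.1), "positive")
})

test_that("nondimensionalization maps parameters and coordinates invertibly", {
  expect_equal(nondimensionalize(hydro_params(1, 1, 0, 1)),
               list(mu = 0, phi = 1))
  expect_equal(nondimensionalize(hydro_params(2, 1, 1, 1)),
               list(mu = 1, phi = 0.5))
  expect_equal(nondimensionalize(hydro_params(1, 2, 2, 1)),
               list(mu = 0.5, phi = 2))
  expect_error(nondimensionalize(hydro_params(0, 1, 1, 1)), "v0")

  h <- hydro_params(v0 = 1.7, alpha = 0.8, sigma = 0.3, tau0 = 2.5)
  x <- c(-3, 0, 4.2); t <- c(0, 1.1, 9)
  nd <- mfrelease:::nondim_coords(x, t, h)
  back <- mfrelease:::nondim_coords_inv(nd$xi, nd$eta, h)
  expect_equal(back$x, x, tolerance = 1e-15)
  expect_equal(back$t, t, tolerance = 1e-15)
})
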