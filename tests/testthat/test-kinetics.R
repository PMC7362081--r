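test_that("linearization produces the models' straight-line coordinates", {
  lin <- linearize_release("higuchi", c(4, 9, 16), c(0.2, 0.3, 0.4))
  expect_equal(lin$x, c(2, 3, 4))
  expect_equal(lin$y, c(0.2, 0.3, 0.4))
  # Hixson-Crowell at zero release: W0^(1/3) - W0^(1/3) = 0
  lin <- linearize_release("hixson_crowell", c(0, 1, 2), c(0, 0.1, 0.2))
  expect_equal(lin$y[1], 0)
  lin <- linearize_release("korsmeyer_peppas", c(10, 20, 40), c(0.1, 0.2, 0.4))
  expect_equal(lin$x[1], 1)
  expect_equal(lin$y[1], -1)
})

test_that("linearization drops unusable points and enforces a minimum count", {
  # Korsmeyer-Peppas validity window drops fractions above 0.6
  lin <- linearize_release("korsmeyer_peppas", 1:5, c(0.2, 0.4, 0.5, 0.7, 0.9))
  expect_equal(lin$n_dropped, 2)
  expect_equal(sum(lin$kept), 3)
  expect_error(linearize_release("korsmeyer_peppas", 1:4,
                                 c(0.2, 0.65, 0.7, 0.9)),
               "fewer than 3")
  # first-order (printed form) needs positive fractions
  lin <- linearize_release("first_order", 0:3, c(0, 0.1, 0.2, 0.3))
  expect_equal(lin$n_dropped, 1)
})

test_that("each model exactly recovers its own generating constants", {
  t <- c(1, 2, 4, 6, 9, 12, 16)

  fit <- fit_kinetic_model(t, 0.05 * t, "zero_order")
  expect_equal(unname(coef(fit)["k0"]), 0.05, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)

  fit <- fit_kinetic_model(t, 0.1 * sqrt(t), "higuchi")
  expect_equal(unname(coef(fit)["kH"]), 0.1, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)

  fit <- fit_kinetic_model(t, 0.08 * t^0.45, "korsmeyer_peppas")
  expect_equal(unname(coef(fit)["K"]), 0.08, tolerance = 1e-9)
  expect_equal(unname(coef(fit)["n"]), 0.45, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)

  # printed first-order form: log10 Q = (k/2.303) t
  k <- 0.04
  fit <- fit_kinetic_model(t, 10^(k * t / 2.303 - 1), "first_order")
  expect_equal(unname(coef(fit)["k"]), k, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)

  # Hixson-Crowell: 1 - (1 - Q)^(1/3) = k t
  k <- 0.02
  fit <- fit_kinetic_model(t, 1 - (1 - k * t)^3, "hixson_crowell")
  expect_equal(unname(coef(fit)["k_hc"]), k, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
})

test_that("prediction round-trips the fit on noise-free generated data", {
  t <- c(1, 2, 4, 8, 12)
  gens <- list(
    zero_order = function(t) 0.03 * t,
    first_order = function(t) 10^(0.02 * t - 1),
    higuchi = function(t) 0.12 * sqrt(t),
    korsmeyer_peppas = function(t) 0.07 * t^0.6,
    hixson_crowell = function(t) 1 - (1 - 0.015 * t)^3)
  for (model in names(gens)) {
    q <- gens[[model]](t)
    fit <- fit_kinetic_model(t, q, model)
    expect_equal(predict(fit, t), q, tolerance = 1e-9)
    expect_equal(predict_kinetic(fit, t), predict(fit, t))
  }
})

test_that("conventional first-order variant regresses the remaining amount", {
  t <- 1:8
  k <- 0.05
  q <- 1 - 10^(-k * t / 2.303)   # remaining = 10^(-kt/2.303)
  fit <- fit_kinetic_model(t, q, "first_order", first_order = "remaining")
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(predict(fit, t), q, tolerance = 1e-9)
})

test_that("independent noise does not improve the linear fit", {
  t <- c(1, 2, 4, 6, 9, 12, 16, 20, 25)
  q <- 0.02 * t
  r2_clean <- fit_kinetic_model(t, q, "zero_order")$r_squared
  violations <- 0
  for (s in 1:20) {
    set.seed(s)
    qn <- pmax(1e-6, q + stats::rnorm(length(q), 0, 0.01))
    r2 <- fit_kinetic_model(t, qn, "zero_order")$r_squared
    if (r2 > r2_clean + 1e-12) violations <- violations + 1
  }
  expect_lte(violations, 1)
})

test_that("degenerate abscissa is rejected", {
  expect_error(fit_kinetic_model(c(2, 2, 2), c(0.1, 0.2, 0.3), "zero_order"),
               "degenerate")
})

test_that("stage-wise report grids five models by three stages", {
  cfg <- generator_config(noise_rel = 0)
  panel <- generate_panel(cfg, seed = 7)
  prof <- panel$profiles[panel$profiles$formulation == "2-U1", ]
  rep <- stagewise_model_report(prof)
  expect_equal(nrow(rep), 15)
  expect_setequal(unique(rep$model), kinetic_models())
  expect_setequal(unique(rep$stage), 1:3)
  # generator-known truths: the burst stage is first-order by construction,
  # the erosion tail is not zero-order
  expect_true(rep$adequate[rep$stage == 1 & rep$model == "first_order"])
  expect_false(rep$adequate[rep$stage == 3 & rep$model == "zero_order"])
})
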