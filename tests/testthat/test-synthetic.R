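test_that("printed urea percentages are reproduced exactly", {
  expect_identical(formulation_percent(141, 141), 50L)
  expect_identical(formulation_percent(70.5, 141), 33L)
  expect_identical(formulation_percent(65, 131), 33L)   # 33.16 rounds down
  expect_identical(formulation_percent(131, 131), 50L)
  # doubled-urea rows: exact 2/3 printed truncated, not rounded
  expect_identical(formulation_percent(282, 141), 66L)
  expect_identical(formulation_percent(262, 131), 66L)
  expect_identical(formulation_percent(0, 141), 0L)
  expect_error(formulation_percent(-1, 141), "urea_mg")
})

test_that("the composition table has eight internally consistent rows", {
  tab <- table1_formulations()
  expect_equal(nrow(tab), 8)
  expect_equal(tab$matrix_mg, tab$chitosan_mg + tab$sa_mg)
  expect_equal(tab$formulation_mg, tab$matrix_mg + tab$urea_mg)
  expect_equal(tab$formulation_mg[tab$code == "2-U2"], 393)
  expect_equal(sum(startsWith(tab$code, "1.5-U")), 4)
  expect_equal(sum(startsWith(tab$code, "2-U")), 4)
  expect_equal(tab$urea_percent, c(0L, 33L, 50L, 66L, 0L, 33L, 50L, 66L))
})

test_that("the true release curve hits its milestones exactly", {
  cfg <- generator_config()
  expect_equal(true_release_curve(0, cfg), 0)
  expect_identical(true_release_curve(cfg$t1, cfg), cfg$F1)
  expect_identical(true_release_curve(cfg$t2, cfg), cfg$F2)
  expect_identical(true_release_curve(cfg$t_final, cfg), cfg$F_final)
  expect_warning(out <- true_release_curve(900, cfg), "clamped")
  expect_equal(out, cfg$F_final)
})

test_that("the true release curve is continuous and nondecreasing", {
  cfg <- generator_config()
  for (mod in c(0.9, 1, 1.265)) {
    tt <- seq(0, 840, by = 0.25)
    f <- true_release_curve(tt, cfg, modifier = mod)
    expect_true(all(diff(f) >= -1e-12))
    expect_true(all(f >= 0 & f <= 1))
    # continuity at the stage boundaries (the stage-2 square root has an
    # infinite one-sided derivative, so the gap scales as sqrt(eps))
    eps <- 1e-12
    for (tb in c(cfg$t1, cfg$t2)) {
      expect_equal(true_release_curve(tb - eps, cfg, mod),
                   true_release_curve(tb + eps, cfg, mod),
                   tolerance = 1e-6)
    }
  }
})

test_that("formulation speed factors encode the observed release ordering", {
  cfg <- generator_config()
  tab <- table1_formulations()
  row <- function(code) tab[tab$code == code, ]
  # larger urea crystals and higher crosslinking release faster
  expect_gt(formulation_modifiers(row("1.5-U2"), cfg),
            formulation_modifiers(row("2-U0.5"), cfg))
  expect_equal(formulation_modifiers(row("2-U1"), cfg), 1.0)
  expect_true(is.na(formulation_modifiers(row("2-U0"), cfg)))
})

test_that("the sampling schedule matches the protocol", {
  sch <- sampling_schedule()
  expect_length(sch, 58)
  expect_equal(sch[1], 1)
  expect_equal(sch[length(sch)], 840)
  expect_true(all(diff(sch) > 0))
})

test_that("simulation is deterministic in the seed", {
  cfg <- generator_config()
  a <- simulate_sampling(cfg, seed = 11)
  b <- simulate_sampling(cfg, seed = 11)
  d <- simulate_sampling(cfg, seed = 12)
  expect_identical(a, b)
  expect_false(identical(a$conc_mg_per_ml, d$conc_mg_per_ml))
  # replicates carry distinct noise
  expect_false(identical(a$conc_mg_per_ml[a$replicate == "R1"],
                         a$conc_mg_per_ml[a$replicate == "R2"]))
  p1 <- generate_panel(cfg, seed = 5)
  p2 <- generate_panel(cfg, seed = 5)
  expect_identical(p1$profiles, p2$profiles)
})

test_that("measurement noise averages out of the corrected release", {
  cfg <- generator_config()  # 3% relative noise
  truth <- NULL
  devs <- vapply(1:50, function(s) {
    sim <- simulate_sampling(cfg, seed = s)
    truth <<- attr(sim, "true_cumulative_mg")
    rec <- vapply(unique(sim$replicate), function(r) {
      s_ <- sim[sim$replicate == r, ]
      correct_sampling(s_$conc_mg_per_ml, cfg$medium_ml, cfg$sample_ml)
    }, numeric(58))
    mean(abs(rowMeans(rec) - truth) / truth)
  }, 0)
  expect_lt(mean(devs), 0.01)
})

test_that("the default panel holds twelve urea-bearing profiles and a manifest", {
  cfg <- generator_config()
  panel <- generate_panel(cfg, seed = 2)
  combos <- unique(panel$profiles[, c("formulation", "replicate")])
  expect_equal(nrow(combos), 12)  # 6 formulations x 2 replicates
  expect_length(unique(combos$formulation), 6)
  expect_false(any(grepl("U0$", combos$formulation)))
  # manifest echoes the generating configuration exactly
  expect_identical(panel$manifest$config, unclass(cfg))
  expect_identical(panel$manifest$seed, 2)
  # and survives a JSON round-trip
  j <- jsonlite::toJSON(panel$manifest$config, auto_unbox = TRUE, digits = NA)
  back <- jsonlite::fromJSON(j, simplifyVector = FALSE)
  back$n_replicates <- as.integer(back$n_replicates)
  expect_equal(back, unclass(cfg))
})
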