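test_that("temperature polynomials evaluate the default regressions and clamp", {
  cfg <- default_config()
  # skin-tannin release constant at 20 C, evaluated by hand from the
  # quadratic coefficients
  expect_equal(
    as.numeric(eval_temperature_polynomial(
      cfg$kinetics$skin_tannin$release$coefficients, 20)),
    0.005564, tolerance = 1e-9)
  # unavailable anthocyanin at 35 C is negative (-0.84 mg/L) and clamps to 0
  expect_warning(
    v <- eval_temperature_polynomial(
      cfg$kinetics$anthocyanin$unavailable$coefficients, 35),
    "clamped")
  expect_equal(as.numeric(v), 0)
  expect_equal(attr(v, "raw"), -0.8415, tolerance = 1e-6)
  expect_true(attr(v, "clamped"))
  # zero polynomial is zero everywhere
  expect_equal(as.numeric(eval_temperature_polynomial(c(0, 0, 0), 27.3)), 0)
  expect_error(eval_temperature_polynomial(c(1, NA), 20), "finite")
  expect_error(eval_temperature_polynomial(c(1, 2), Inf), "finite")
})

test_that("rate polynomials stay non-negative across the calibrated range", {
  cfg <- default_config()
  grid <- seq(20, 35, by = 0.25)
  for (sp in c("anthocyanin", "skin_tannin", "seed_tannin")) {
    vals <- eval_temperature_polynomial(
      cfg$kinetics[[sp]]$release$coefficients, grid, warn = FALSE)
    expect_true(all(vals >= 0))
  }
})

test_that("Arrhenius law reproduces the disappearance rates and its properties", {
  # 35 C value matches the worked zero-order disappearance slope
  expect_equal(arrhenius_rate(1.38e18, 107300, 35), 0.89,
               tolerance = 0.005)
  # 20 C value from direct closed-form evaluation
  expect_equal(arrhenius_rate(1.38e18, 107300, 20), 0.1047238,
               tolerance = 1e-6)
  # zero barrier: rate equals the pre-exponential at every temperature
  expect_equal(arrhenius_rate(3.7, 0, c(-40, 0, 100)), rep(3.7, 3))
  expect_error(arrhenius_rate(-1, 10, 20), "non-negative")
  expect_error(arrhenius_rate(1, 10, -280), "absolute zero")

  # strictly increasing in T for positive Ea
  grid <- seq(15, 40, by = 1)
  expect_true(all(diff(arrhenius_rate(1e10, 5e4, grid)) > 0))

  # ln k is affine in 1/T(K): three points are collinear to 1e-10 relative
  Tc <- c(20, 28, 35)
  lnk <- log(arrhenius_rate(1.38e18, 107300, Tc))
  x <- 1 / (Tc + 273.15)
  slope12 <- (lnk[2] - lnk[1]) / (x[2] - x[1])
  slope13 <- (lnk[3] - lnk[1]) / (x[3] - x[1])
  expect_equal(slope12, slope13, tolerance = 1e-10)
})

test_that("params_at_conditions assembles the full bundle", {
  cfg <- default_config()
  p <- params_at_conditions(cfg, 20)
  kin <- p$kinetics
  expect_setequal(kin$species,
                  c("anthocyanin", "skin_tannin", "seed_tannin"))
  expect_equal(kin$k_G[kin$species == "anthocyanin"], 0.0096015,
               tolerance = 1e-9)
  expect_equal(kin$C_U[kin$species == "skin_tannin"], 577.04,
               tolerance = 1e-4)
  expect_equal(kin$alpha, c(1, 1, 0))
  expect_equal(kin$beta, c(0, 0, 0))
  expect_true(all(kin$C_U >= 0 & kin$C_U <= kin$C_G0))
  # switching the reaction off freezes the anthocyanin decline
  cfg0 <- cfg
  cfg0$kinetics$anthocyanin$reaction <- list(type = "arrhenius", A = 0, Ea = 0)
  p0 <- params_at_conditions(cfg0, 20)
  expect_equal(p0$kinetics$k_R, rep(0, 3))
  # missing row is a configuration error naming the species
  cfg_bad <- cfg
  cfg_bad$kinetics$skin_tannin$release <- NULL
  expect_error(params_at_conditions(cfg_bad, 20), "skin_tannin")
})

test_that("adsorption lookup interpolates bilinearly and flags extrapolation", {
  cfg <- default_config()
  ads_cfg <- cfg$adsorption
  # the default synthetic tables are separable-bilinear, so interpolation at
  # an interior point must reproduce the generating product form exactly
  a <- adsorption_at(ads_cfg, 27.5, 7.5)
  expect_equal(unname(a$K["anthocyanin"]),
               0.004 * (1 - 0.010 * 7.5) * (1 - 0.040 * 7.5),
               tolerance = 1e-12)
  expect_equal(unname(a$Q["skin_tannin"]),
               0.05 * 0.2 * 1000 * 30 * (1 - 0.005 * 7.5) * (1 - 0.020 * 7.5),
               tolerance = 1e-12)
  # grid nodes are reproduced exactly
  node <- adsorption_at(ads_cfg, 25, 5)
  expect_equal(unname(node$K["seed_tannin"]), ads_cfg$species$seed_tannin$K[2, 2])
  expect_warning(adsorption_at(ads_cfg, 40, 0), "outside")
  # clamped lookup equals the edge value
  edge <- suppressWarnings(adsorption_at(ads_cfg, 40, 0))
  expect_equal(edge$K, adsorption_at(ads_cfg, 35, 0)$K)
})

test_that("out-of-range temperatures warn and are flagged", {
  expect_warning(cond <- fermentation_conditions(50), "extrapolated")
  expect_true(cond$extrapolated)
  expect_silent(cond2 <- fermentation_conditions(25, ethanol = 0))
  expect_false(cond2$extrapolated)
})

test_that("Fickian flux and the seed-ablation demonstration", {
  expect_equal(fickian_flux(1, 1, 10), 10)
  expect_equal(fickian_flux(1, 0.5, 5), 10)
  expect_error(fickian_flux(1, 0, 5), "path length")
  # shrinking the path in proportion to the driving force keeps flux constant
  tt <- seq(0, 100, by = 1)
  dC <- 80 * exp(-0.03 * tt) + 5 * cos(tt / 7)^2 + 1  # arbitrary positive decay
  demo <- ablation_flux_demo(tt, dC, D = 2, L0 = 0.4)
  expect_lt(max(abs(demo$flux - demo$flux[1])) / abs(demo$flux[1]), 1e-12)
  expect_error(ablation_flux_demo(tt, dC - 100), "positive")
})
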