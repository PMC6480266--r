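test_that("release fitter recovers exact exponential gaps on any grid", {
  grids <- list(seq(0, 240, by = 1), seq(0, 240, by = 24),
                c(0, 5, 11, 26, 50, 90, 180), seq(0, 100, length.out = 6))
  for (tt in grids) {
    gap <- 379.4 * exp(-0.006 * tt)
    fit <- fit_release_first_order(tt, gap, window = NULL, is_gap = TRUE)
    expect_equal(unname(fit$estimate["k"]), 0.006, tolerance = 1e-6)
    expect_equal(unname(fit$estimate["A"]), 379.4, tolerance = 1e-6)
  }
  # second worked pair
  tt <- seq(0, 240, by = 12)
  fit2 <- fit_release_first_order(tt, 492.5 * exp(-0.01 * tt),
                                  window = NULL, is_gap = TRUE)
  expect_equal(unname(fit2$estimate["k"]), 0.01, tolerance = 1e-6)
  expect_equal(unname(fit2$estimate["A"]), 492.5, tolerance = 1e-6)
})

test_that("release fitter computes the gap from a rising series", {
  tt <- seq(0, 400, by = 8)
  conc <- 300 * (1 - exp(-0.02 * tt))
  fit <- fit_release_first_order(tt, conc)
  # the observed peak (not the asymptote) defines the gap, so the decay
  # constant is recovered while the amplitude is peak-relative
  expect_equal(unname(fit$estimate["k"]), 0.02, tolerance = 0.01)
  expect_match(fit$note, "2\\*k_G")
})

test_that("release fitter rejects degenerate input", {
  tt <- seq(0, 100, by = 10)
  expect_error(fit_release_first_order(tt, rep(5, length(tt))),
               "positive gap")
})

test_that("zero-order slope fits report magnitude and sign", {
  tt <- seq(100, 336, by = 12)
  fit <- fit_zero_order_slope(tt, 500 - 0.89 * tt)
  expect_equal(unname(fit$estimate["rate"]), 0.89, tolerance = 1e-9)
  expect_equal(fit$sign, -1)
  fit_up <- fit_zero_order_slope(tt, 0.4057 * tt)
  expect_equal(unname(fit_up$estimate["rate"]), 0.4057, tolerance = 1e-9)
  expect_equal(fit_up$sign, 1)
  flat <- fit_zero_order_slope(tt, rep(42, length(tt)))
  expect_equal(unname(flat$estimate["rate"]), 0)
  expect_error(fit_zero_order_slope(c(0, 1), c(0, 1)), "at least 3")
})

test_that("windows resolve by the peak rules", {
  tt <- seq(0, 200, by = 10)
  conc <- 100 * (1 - exp(-0.03 * tt))
  early <- resolve_window(fit_window("early"), tt, conc)
  late <- resolve_window(fit_window("late"), tt, conc)
  # early stops once 90% of the peak is reached; late starts at the peak
  expect_true(all(which(early) <= which.max(conc)))
  expect_true(min(tt[late]) == tt[which.max(conc)])
  expect_equal(sum(resolve_window(c(50, 100), tt, conc)), 6)
})

test_that("Arrhenius regression inverts the rate law", {
  Tc <- c(20, 25, 30, 35)
  k <- arrhenius_rate(1.38e18, 107300, Tc)
  fit <- fit_arrhenius(Tc, k)
  expect_equal(unname(fit$estimate["Ea"]), 107300, tolerance = 1e-6)
  expect_equal(unname(fit$estimate["A"]), 1.38e18, tolerance = 1e-6)
  # flat rates give zero activation energy
  flat <- fit_arrhenius(Tc, rep(0.5, 4))
  expect_equal(unname(flat$estimate["Ea"]), 0, tolerance = 1e-8)
  expect_error(fit_arrhenius(c(20, 20, 20), c(1, 2, 3)), "distinct")
  expect_error(fit_arrhenius(Tc, c(1, -1, 1, 1)), "positive")
})

test_that("temperature polynomial regression recovers exact coefficients", {
  cfg <- default_config()
  coefs <- cfg$kinetics$skin_tannin$release$coefficients
  Tc <- c(20, 25, 30, 35)
  vals <- vapply(Tc, function(T) sum(coefs * T^(0:2)), numeric(1))
  fit <- fit_temperature_polynomial(Tc, vals, degree = 2)
  expect_equal(unname(fit$estimate), coefs, tolerance = 1e-6)
  # a line is recovered exactly at degree 1
  lin <- fit_temperature_polynomial(Tc, 1080.7055 - 25.1835 * Tc, degree = 1)
  expect_equal(unname(lin$estimate), c(1080.7055, -25.1835),
               tolerance = 1e-9)
  # constant data: higher-order coefficients vanish
  const <- fit_temperature_polynomial(Tc, rep(7, 4), degree = 2)
  expect_lt(max(abs(const$estimate[2:3])), 1e-10)
  expect_error(fit_temperature_polynomial(c(20, 25), rep(1, 2), degree = 2),
               "rank")
})

test_that("estimates rescale consistently with the time unit", {
  tt_h <- seq(0, 240, by = 12)
  gap <- 300 * exp(-0.012 * tt_h)
  fit_h <- fit_release_first_order(tt_h, gap, window = NULL, is_gap = TRUE)
  fit_d <- fit_release_first_order(tt_h / 24, gap, window = NULL,
                                   is_gap = TRUE)
  expect_equal(unname(fit_d$estimate["k"]), 24 * unname(fit_h$estimate["k"]),
               tolerance = 1e-6)
  expect_equal(unname(fit_d$estimate["A"]), unname(fit_h$estimate["A"]),
               tolerance = 1e-6)
  # zero-order rates scale inversely with the time unit too
  lin_h <- fit_zero_order_slope(tt_h, 500 - 0.89 * tt_h)
  lin_d <- fit_zero_order_slope(tt_h / 24, 500 - 0.89 * tt_h)
  expect_equal(unname(lin_d$estimate["rate"]),
               24 * unname(lin_h$estimate["rate"]), tolerance = 1e-9)
})

test_that("goodness of fit scores models against data", {
  traj <- simulate_fermentation(times = seq(0, 336, by = 12))
  ds <- generate_dataset(temperature_C = 20, noise = noise_model("none"),
                         trajectory = traj)
  r2 <- goodness_of_fit(traj, ds)
  expect_equal(unname(r2), rep(1, 3), tolerance = 1e-9)
  # a flat (zero-release) model against varying data scores at or below zero
  cfg0 <- no_adsorption_config(k_G = 0, A0 = 1)
  flat <- simulate_fermentation(cfg0, fermentation_conditions(20, ethanol = 0),
                                seq(0, 336, by = 12))
  r2_flat <- goodness_of_fit(flat, ds)
  expect_true(all(r2_flat <= 0))
  # zero-variance data are reported as undefined
  const_ds <- data.frame(time_h = c(0, 12, 24), species = "anthocyanin",
                         concentration_mg_L = c(5, 5, 5))
  expect_true(is.na(goodness_of_fit(traj, const_ds)[["anthocyanin"]]))
})

test_that("noisy goodness of fit stays high at 5% noise", {
  traj <- simulate_fermentation(times = seq(0, 336, by = 12))
  ds <- generate_dataset(temperature_C = 20,
                         noise = noise_model(sigma = 0.05, seed = 11),
                         trajectory = traj)
  r2 <- goodness_of_fit(traj, ds)
  expect_true(all(r2 > 0.9))
})
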