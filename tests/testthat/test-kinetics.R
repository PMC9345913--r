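test_that("moisture content and moisture ratio follow their definitions", {
  expect_equal(moisture_content(2, 1), 100)
  expect_equal(moisture_content(1, 1), 0)
  # invert Mc = 100 (Ww - Dw)/Dw for the 11%-class initial moisture regime
  expect_equal(moisture_content(3.10, 2.7927), 100 * (3.10 - 2.7927) / 2.7927)
  expect_error(moisture_content(1, 0), "positive")

  expect_equal(moisture_ratio(10, 10, 0), 1)
  expect_equal(moisture_ratio(0, 10, 0), 0)
  expect_equal(moisture_ratio(5, 10, 0), 0.5)
  expect_equal(moisture_ratio(3, 5, 1), 0.5)
  expect_error(moisture_ratio(5, 10, 10), "degenerate")
})

test_that("drying_curve validates its invariants", {
  expect_s3_class(drying_curve(c(0, 10, 20), c(1, 0.8, 0.6)), "drying_curve")
  expect_error(drying_curve(c(10, 20), c(1, 0.8)), "increasing")
  expect_error(drying_curve(c(0, 10, 5), c(1, 0.8, 0.6)), "increasing")
  expect_error(drying_curve(c(0, 10), c(0.5, 0.4)), "first moisture ratio")
  expect_error(drying_curve(c(0, 10), c(1, 0.5), radius_m = 0), "positive")
  expect_warning(drying_curve(c(0, 10, 20), c(1, 1.2, 0.5)), "outside")
})

test_that("ln-MR regression recovers a generating line exactly", {
  # coefficients of the unblanched 60 C published fit
  t <- seq(0, 500, by = 50)
  mr <- exp(0.162015 - 0.000205 * t)
  cur <- suppressWarnings(drying_curve(t, mr, tol = 0.2))
  fit <- fit_ln_mr(cur)
  expect_equal(fit$slope, -0.000205, tolerance = 1e-10)
  expect_equal(fit$intercept, 0.162015, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$n_points, 11L)

  two <- drying_curve(c(0, 100), c(1, exp(-1)))
  expect_equal(fit_ln_mr(two)$slope, -0.01, tolerance = 1e-12)
})

test_that("ln-MR regression window and degenerate cases behave", {
  cur <- drying_curve(c(0, 10, 20, 30), c(1, 0.5, 0.005, 0.001))
  expect_message(fit <- fit_ln_mr(cur, min_mr = 0.01), "excluding 2")
  expect_equal(fit$n_points, 2L)
  flat <- drying_curve(c(0, 10, 20), c(1, 1, 1))
  expect_equal(fit_ln_mr(flat)$slope, 0)
  steep <- drying_curve(c(0, 10), c(1, 0.001))
  expect_error(suppressMessages(fit_ln_mr(steep)), "insufficient")
  # max_mr restricts to the late-time points
  win <- suppressMessages(fit_ln_mr(cur, min_mr = 1e-4, max_mr = 0.6))
  expect_equal(win$n_points, 3L)
})

test_that("slope-to-diffusivity conversion respects units and physics", {
  d <- deff_from_slope(-0.000205, radius_m = 0.02, mode = "table")
  expect_equal(d$deff, 0.000205 * 0.02^2 / pi^2)
  expect_true(d$physical)
  # si mode divides the per-minute slope by 60, exactly
  dsi <- deff_from_slope(-0.000205, radius_m = 0.02, mode = "si")
  expect_identical(dsi$deff, d$deff / 60)
  expect_equal(deff_from_slope(0, 0.02)$deff, 0)
  expect_warning(dz <- deff_from_slope(0.001, 0.02), "non-physical")
  expect_equal(dz$deff, 0)
  expect_false(dz$physical)
})

test_that("diffusivity is monotone in slope magnitude and radius", {
  set.seed(11)
  for (i in 1:25) {
    s <- -runif(1, 1e-5, 1e-3); r <- runif(1, 0.005, 0.05)
    d0 <- deff_from_slope(s, r)$deff
    expect_gt(deff_from_slope(s * 1.5, r)$deff, d0)
    expect_gt(deff_from_slope(s, r * 1.2)$deff, d0)
  }
})

test_that("Arrhenius fit matches closed-form inversion and is unit invariant", {
  # synthesize diffusivities from known Ea and D0
  ea <- 35; d0 <- 1e-4
  temps <- c(50, 60, 70)
  deff <- d0 * exp(-ea * 1000 / (8.314 * (temps + 273.15)))
  fit <- arrhenius_fit(stats::setNames(deff, temps))
  expect_equal(fit$ea_kj_per_mol, 35, tolerance = 1e-10)
  expect_equal(fit$d0, 1e-4, tolerance = 1e-8)
  # unit invariance: rescaling diffusivities leaves Ea unchanged
  fit2 <- arrhenius_fit(stats::setNames(deff * 60, temps))
  expect_equal(fit2$ea_kj_per_mol, fit$ea_kj_per_mol, tolerance = 1e-12)
  # equal diffusivities: zero activation energy
  flat <- arrhenius_fit(c("50" = 1e-8, "60" = 1e-8, "70" = 1e-8))
  expect_equal(flat$ea_kj_per_mol, 0, tolerance = 1e-12)
  expect_error(arrhenius_fit(c("50" = -1e-9, "60" = 1e-9)), "positive")
  expect_error(arrhenius_fit(c("50" = 1e-9)), "distinct")
  expect_warning(arrhenius_fit(c("50" = 1e-9, "50" = 2e-9, "60" = 3e-9)),
                 "duplicate")
})

test_that("energy accounting is linear and guards its inputs", {
  expect_equal(total_energy(1, 1, 1, 1, 0, 1), 0)
  # power (kW) x hours = kWh: all-ones product is 1 kWh
  expect_equal(total_energy(1, 1, 1, 1, 1, 1), 1)
  et <- total_energy(0.078, 1.5, 1.09, 1.006, 20, 8.83)
  expect_equal(specific_energy(et, 1.0), et)
  expect_error(total_energy(-1, 1, 1, 1, 1, 1), "non-negative")
  expect_error(specific_energy(10, 0), "positive")
  # Es o Et linear in delta T and drying time
  base <- specific_energy(total_energy(0.1, 1.5, 1.1, 1, 10, 2), 0.2)
  expect_equal(specific_energy(total_energy(0.1, 1.5, 1.1, 1, 30, 2), 0.2),
               3 * base)
  expect_equal(specific_energy(total_energy(0.1, 1.5, 1.1, 1, 10, 6), 0.2),
               3 * base)
})

test_that("kinetics_report reproduces per-cell fits over a long dataset", {
  gen <- generate_drying_data(generator_config(noise_sd = 0))
  rep <- suppressMessages(kinetics_report(gen$data, mode = "si",
                                          max_mr = 0.2))
  expect_equal(nrow(rep$diffusivity), 12)
  expect_equal(nrow(rep$arrhenius), 4)
  expect_true(all(rep$diffusivity$deff > 0))
  expect_true(all(rep$diffusivity$r_squared > 0.99))
})
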