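test_that("surface-area allometry and hydration arithmetic", {
  expect_identical(surface_area(1), 9.9)
  expect_identical(surface_area(0), 0)
  expect_equal(surface_area(1.35), 9.9 * 1.35^0.56, tolerance = 1e-12)
  expect_equal(surface_area(1.35), 11.71, tolerance = 1e-3)
  expect_error(surface_area(-1), "non-negative")
  expect_equal(hydration_fraction(1.215, 1.35), 0.9)
  expect_identical(hydration_fraction(1.35, 1.35), 1)
  expect_error(hydration_fraction(1, 0), "> 0")
})

test_that("flux rate arithmetic, antisymmetry and proportionality", {
  expect_identical(flux_rate(1, 1, 2, 1), 0)
  expect_equal(flux_rate(1.000, 0.9766, 2, 1.000), -23.4 / 9.9 / 2,
               tolerance = 1e-12)
  expect_equal(flux_rate(1.000, 0.9766, 2, 1.000), -1.182, tolerance = 1e-3)
  # antisymmetric in swapping start/end masses
  expect_equal(flux_rate(1.2, 0.9, 2, 1.3), -flux_rate(0.9, 1.2, 2, 1.3))
  # doubling duration halves flux
  expect_equal(flux_rate(1, 0.98, 4, 1), flux_rate(1, 0.98, 2, 1) / 2)
  expect_error(flux_rate(1, 1, 0, 1), "positive")
})

test_that("absorption threshold: bracketing interpolation on treatment means", {
  m <- data.frame(water_potential = rep(c(-40, -60), each = 3),
                  flux = c(0.4, 0.5, 0.6, -0.4, -0.5, -0.6))
  est <- estimate_absorption_threshold(m)
  expect_equal(est$threshold, -50)
  expect_equal(est$bracketing, c(-40, -60))
  # invariant to measurement order and to uniform flux rescaling
  m2 <- m[sample(nrow(m)), ]
  expect_equal(estimate_absorption_threshold(m2)$threshold, -50)
  m3 <- m; m3$flux <- m3$flux * 7.3
  expect_equal(estimate_absorption_threshold(m3)$threshold, -50)
  # excluded measurements are dropped
  m4 <- rbind(m, data.frame(water_potential = -40, flux = -50))
  m4$excluded <- c(rep(0, 6), 1)
  expect_equal(estimate_absorption_threshold(m4)$threshold, -50)
})

test_that("absorption threshold error modes", {
  pos <- data.frame(water_potential = c(-10, -40, -80), flux = c(1, 0.5, 0.2))
  expect_error(estimate_absorption_threshold(pos), "sign")
  one <- data.frame(water_potential = -10, flux = 1)
  expect_error(estimate_absorption_threshold(one), "at least 2")
  all_ex <- data.frame(water_potential = c(-10, -80), flux = c(1, -1),
                       excluded = c(1, 1))
  expect_error(estimate_absorption_threshold(all_ex), "excluded or empty")
})

test_that("isotonic method agrees with bracketing on monotone means", {
  fx <- gen_flux_data(noise_sd = 0, frog_sd = 0, seed = 1)
  b <- estimate_absorption_threshold(fx, method = "bracket")
  i <- estimate_absorption_threshold(fx, method = "isotonic")
  expect_equal(b$threshold, -50, tolerance = 1e-9)
  expect_equal(i$threshold, -50, tolerance = 1e-9)
})

test_that("threshold recovery over replicates is accurate and unbiased", {
  errs <- vapply(1:200, function(s) {
    fx <- gen_flux_data(noise_sd = 0.3, seed = s)
    estimate_absorption_threshold(fx)$threshold - (-50)
  }, numeric(1))
  expect_lt(median(abs(errs)), 5)
  expect_lt(abs(mean(errs)), 2)
})

test_that("dehydration rate across a hydration window", {
  # linear series losing 0.01 g/h
  frog <- list(standard_mass = 1.0,
               mass_series = data.frame(time_h = 0:15,
                                        mass_g = 1.0 - 0.01 * (0:15)))
  r <- dehydration_rate(frog)
  expect_equal(r$rate_g_h, 0.01, tolerance = 1e-12)
  expect_equal(r$rate_pct_h, 1, tolerance = 1e-12)
  expect_equal(r$t_from, 0)
  expect_equal(r$t_to, 10)
  # two-point series: slope of the two points
  frog2 <- list(standard_mass = 2.0,
                mass_series = data.frame(time_h = c(0, 4),
                                         mass_g = c(2.0, 1.8)))
  expect_equal(dehydration_rate(frog2)$rate_g_h, 0.05)
  # piecewise series: hand-computed interpolated window on a 5-point fixture
  frog3 <- list(standard_mass = 1.0,
                mass_series = data.frame(time_h = c(0, 1, 2, 3, 4),
                                         mass_g = c(1.0, 0.99, 0.95, 0.92, 0.88)))
  # crosses 0.90 between t=3 (0.92) and t=4 (0.88): t = 3 + 0.02/0.04 = 3.5
  r3 <- dehydration_rate(frog3)
  expect_equal(r3$t_to, 3.5)
  expect_equal(r3$rate_g_h, 0.1 / 3.5, tolerance = 1e-12)
  # rehydration mirrors with reversed bounds
  frog4 <- list(standard_mass = 1.0,
                mass_series = data.frame(time_h = 0:12,
                                         mass_g = 0.89 + 0.01 * (0:12)))
  r4 <- dehydration_rate(frog4, from_fraction = 0.89, to_fraction = 1.0)
  expect_equal(r4$rate_g_h, 0.01, tolerance = 1e-12)
  # window never reached
  frog5 <- list(standard_mass = 1.0,
                mass_series = data.frame(time_h = 0:3, mass_g = c(1, 0.99, 0.98, 0.97)))
  expect_error(dehydration_rate(frog5), "never reaches")
})
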