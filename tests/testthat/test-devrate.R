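test_that("rate curve peaks at b3 with value b1 and has unimodal shape", {
  p <- alba_params()
  expect_equal(dev_rate(p$b3, p), p$b1, tolerance = 1e-10)
  # far below the lower reference range the rate is negligible
  expect_lt(dev_rate(-40, p), 0.01 * p$b1)
  # unimodal with argmax at b3 on a fine grid, for several parameter sets
  set.seed(42)
  for (k in 1:5) {
    b3 <- runif(1, 18, 28)
    q <- rate_curve_params(runif(1, 1, 5), runif(1, 4, 12), b3,
                           runif(1, 2, 8), runif(1, 0.3, 0.6))
    grid <- seq(-5, 45, by = 0.01)
    r <- dev_rate(grid, q)
    expect_true(all(is.finite(r)) && all(r >= 0))
    expect_lt(abs(grid[which.max(r)] - b3), 0.011)
    # strictly decreasing above the optimum over the operational range
    # (down to where the rate has effectively reached zero)
    above <- grid[grid > b3 & grid < b3 + 2 * q$b2]
    ra <- dev_rate(above, q)
    oper <- ra > 1e-8 * q$b1
    expect_true(all(diff(ra[oper]) < 0))
  }
})

test_that("rate at 28 C matches independent hand evaluation of the formula", {
  p <- alba_params()
  u <- (28 - 23.33) / 8.94
  by_hand <- 3.02 * 2^(-u^2 * (1 + (4.9 * u)^(5 * 0.4)))
  expect_equal(dev_rate(28, p), by_hand, tolerance = 1e-12)
  expect_equal(by_hand, 0.7239265, tolerance = 1e-6)  # frozen arithmetic check
})

test_that("parameter and input validation errors fire", {
  expect_error(rate_curve_params(-1, 8, 23, 5), "b1")
  expect_error(rate_curve_params(3, 25, 23, 5), "b2 must be smaller")
  expect_error(dev_rate(NaN, alba_params()), "finite")
  expect_error(incubation_regime("x", "fluctuating", hourly_temps = numeric(0)),
               "non-empty")
  expect_error(incubation_regime("x", "constant", constant_temp = 80),
               "within -10..50")
})

test_that("constant-regime rate summation equals the closed form", {
  p <- alba_params()
  for (tc in seq(12, 27, by = 1.5)) {
    if (dev_rate(tc, p) < 0.1 * p$b1) next
    reg <- incubation_regime(paste0("c", tc), "constant", constant_temp = tc)
    d <- predict_duration(reg, p)
    expect_lt(abs(d - 100 / dev_rate(tc, p)) / d, 0.005)
  }
})

test_that("rate summation matches brute-force hourly accumulation", {
  p <- alba_params()
  # square wave: alternating hourly between two temperatures
  reg <- incubation_regime("sq", "fluctuating", hourly_temps = c(16, 24))
  d <- predict_duration(reg, p)
  mean_rate <- mean(dev_rate(c(16, 24), p))
  expect_equal(d, 100 / mean_rate, tolerance = 1e-3)
  # arbitrary piecewise regime vs an explicit loop oracle
  set.seed(7)
  temps <- runif(24, 12, 26)
  reg2 <- incubation_regime("pw", "fluctuating", hourly_temps = temps)
  d2 <- predict_duration(reg2, p)
  acc <- 0; hrs <- 0
  while (acc < 100) {
    hrs <- hrs + 1
    acc <- acc + dev_rate(temps[(hrs - 1) %% 24 + 1], p) / 24
  }
  expect_lt(abs(d2 * 24 - hrs), 1)  # within one step's development
})

test_that("regimes outside the viable range refuse to complete", {
  p <- alba_params()
  reg <- incubation_regime("hot", "constant", constant_temp = 45)
  expect_error(predict_duration(reg, p), "viable|complete")
})

test_that("noise-free fitting recovers the generating parameters", {
  p <- alba_params()
  dat <- gen_development_data(params = p, noise_sd = 0, seed = 1)
  fit <- fit_rate_curve(dat$observations, dat$regimes, fixed = c(b5 = 0.4),
                        n_starts = 2)
  for (k in c("b1", "b2", "b3", "b4"))
    expect_lt(abs(fit[[k]] - p[[k]]) / abs(p[[k]]), 1e-3)
  expect_identical(fit$b5, 0.4)  # fixed parameter honoured exactly
  expect_lt(fit$rss, 1e-6)
})

test_that("noisy refit recovers the thermal optimum within its SE scale", {
  p <- alba_params()
  dat <- gen_development_data(params = p, noise_sd = 1, seed = 1)
  fit <- fit_rate_curve(dat$observations, dat$regimes, fixed = c(b5 = 0.4))
  expect_lt(abs(fit$b3 - p$b3), 0.7)
  expect_true(all(c("b1", "b2", "b3", "b4") %in% names(fit$se)))
  expect_false("b5" %in% names(fit$se))
  # freeing b5 cannot worsen the fit (nested models)
  fit_free <- fit_rate_curve(dat$observations, dat$regimes, fixed = numeric(0),
                             init = fit, n_starts = 2)
  expect_lte(fit_free$rss, fit$rss * (1 + 1e-6))
})

test_that("fit input validation errors fire", {
  p <- alba_params()
  dat <- gen_development_data(params = p, noise_sd = 0, seed = 1)
  few <- dat$observations[1:3, ]
  expect_error(fit_rate_curve(few, dat$regimes, fixed = c(b5 = 0.4)),
               "at least")
  one_regime <- dat$observations[dat$observations$regime_id %in%
                                   c("const_15", "const_18"), ]
  expect_error(fit_rate_curve(one_regime, dat$regimes), "3 distinct regimes")
})

test_that("CT_max extrapolation rule behaves and is grid-convergent", {
  p <- alba_params()
  thr <- estimate_ctmax(p)
  expect_gt(thr$ct_max, thr$t_opt)
  expect_identical(thr$t_opt, p$b3)
  expect_identical(thr$ct_max_rule$epsilon, 0.01)
  # monotone non-increasing in epsilon
  eps <- c(0.002, 0.01, 0.05, 0.2)
  cts <- vapply(eps, function(e) estimate_ctmax(p, epsilon = e)$ct_max,
                numeric(1))
  expect_true(all(diff(cts) <= 0))
  # halving the grid step moves the estimate by less than one step
  c1 <- estimate_ctmax(p, grid_step = 0.01)$ct_max
  c2 <- estimate_ctmax(p, grid_step = 0.005)$ct_max
  expect_lt(abs(c1 - c2), 0.01)
})

test_that("warming tolerance and thermal safety margin are plain differences", {
  expect_identical(warming_tolerance(29.6, 29.6), 0)
  expect_equal(warming_tolerance(29.6, 23.2), 6.4)
  expect_equal(warming_tolerance(29.6, 30.0), -0.4)
  expect_identical(thermal_safety_margin(23.3, 23.3), 0)
  expect_equal(thermal_safety_margin(23.3, 18.0), 5.3)
  expect_equal(thermal_safety_margin(23.3, 25.0), -1.7)
  expect_error(warming_tolerance(NA_real_, 1), "finite")
})
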