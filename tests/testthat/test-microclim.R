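test_that("exceedance day counting follows the any-reading rule", {
  # constant wet series: no AT exceedance
  s <- daily_series(rep(-10, 20), rep(15, 20))
  sm <- summarize_site_year(s, at = -50, t_opt = 23.33, ct_max = 29.6,
                            year_start = 2019)
  expect_identical(sm$days_exceeding_at, 0L)
  expect_identical(sm$n_days_observed, 20L)
  # psi below threshold on days 3-5 only
  psi <- rep(-10, 10); psi[3:5] <- -60
  sm2 <- summarize_site_year(daily_series(psi, rep(15, 10)), at = -50,
                             t_opt = 23.33, ct_max = 29.6, year_start = 2019)
  expect_identical(sm2$days_exceeding_at, 3L)
  expect_equal(sm2$prop_at, 3 / 10)
  # ties at exactly the threshold do not count (strict <)
  sm3 <- summarize_site_year(daily_series(rep(-50, 5), rep(15, 5)), at = -50,
                             t_opt = 23.33, ct_max = 29.6, year_start = 2019)
  expect_identical(sm3$days_exceeding_at, 0L)
  # constant 30 C: every day exceeds ct_max and wt is negative
  sm4 <- summarize_site_year(daily_series(rep(-10, 7), rep(30, 7)), at = -50,
                             t_opt = 23.33, ct_max = 29.6, year_start = 2019)
  expect_identical(sm4$days_exceeding_ctmax, 7L)
  expect_equal(sm4$wt, -0.4)
  expect_equal(sm4$t_hab_max, 30)
})

test_that("window overlap, missing days and partial days behave", {
  s <- daily_series(rep(-10, 10), rep(15, 10), year_start = 2019)
  expect_error(summarize_site_year(s, -50, 23.33, 29.6, year_start = 2021),
               "overlap")
  # a day of all-NA readings drops out of the denominator
  psi <- rep(-10, 5 * 48); temp <- rep(15, 5 * 48)
  psi[49:96] <- NA; temp[49:96] <- NA           # day 2 empty
  t0 <- as.POSIXct("2019-07-01 00:00:00", tz = "UTC")
  s2 <- sensor_series("sB", "riparian", t0 + (seq_len(5 * 48) - 1) * 1800,
                      psi, temp)
  sm <- summarize_site_year(s2, -50, 23.33, 29.6, 2019)
  expect_identical(sm$n_days_observed, 4L)
  # partial day counts normally and a single breaching reading is enough
  psi2 <- rep(-10, 3 * 48); temp2 <- rep(15, 3 * 48)
  psi2[100] <- -70; psi2[120:144] <- NA
  s3 <- sensor_series("sC", "riparian", t0 + (seq_len(3 * 48) - 1) * 1800,
                      psi2, temp2)
  expect_identical(summarize_site_year(s3, -50, 23.33, 29.6, 2019)$days_exceeding_at, 1L)
})

test_that("splitting a series preserves summed exceedance counts", {
  set.seed(31)
  n_days <- 40
  psi <- -10^runif(n_days, 0.5, 2.3)
  temp <- runif(n_days, 12, 32)
  s <- daily_series(psi, temp)
  whole <- summarize_site_year(s, -50, 23.33, 29.6, 2019)
  split_at <- 17 * 48
  idx1 <- seq_len(split_at); idx2 <- (split_at + 1):(n_days * 48)
  part <- function(i) sensor_series("sA", "riparian", s$timestamps[i],
                                    s$psi[i], s$temp[i])
  p1 <- summarize_site_year(part(idx1), -50, 23.33, 29.6, 2019)
  p2 <- summarize_site_year(part(idx2), -50, 23.33, 29.6, 2019)
  for (f in c("days_exceeding_at", "days_exceeding_topt",
              "days_exceeding_ctmax", "n_days_observed"))
    expect_identical(whole[[f]], p1[[f]] + p2[[f]])
})

test_that("exceedance counts are monotone in thresholds and in data removal", {
  set.seed(32)
  psi <- -10^runif(30, 0.5, 2.3)
  temp <- runif(30, 12, 32)
  s <- daily_series(psi, temp)
  cnt <- function(at, topt) {
    sm <- summarize_site_year(s, at, topt, 45, 2019)
    c(sm$days_exceeding_at, sm$days_exceeding_topt)
  }
  # drier AT threshold -> fewer psi exceedances
  at_seq <- c(-20, -50, -80, -120)
  at_counts <- vapply(at_seq, function(a) cnt(a, 23.33)[1], numeric(1))
  expect_true(all(diff(at_counts) <= 0))
  # lowering a temperature threshold -> more exceedances
  topt_seq <- c(30, 25, 20, 15)
  t_counts <- vapply(topt_seq, function(tt) cnt(-50, tt)[2], numeric(1))
  expect_true(all(diff(t_counts) >= 0))
  # removing readings can never increase a count under the any-reading rule
  keep <- rep(TRUE, length(s$psi)); keep[sample(length(keep), 300)] <- FALSE
  s_sub <- sensor_series("sA", "riparian", s$timestamps[keep], s$psi[keep],
                         s$temp[keep])
  expect_lte(summarize_site_year(s_sub, -50, 23.33, 29.6, 2019)$days_exceeding_at,
             summarize_site_year(s, -50, 23.33, 29.6, 2019)$days_exceeding_at)
})

test_that("day-rule options order as expected", {
  # half of each day at -60, half at -10: 'any' breaches, daily mean (-35) not
  t0 <- as.POSIXct("2019-08-01 00:00:00", tz = "UTC")
  ts <- t0 + (seq_len(4 * 48) - 1) * 1800
  psi <- rep(c(rep(-60, 24), rep(-10, 24)), 4)
  s <- sensor_series("sD", "riparian", ts, psi, rep(15, length(ts)))
  any_rule <- summarize_site_year(s, -50, 23.33, 29.6, 2019, day_rule = "any")
  mean_rule <- summarize_site_year(s, -50, 23.33, 29.6, 2019,
                                   day_rule = "daily_mean")
  ext_rule <- summarize_site_year(s, -50, 23.33, 29.6, 2019,
                                  day_rule = "daily_extreme")
  expect_identical(any_rule$days_exceeding_at, 4L)
  expect_identical(ext_rule$days_exceeding_at, 4L)
  expect_identical(mean_rule$days_exceeding_at, 0L)
})

test_that("Spearman correlation on site pairs matches rank arithmetic", {
  # perfectly monotone decreasing -> rs = -1
  sy <- data.frame(site_id = paste0("s", 1:6),
                   days_exceeding_at = c(50, 40, 30, 20, 10, 0))
  pop <- population_estimate(paste0("s", 1:6), calling_males = 1:6)
  res <- exceedance_population_correlation(sy, pop)
  expect_equal(res$rs, -1)
  expect_equal(res$p_value, 0)
  # tie fixture: brute-force average-rank arithmetic
  days <- c(40, 40, 12, 7, 30, 5, 5, 18)
  size <- c(4, 10, 30, 44, 8, 44, 36, 20)
  sy2 <- data.frame(site_id = paste0("s", 1:8), days_exceeding_at = days)
  pop2 <- data.frame(site_id = paste0("s", 1:8), estimated_size = size)
  res2 <- exceedance_population_correlation(sy2, pop2)
  rx <- rank(days); ry <- rank(size)
  rs_hand <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(res2$rs, rs_hand, tolerance = 1e-12)
  t_hand <- rs_hand * sqrt(6 / (1 - rs_hand^2))
  expect_equal(res2$p_value, 2 * pt(-abs(t_hand), 6), tolerance = 1e-12)
  # cross-check against the independent implementation in stats
  ct <- suppressWarnings(cor.test(days, size, method = "spearman",
                                  exact = FALSE))
  expect_equal(res2$rs, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(res2$p_value, ct$p.value, tolerance = 1e-10)
  # order invariance
  perm <- c(3, 1, 5, 7, 2, 8, 4, 6)
  res3 <- exceedance_population_correlation(sy2[perm, ], pop2)
  expect_equal(res3$rs, res2$rs)
})

test_that("correlation input validation", {
  sy <- data.frame(site_id = paste0("s", 1:3), days_exceeding_at = 1:3)
  pop <- data.frame(site_id = paste0("s", 1:3), estimated_size = 3:1)
  expect_error(exceedance_population_correlation(sy, pop), "at least 4")
  sy4 <- data.frame(site_id = paste0("s", 1:4), days_exceeding_at = 1:4)
  pop_bad <- data.frame(site_id = c("s1", "s2", "s3", "zz"),
                        estimated_size = 1:4)
  expect_error(exceedance_population_correlation(sy4, pop_bad), "zz")
  expect_error(population_estimate("a", -1), "non-negative")
  expect_identical(population_estimate("a", 10)$estimated_size, 20L)
})

test_that("mean exceedance days averages across sites", {
  sy <- data.frame(site_id = c("a", "b", "c"),
                   days_exceeding_at = c(0, 10, 20),
                   days_exceeding_topt = c(1, 2, 3))
  expect_equal(mean_exceedance_days(sy), 10)
  expect_equal(mean_exceedance_days(sy, "days_exceeding_topt"), 2)
  expect_equal(mean_exceedance_days(sy[2, ]), 10)
  # 8-site fixture with a hand-computed mean
  counts <- c(40, 40, 12, 7, 30, 5, 5, 18)
  sy8 <- data.frame(site_id = paste0("s", 1:8), days_exceeding_at = counts)
  expect_equal(mean_exceedance_days(sy8), sum(counts) / 8)
})
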