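# Shared fixtures built in code.

alba_params <- function() default_rate_curves()$alba
vitellina_params <- function() default_rate_curves()$vitellina

# 30-minute series over a given number of days from July 1 of year_start,
# with per-day psi/temp values repeated across the day's 48 readings.
daily_series <- function(psi_by_day, temp_by_day, year_start = 2019,
                         site_id = "sA", habitat = "riparian") {
  n_days <- length(psi_by_day)
  t0 <- as.POSIXct(sprintf("%d-07-01 00:00:00", year_start), tz = "UTC")
  ts <- t0 + (seq_len(n_days * 48) - 1) * 30 * 60
  sensor_series(site_id, habitat, ts,
                psi = rep(psi_by_day, each = 48),
                temp = rep(temp_by_day, each = 48))
}

# deterministic 30-value climate fixture with ties
tie_fixture <- function() {
  annual_series(1990:2019, round(sin(1:30) * 3) + 0.5 * floor((0:29) / 3),
                variable = "fixture")
}

# textbook Mann-Kendall by explicit pair enumeration (independent oracle)
mk_brute <- function(x) {
  n <- length(x)
  S <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) S <- S + sign(x[j] - x[i])
  tt <- table(x); tt <- tt[tt > 1]
  varS <- (n * (n - 1) * (2 * n + 5) - sum(tt * (tt - 1) * (2 * tt + 5))) / 18
  list(S = S, varS = varS)
}
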