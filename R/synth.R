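# Seeded synthetic-data generators. Each is a pure function of its
# arguments and seed: the global RNG stream is saved and restored, so the
# same call always returns bit-identical output.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulate an incubation experiment
#'
#' Generates split-clutch development durations under the standard design:
#' constant regimes plus sine-wave fluctuating regimes (diel cycle, hourly
#' cadence). Durations are rate-summation predictions from the truth curve
#' plus Gaussian noise.
#'
#' @param params Truth [rate_curve_params()] (default: the *G. alba*
#'   reference curve).
#' @param constant_temps Constant-regime temperatures, degrees C.
#' @param fluctuating List of `c(mean, amplitude)` pairs for sine-wave
#'   regimes.
#' @param n_per_regime Split clutches per regime (default 4).
#' @param noise_sd Duration noise SD, days (default 1).
#' @param seed RNG seed.
#' @return List with `regimes` (list of [incubation_regime()]),
#'   `observations` (data frame `clutch_id`, `regime_id`, `duration_days`,
#'   `mean_temp`) and `truth` (the parameters and noiseless durations).
#' @export
gen_development_data <- function(params = default_rate_curves()$alba,
                                 constant_temps = c(15, 18, 20, 21, 25),
                                 fluctuating = list(c(21, 2.5), c(25, 5)),
                                 n_per_regime = 4, noise_sd = 1, seed = 1) {
  regimes <- c(
    lapply(constant_temps, function(tc)
      incubation_regime(sprintf("const_%g", tc), "constant", constant_temp = tc,
                        nominal_label = sprintf("%g C", tc))),
    lapply(fluctuating, function(fl)
      incubation_regime(sprintf("fluct_%g pm %g", fl[1], fl[2]), "fluctuating",
                        hourly_temps = fl[1] + fl[2] * sin(2 * pi * (0:23) / 24),
                        nominal_label = sprintf("%g +/- %g C", fl[1], fl[2])))
  )
  names(regimes) <- vapply(regimes, `[[`, character(1), "regime_id")
  true_dur <- vapply(regimes, predict_duration, numeric(1), params = params)
  obs <- with_seed(seed, {
    do.call(rbind, lapply(seq_along(regimes), function(i) {
      r <- regimes[[i]]
      data.frame(
        clutch_id = sprintf("%s_clutch%d", r$regime_id, seq_len(n_per_regime)),
        regime_id = r$regime_id,
        duration_days = true_dur[i] + stats::rnorm(n_per_regime, 0, noise_sd),
        mean_temp = mean(regime_temps(r)),
        stringsAsFactors = FALSE)
    }))
  })
  if (any(obs$duration_days <= 0))
    stop("noise produced non-positive durations; lower noise_sd", call. = FALSE)
  list(regimes = regimes, observations = obs,
       truth = list(params = params, durations = true_dur))
}

#' Simulate a water-flux experiment
#'
#' Per-frog area-normalised fluxes on wetted substrates. The population
#' mean flux is a monotone piecewise-linear function of water potential
#' crossing zero exactly at `true_at`, calibrated to the qualitative
#' behaviour observed in *Geocrinia*: uptake peaks on free water and drops
#' steeply over the first 30 percent of the way to the threshold (3.0 down
#' to 1.0 mg cm^-2 h^-1), crosses zero at `true_at`, and is sufficiently
#' negative 30 kPa beyond it (-0.8) that essentially every individual
#' loses water there under the default measurement noise. Measurements add
#' residual Gaussian noise (and optionally a per-frog intercept).
#'
#' @param true_at Truth absorption threshold, kPa (in (-200, 0)).
#' @param treatments Water-potential treatments, kPa (<= 0).
#' @param n_frogs Frogs per treatment (default 10).
#' @param noise_sd Residual flux noise SD, mg cm^-2 h^-1 (default 0.3).
#' @param frog_sd SD of an optional per-frog intercept (default 0: the
#'   noise model is purely residual).
#' @param seed RNG seed.
#' @return Data frame with `frog_id`, `species`, `standard_mass_g`,
#'   `water_potential`, `mass_start_g`, `mass_end_g`, `duration_h`, `flux`,
#'   `excluded`; attribute `truth` holds `true_at` and the mean-flux knots.
#' @export
gen_flux_data <- function(true_at = -50,
                          treatments = c(0, -7, -15, -30, -40, -50, -70,
                                         -80, -100, -200),
                          n_frogs = 10, noise_sd = 0.3, frog_sd = 0,
                          seed = 7) {
  if (!(true_at > -200 && true_at < 0))
    stop("true_at must lie in (-200, 0) kPa", call. = FALSE)
  dry_knot <- max(true_at - 30, (true_at - 200) / 2)
  knots_psi <- c(0, 0.3 * true_at, true_at, dry_knot, -200)
  knots_flux <- c(3, 1, 0, -0.8, -1.5)
  mean_flux <- function(psi) stats::approx(knots_psi, knots_flux, xout = psi,
                                           rule = 2)$y
  with_seed(seed, {
    std_mass <- pmax(stats::rnorm(n_frogs, 1.35, 0.27), 0.5)
    frog_eff <- stats::rnorm(n_frogs, 0, frog_sd)
    grid <- expand.grid(frog = seq_len(n_frogs), psi = treatments)
    flux <- mean_flux(grid$psi) + frog_eff[grid$frog] +
      stats::rnorm(nrow(grid), 0, noise_sd)
    dur <- 2
    m0 <- std_mass[grid$frog] * 0.9   # dehydrated to ~90% standard mass
    dm <- flux * surface_area(std_mass[grid$frog]) * dur / 1000
    out <- data.frame(
      frog_id = sprintf("frog%02d", grid$frog),
      species = "synthetic",
      standard_mass_g = std_mass[grid$frog],
      water_potential = grid$psi,
      mass_start_g = m0,
      mass_end_g = m0 + dm,
      duration_h = dur,
      flux = flux,
      excluded = 0L,
      stringsAsFactors = FALSE)
    attr(out, "truth") <- list(true_at = true_at,
                               knots = data.frame(psi = knots_psi,
                                                  flux = knots_flux))
    out
  })
}

#' Simulate seasonal soil microclimate series
#'
#' 30-minute soil water potential and temperature series for a set of
#' sites over one July-June year, emulating a Mediterranean-climate
#' seasonal cycle: soils saturated (about -5 kPa) through the cool-wet
#' winter, with a summer dry-down to a site-specific minimum (sinusoidal
#' drying episode on the log10 scale, multiplicative log-scale noise), and
#' temperature following an annual sinusoid (winter about 10 C, summer
#' about 20 C, plus a site offset and a diel sinusoid). The noiseless
#' skeleton's exceedance-day counts are returned as ground truth.
#'
#' @param n_sites Number of riparian sites (default 8).
#' @param year_start Integer year Y; series runs Y-07-01 to (Y+1)-06-30.
#' @param psi_min Site-specific dry-down minima, kPa (length `n_sites`;
#'   the defaults span saturated to severely dry so that six of the eight
#'   default sites dry past -50 kPa).
#' @param site_temp_offset Per-site summer temperature offsets, degrees C
#'   (winter stays pinned near 10 C; the summer daytime maximum is about
#'   `22.5 + offset`). The defaults span cool, buffered sites to one
#'   markedly hot site, so that three of the eight default sites exceed a
#'   23.3 C optimum and habitat maxima range from about 20 to 30 C.
#' @param at Threshold used for the truth exceedance count (default -50).
#' @param psi_noise_sd Log10-scale psi noise SD (default 0.04).
#' @param temp_noise_sd Temperature noise SD, degrees C (default 0.4).
#' @param seed RNG seed.
#' @return List with `series` (list of [sensor_series()]) and `truth`
#'   (data frame: `site_id`, `psi_min`, `skeleton_days_below_at`,
#'   `skeleton_t_max`).
#' @export
gen_microclimate <- function(n_sites = 8, year_start = 2019,
                             psi_min = c(-20, -35, -55, -60, -80, -100,
                                         -140, -180)[seq_len(n_sites)],
                             site_temp_offset = c(-2.5, -1.5, -0.5, 0, 0.5,
                                                  1.5, 3.5, 7.5)[seq_len(n_sites)],
                             at = -50, psi_noise_sd = 0.04,
                             temp_noise_sd = 0.4, seed = 3) {
  stopifnot(length(psi_min) == n_sites, all(psi_min < 0),
            length(site_temp_offset) == n_sites)
  t0 <- as.POSIXct(sprintf("%d-07-01 00:00:00", year_start), tz = "UTC")
  t1 <- as.POSIXct(sprintf("%d-07-01 00:00:00", year_start + 1L), tz = "UTC")
  ts <- seq(t0, t1 - 1, by = 30 * 60)
  days_since <- as.numeric(ts - t0, units = "days")
  hour <- (days_since %% 1) * 24
  year_len <- as.numeric(t1 - t0, units = "days")

  # dry season: sinusoidal drying episode on log10|psi|, peaking mid-summer
  dry_start <- 150; dry_len <- 150   # ~ late Nov to late Apr
  s <- pmax(0, sin(pi * (days_since - dry_start) / dry_len))
  s[days_since < dry_start | days_since > dry_start + dry_len] <- 0

  skeleton <- function(i) {
    lpsi <- log10(5) + s * (log10(abs(psi_min[i])) - log10(5))
    temp <- 15 + site_temp_offset[i] / 2 -
      (5 + site_temp_offset[i] / 2) * cos(2 * pi * days_since / year_len) +
      2.5 * sin(2 * pi * (hour - 9) / 24)
    list(psi = -10^lpsi, temp = temp)
  }
  truth <- do.call(rbind, lapply(seq_len(n_sites), function(i) {
    sk <- skeleton(i)
    day <- as.Date(ts, tz = "UTC")
    data.frame(site_id = sprintf("site%02d", i), psi_min = psi_min[i],
               skeleton_days_below_at = sum(tapply(sk$psi < at, day, any)),
               skeleton_t_max = max(sk$temp),
               stringsAsFactors = FALSE)
  }))
  series <- with_seed(seed, {
    lapply(seq_len(n_sites), function(i) {
      sk <- skeleton(i)
      lpsi <- log10(pmax(abs(sk$psi), 1e-6)) +
        stats::rnorm(length(ts), 0, psi_noise_sd)
      sensor_series(sprintf("site%02d", i), "riparian", ts,
                    psi = -10^lpsi,
                    temp = sk$temp + stats::rnorm(length(ts), 0, temp_noise_sd))
    })
  })
  list(series = series, truth = truth)
}

#' Simulate an annual climate series with a linear trend
#'
#' @param n_years Number of years.
#' @param start_year First year.
#' @param mean_level Series mean at the midpoint year.
#' @param slope_per_year Truth trend, units per year.
#' @param noise_sd Gaussian noise SD.
#' @param variable Label.
#' @param seed RNG seed.
#' @return An [annual_series()] with attribute `truth` (the slope).
#' @export
gen_climate_series <- function(n_years = 30, start_year = 1990,
                               mean_level = 1150, slope_per_year = -10.9,
                               noise_sd = 80, variable = "rainfall_mm",
                               seed = 11) {
  years <- start_year + seq_len(n_years) - 1L
  mid <- mean(years)
  vals <- with_seed(seed,
    mean_level + slope_per_year * (years - mid) + stats::rnorm(n_years, 0, noise_sd))
  out <- annual_series(years, vals, variable = variable)
  attr(out, "truth") <- list(slope_per_year = slope_per_year)
  out
}

#' Simulate agar-model field deployments
#'
#' Habitat experiment: adult- and juvenile-sized models in frog habitat,
#' adjacent riparian and adjacent terrestrial habitat at 0/25/50 m, with
#' truth 9-h losses of 6.4, 13.5 and 31.0 percent (adults; juveniles scaled
#' up) at the 25-50 m distances. Cover experiment: adult models under leaf
#' litter, moss, sedge, log (3-9 percent) and in the open (about 30
#' percent).
#'
#' @param experiment `"habitat"` or `"cover"`.
#' @param n_sites Sites (default 5 habitat, 3 cover).
#' @param reps Replicate models per site x group (default 3).
#' @param juvenile_factor Multiplier on truth means for juvenile models
#'   (default 1.3).
#' @param noise_sd SD of the 9-h loss noise, percentage points (default 2).
#' @param seed RNG seed.
#' @return Deployment data frame (`model_id`, `size_class`, `habitat` or
#'   `cover`, `distance_m`, `site_id`, `mass_out`, `mass_in`,
#'   `exposure_h`); attribute `truth` holds the group means.
#' @export
gen_field_deployments <- function(experiment = c("habitat", "cover"),
                                  n_sites = NULL, reps = 3,
                                  juvenile_factor = 1.3, noise_sd = 2,
                                  seed = 5) {
  experiment <- match.arg(experiment)
  if (experiment == "habitat") {
    if (is.null(n_sites)) n_sites <- 5
    means <- c(frog = 6.4, adjacent_riparian = 13.5, adjacent_terrestrial = 31.0)
    grid <- expand.grid(habitat = names(means), distance_m = c(0, 25, 50),
                        site = seq_len(n_sites), rep = seq_len(reps),
                        size_class = c("adult", "juvenile"),
                        stringsAsFactors = FALSE)
    truth_loss <- means[grid$habitat] *
      ifelse(grid$size_class == "juvenile", juvenile_factor, 1)
  } else {
    if (is.null(n_sites)) n_sites <- 3
    means <- c(leaf_litter = 5, moss = 4, sedge = 6, log = 7, open = 30)
    grid <- expand.grid(cover = names(means), distance_m = NA_real_,
                        site = seq_len(n_sites), rep = seq_len(reps),
                        size_class = c("adult", "juvenile"),
                        stringsAsFactors = FALSE)
    truth_loss <- means[grid$cover] *
      ifelse(grid$size_class == "juvenile", juvenile_factor, 1)
  }
  with_seed(seed, {
    n <- nrow(grid)
    mass_out <- ifelse(grid$size_class == "adult",
                       stats::rnorm(n, 1.97, 0.16), stats::rnorm(n, 0.46, 0.07))
    exposure <- stats::runif(n, 9, 11)
    loss9 <- pmax(truth_loss + stats::rnorm(n, 0, noise_sd), 0.1)
    total_loss <- pmin(loss9 / 9 * exposure, 95)
    out <- data.frame(
      model_id = sprintf("model%04d", seq_len(n)),
      size_class = grid$size_class,
      site_id = sprintf("site%02d", grid$site),
      distance_m = grid$distance_m,
      mass_out = mass_out,
      mass_in = mass_out * (1 - total_loss / 100),
      exposure_h = exposure,
      stringsAsFactors = FALSE)
    if (experiment == "habitat") out$habitat <- grid$habitat else out$cover <- grid$cover
    attr(out, "truth") <- list(group_means_9h = means,
                               juvenile_factor = juvenile_factor)
    out
  })
}
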