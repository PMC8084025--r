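#!/usr/bin/env Rscript
# Stage 1: generate every synthetic input consumed by the later stages,
# with known ground truth, and write them as delimited text under
# results/data/. All downstream scripts read these files (or regenerate
# with the same seeds), so the whole workflow is reproducible end to end.

library(frogniche)

out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

# --- incubation experiment (truth: the G. alba reference curve) ---------
dev <- gen_development_data(params = default_rate_curves()$alba,
                            n_per_regime = 4, noise_sd = 1, seed = 1)
write.csv(dev$observations, file.path(out, "incubation_observations.csv"),
          row.names = FALSE)
regime_tab <- do.call(rbind, lapply(dev$regimes, function(r)
  data.frame(regime_id = r$regime_id, kind = r$kind,
             constant_temp = if (r$kind == "constant") r$constant_temp else NA,
             nominal_label = r$nominal_label)))
write.csv(regime_tab, file.path(out, "incubation_regimes.csv"), row.names = FALSE)
for (r in dev$regimes)
  if (r$kind == "fluctuating")
    write.csv(data.frame(hour = seq_along(r$hourly_temps) - 1,
                         temp_C = r$hourly_temps),
              file.path(out, paste0("regime_", gsub("[^A-Za-z0-9]", "_", r$regime_id), ".csv")),
              row.names = FALSE)
message("incubation: ", nrow(dev$observations), " split-clutch durations over ",
        length(dev$regimes), " regimes (truth T_opt = ",
        dev$truth$params$b3, " C)")

# --- water-flux experiment (truth: absorption threshold -50 kPa) --------
flux <- gen_flux_data(true_at = -50, n_frogs = 10, noise_sd = 0.3, seed = 7)
write.csv(flux, file.path(out, "water_flux.csv"), row.names = FALSE)
message("water flux: ", nrow(flux), " measurements, truth threshold -50 kPa")

# --- soil microclimate year 2019-20 (8 riparian sites) ------------------
mc <- gen_microclimate(n_sites = 8, year_start = 2019, seed = 3)
for (s in mc$series) {
  df <- data.frame(timestamp = format(s$timestamps, "%Y-%m-%d %H:%M:%S"),
                   psi_kPa = round(s$psi, 3), temp_C = round(s$temp, 3))
  write.csv(df, file.path(out, paste0("sensor_", s$site_id, ".csv")),
            row.names = FALSE)
}
write.csv(mc$truth, file.path(out, "microclimate_truth.csv"), row.names = FALSE)
message("microclimate: 8 site-years at 30-min cadence; skeleton days below ",
        "-50 kPa span ", min(mc$truth$skeleton_days_below_at), "-",
        max(mc$truth$skeleton_days_below_at))

# --- annual climate series ----------------------------------------------
rain <- gen_climate_series(n_years = 30, start_year = 1990, mean_level = 1150,
                           slope_per_year = -10.9, noise_sd = 80,
                           variable = "rainfall_mm", seed = 11)
tmax <- gen_climate_series(n_years = 30, start_year = 1990, mean_level = 21,
                           slope_per_year = 0.013, noise_sd = 0.5,
                           variable = "mean_max_temp_C", seed = 12)
write.csv(data.frame(year = rain$years, rainfall_mm = rain$values),
          file.path(out, "rainfall.csv"), row.names = FALSE)
write.csv(data.frame(year = tmax$years, mean_max_temp_C = tmax$values),
          file.path(out, "mean_max_temp.csv"), row.names = FALSE)
message("climate: 30-year rainfall (truth -109 mm/decade) and mean maximum ",
        "temperature (truth +0.13 C/decade) series")

# --- agar-model deployments ---------------------------------------------
dep <- gen_field_deployments("habitat", seed = 5)
write.csv(dep, file.path(out, "agar_deployments_habitat.csv"), row.names = FALSE)
cov <- gen_field_deployments("cover", seed = 6)
write.csv(cov, file.path(out, "agar_deployments_cover.csv"), row.names = FALSE)
message("agar models: ", nrow(dep), " habitat-transect and ", nrow(cov),
        " ground-cover deployments")
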