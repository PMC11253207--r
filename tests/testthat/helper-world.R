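# Shared fixture builders: small synthetic worlds assembled in code.

vlr_site <- function(site_id = "vlr1", lat = 33.1, lon = 35.6, elev = 70,
                     ...) {
  site_config(site_id, lat, lon, elev, "vertical-looking", ...)
}

wr_site <- function(site_id = "wr1", lat = 30.6, lon = 34.8, elev = 868,
                    ...) {
  site_config(site_id, lat, lon, elev, "weather", ...)
}

# a single-site spring world; pass overrides through to sim_world()
tiny_world <- function(site = vlr_site(), seasons = list(
                         list(season = "spring", year = 2018)),
                       seed = 42, ...) {
  sim_world(list(site), seasons, rng_seed = seed, ...)
}

# deterministic world: no wind, no temperature anomaly, no contaminants,
# no clutter, no rain, no heading/airspeed spread - for exact identities
calm_weather <- function(mean_speed = 0, wind_sd = 0, shear = 0,
                         temp_anomaly_sd = 0) {
  wx <- sim_weather_defaults(temp_anomaly_sd = temp_anomaly_sd,
                             wind_sd = wind_sd)
  wx$wind$spring$mean_speed <- mean_speed
  wx$wind$autumn$mean_speed <- mean_speed
  wx$wind$shear_per_km <- shear
  wx
}

calm_world <- function(site = vlr_site(), seed = 42, ...) {
  args <- modifyList(
    list(site = site, seed = seed, weather = calm_weather(),
         contaminant_fraction = 0, clutter_per_night = 0,
         rain_prob_per_night = 0, heading_sd_deg = 0, airspeed_sd = 0),
    list(...))
  do.call(tiny_world, args)
}

# brute-force nightly MTR recount, independent of mtr_profile():
# per sunset-anchored clock hour and altitude bin, count echoes and divide
# by width x duration; sum bins per hour, average hours
recount_nightly_mtr <- function(echoes, night, bin_edges, width_km) {
  t0 <- as.numeric(night$sunset); t1 <- as.numeric(night$sunrise)
  edges <- seq(t0, t1, by = 3600)
  if (edges[length(edges)] >= t1) edges <- edges[-length(edges)]
  hour_tot <- numeric(length(edges))
  for (i in seq_along(edges)) {
    h0 <- edges[i]; h1 <- min(edges[i] + 3600, t1)
    dur <- (h1 - h0) / 3600
    for (b in seq_len(length(bin_edges) - 1L)) {
      lo <- bin_edges[b]; hi <- bin_edges[b + 1L]
      last_bin <- b == length(bin_edges) - 1L
      last_hour <- i == length(edges)
      n <- sum(as.numeric(echoes$timestamp) >= h0 &
                 (if (last_hour) as.numeric(echoes$timestamp) <= h1
                  else as.numeric(echoes$timestamp) < h1) &
                 !is.na(echoes$altitude_agl_m) &
                 echoes$altitude_agl_m >= lo &
                 (if (last_bin) echoes$altitude_agl_m <= hi
                  else echoes$altitude_agl_m < hi))
      hour_tot[i] <- hour_tot[i] + n / (width_km * dur)
    }
  }
  mean(hour_tot)
}

# fast boosting settings for unit tests that exercise the machinery rather
# than the frozen defaults
fast_hp <- function(...) {
  brt_hyperparams(learning_rate = 0.05, max_trees = 1500, cv_folds = 5,
                  ...)
}
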