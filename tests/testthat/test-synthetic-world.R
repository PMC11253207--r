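test_that("identical seed and configuration give identical output", {
  w <- tiny_world(seed = 99)
  site <- w$sites[[1]]
  a <- generate_weather(w, site, "spring", 2018)
  b <- generate_weather(w, site, "spring", 2018)
  expect_identical(a, b)
  night <- solar_night(site$latitude, site$longitude, "2018-04-10")
  e1 <- generate_night_echoes(w, site, night, a)
  e2 <- generate_night_echoes(w, site, night, b)
  expect_identical(e1, e2)
})

test_that("zero anomaly variance gives the exact seasonal temperature trend", {
  w <- tiny_world(weather = calm_weather(temp_anomaly_sd = 0))
  site <- w$sites[[1]]
  wx <- generate_weather(w, site, "spring", 2018)
  # independent re-derivation: linear sea-level trend minus constant lapse
  cfg <- w$weather$temp
  doy <- as.numeric(strftime(wx$timestamp, "%j", tz = "UTC")) +
    (as.numeric(wx$timestamp) %% 86400) / 86400
  frac <- pmin(pmax((doy - 60) / (151 - 60), 0), 1)  # Mar 1 .. May 31
  expected <- cfg$spring$start_c +
    frac * (cfg$spring$end_c - cfg$spring$start_c) -
    cfg$lapse_per_km * wx$z_m / 1000
  expect_equal(wx$t_c, expected, tolerance = 1e-9)
})

test_that("profile invariants hold and heights increase as pressure drops", {
  w <- tiny_world(seed = 5)
  wx <- generate_weather(w, w$sites[[1]], "autumn", 2018)
  one <- wx[wx$timestamp == wx$timestamp[1], ]
  one <- one[order(-one$pressure_hpa), ]
  expect_true(all(diff(one$z_m) > 0))
  expect_true(all(wx$cc >= 0 & wx$cc <= 1))
  expect_true(all(wx$rh_pct >= 0 & wx$rh_pct <= 100))
})

test_that("spring winds are faster than autumn winds on average", {
  w <- tiny_world(seasons = list(list(season = "spring", year = 2018),
                                 list(season = "autumn", year = 2018)),
                  seed = 21)
  site <- w$sites[[1]]
  sp <- generate_weather(w, site, "spring", 2018)
  au <- generate_weather(w, site, "autumn", 2018)
  lev <- function(x) x[x$pressure_hpa == 950, ]
  sp_s <- with(lev(sp), sqrt(u_ms^2 + v_ms^2))
  au_s <- with(lev(au), sqrt(u_ms^2 + v_ms^2))
  # configured means differ by 2 m/s; demand the configured ordering well
  # beyond chance (>= 50 nights per season)
  se <- sqrt(var(sp_s) / length(sp_s) + var(au_s) / length(au_s))
  expect_gt(mean(sp_s) - mean(au_s), 3 * se)
})

test_that("unknown season labels are rejected", {
  w <- tiny_world()
  expect_error(generate_weather(w, w$sites[[1]], "winter", 2018),
               "unknown season")
  expect_error(season_dates("summer", 2018), "unknown season")
})

test_that("intensity multipliers are normalised at neutral conditions", {
  w <- tiny_world()
  sel <- w$wind_selectivity$spring
  expect_equal(wind_multiplier(sel, tw = 0, cw = 0, s = 0), 1)
  expect_equal(temperature_multiplier(w$temp_effect,
                                      w$temp_effect$reference_c), 1)
  expect_equal(phenology_multiplier(w$phenology$spring,
                                    w$phenology$spring$peak_doy), 1)
  # monotone non-decreasing in tailwind below the cutoff
  tws <- seq(-8, 8, by = 0.5)
  ms <- wind_multiplier(sel, tws, 0, abs(tws))
  expect_true(all(diff(ms) >= 0))
  # hard cutoff: a 12 m/s headwind with a 10 m/s cutoff shuts migration down
  expect_equal(wind_multiplier(sel, tw = -12, cw = 0, s = 12), 0)
})

test_that("intensity at peak date, neutral wind and reference temperature equals the base rate", {
  site <- vlr_site(elev = 0)
  w <- tiny_world(site = site, weather = calm_weather(),
                  base_birds_per_night = 250)
  # choose the evening whose ordinal date is the phenology peak (doy 105)
  night <- solar_night(site$latitude, site$longitude, "2018-04-15")
  wx <- generate_weather(w, site, "spring", 2018)
  # force the interpolated night temperature to the reference value
  wx$t_c <- w$temp_effect$reference_c
  expect_equal(as.numeric(true_intensity(w, site, night, wx)), 250,
               tolerance = 1e-9)
})

test_that("with zero wind, ground speed equals the hidden true airspeed", {
  w <- calm_world(airspeed_sd = 3)  # spread allowed; wind is what matters
  site <- w$sites[[1]]
  wx <- generate_weather(w, site, "spring", 2018)
  night <- solar_night(site$latitude, site$longitude, "2018-04-12")
  g <- generate_night_echoes(w, site, night, wx)
  expect_gt(nrow(g$echoes), 0)
  expect_equal(g$echoes$ground_speed_ms, g$truth$true_airspeed_ms,
               tolerance = 1e-12)
  expect_equal(g$echoes$track_direction_deg %% 360,
               g$truth$true_heading_deg %% 360, tolerance = 1e-9)
})

test_that("no contaminants, zero heading spread and constant wind collapse track directions", {
  wx_cfg <- calm_weather(mean_speed = 4)
  w <- tiny_world(weather = wx_cfg, contaminant_fraction = 0,
                  clutter_per_night = 0, rain_prob_per_night = 0,
                  heading_sd_deg = 0, airspeed_sd = 0)
  site <- w$sites[[1]]
  wx <- generate_weather(w, site, "spring", 2018)
  night <- solar_night(site$latitude, site$longitude, "2018-04-12")
  g <- generate_night_echoes(w, site, night, wx)
  expect_gt(nrow(g$echoes), 1)
  expect_lt(diff(range(g$echoes$track_direction_deg)), 1e-9)
})

test_that("ground velocity minus wind reproduces the hidden air velocity", {
  w <- tiny_world(seed = 13)
  site <- w$sites[[1]]
  wx <- generate_weather(w, site, "spring", 2018)
  night <- solar_night(site$latitude, site$longitude, "2018-04-14")
  g <- generate_night_echoes(w, site, night, wx)
  tr <- g$truth[g$truth$is_migrant, ]
  e <- g$echoes[match(tr$echo_id, g$echoes$echo_id), ]
  guv <- bearing_to_uv(e$track_direction_deg, e$ground_speed_ms)
  auv <- bearing_to_uv(tr$true_heading_deg, tr$true_airspeed_ms)
  expect_equal(guv$u - tr$wind_u_ms, auv$u, tolerance = 1e-10)
  expect_equal(guv$v - tr$wind_v_ms, auv$v, tolerance = 1e-10)
})

test_that("expected echo count scales linearly with detection efficiency", {
  # paired sites: identical configuration and weather seed path except for
  # detection efficiency -> expected counts differ by exactly that factor
  dates <- season_dates("spring", 2018)[20:69]  # 50 nights
  eff_ratio <- 0.1
  counts <- sapply(c(1, eff_ratio), function(eff) {
    site <- vlr_site(detection_efficiency = eff)
    w <- tiny_world(site = site, seed = 77, base_birds_per_night = 600)
    wx <- generate_weather(w, site, "spring", 2018)
    sum(sapply(dates, function(d) {
      night <- solar_night(site$latitude, site$longitude, d)
      g <- generate_night_echoes(w, site, night, wx)
      sum(g$truth$is_migrant)
    }))
  })
  ratio <- counts[2] / counts[1]
  se <- sqrt(1 / counts[1] + 1 / counts[2]) * ratio  # Poisson delta method
  expect_lt(abs(ratio - eff_ratio), 3 * se + 0.01)
})

test_that("nightly migrant counts peak near the configured phenology date", {
  site <- vlr_site()
  w <- tiny_world(site = site, seed = 3, base_birds_per_night = 2000,
                  weather = calm_weather(mean_speed = 3, wind_sd = 1,
                                         temp_anomaly_sd = 1))
  wx <- generate_weather(w, site, "spring", 2018)
  dates <- season_dates("spring", 2018)
  nights <- solar_nights(site$latitude, site$longitude, dates)
  counts <- vapply(seq_len(nrow(nights)), function(i)
    sum(generate_night_echoes(w, site, nights[i, ], wx)$truth$is_migrant),
    numeric(1))
  sm <- stats::filter(counts, rep(1 / 7, 7), sides = 2)  # 7-night smoother
  peak_doy <- as.numeric(strftime(dates[which.max(sm)], "%j"))
  expect_lt(abs(peak_doy - w$phenology$spring$peak_doy),
            w$phenology$spring$width_days / 2)
})

test_that("echo generation without weather is rejected", {
  w <- tiny_world()
  night <- solar_night(33, 35, "2018-04-10")
  expect_error(generate_night_echoes(w, w$sites[[1]], night,
                                     data.frame()),
               "empty profile")
})
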