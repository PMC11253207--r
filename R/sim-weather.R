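#' Generate hourly synthetic atmospheric profiles for one site-season
#'
#' Emulates a reanalysis extract: for every hour of the season (plus the
#' following day, so the last night is fully covered) and every pressure
#' level from 1000 to 550 hPa, returns temperature, wind components,
#' relative humidity, vertical velocity, cloud cover and geopotential
#' height in long format.
#'
#' @param world a [sim_world()]
#' @param site a [site_config()] (member of `world$sites`)
#' @param season `"spring"` or `"autumn"`
#' @param year calendar year
#' @return data.frame with columns `site_id, timestamp, pressure_hpa, t_c,
#'   u_ms, v_ms, rh_pct, w_pas, cc, z_m`, hour-major, level-minor ordering
#' @export
generate_weather <- function(world, site, season, year) {
  season <- check_season(season)
  dates <- season_dates(season, year)
  t0 <- as.POSIXct(paste(dates[1], "00:00:00"), tz = "UTC")
  t1 <- as.POSIXct(paste(dates[length(dates)] + 1, "23:00:00"), tz = "UTC")
  hours <- seq(t0, t1, by = 3600)
  nh <- length(hours)
  wx <- world$weather
  lev <- wx$levels_hpa
  z <- standard_height_m(lev)
  nl <- length(lev)

  seed <- derive_seed(world$rng_seed, "weather", site$site_id, season, year)
  with_seed(seed, {
    ## nightly AR(1) temperature anomaly, shared by all hours of a UTC night
    ## (hours are assigned to the evening date of the night they fall in by
    ## shifting 12 h back)
    ndates <- seq(dates[1] - 1, dates[length(dates)] + 1, 1)
    tcfg <- wx$temp
    a <- ar1_series(length(ndates), tcfg$anomaly_rho, tcfg$anomaly_sd)
    night_of_hour <- as.Date(hours - 12 * 3600, tz = "UTC")
    anom <- a[match(night_of_hour, ndates)]

    ## sea-level seasonal trend, linear across the season's dates
    doy <- as.numeric(strftime(hours, "%j", tz = "UTC")) +
      (as.numeric(hours) %% 86400) / 86400
    doy0 <- as.numeric(strftime(dates[1], "%j"))
    doy1 <- as.numeric(strftime(dates[length(dates)], "%j"))
    scfg <- tcfg[[season]]
    frac <- pmin(pmax((doy - doy0) / (doy1 - doy0), 0), 1)
    t_sl <- scfg$start_c + frac * (scfg$end_c - scfg$start_c)

    ## hourly AR(1) wind anomalies around the seasonal mean vector
    wcfg <- wx$wind
    mu <- bearing_to_uv((wcfg[[season]]$from_deg + 180) %% 360,
                        wcfg[[season]]$mean_speed)
    au <- ar1_series(nh, wcfg$rho, wcfg$sd)
    av <- ar1_series(nh, wcfg$rho, wcfg$sd)

    rh_a <- ar1_series(nh, wx$rh$rho, 1)
    w_a <- ar1_series(nh, wx$w$rho, 1)
    cc_a <- ar1_series(nh, wx$cloud$rho, 1)
  })

  ## expand hour-major, level-minor
  idx <- rep(seq_len(nh), each = nl)
  zrep <- rep(z, times = nh)
  shear <- 1 + wx$wind$shear_per_km * zrep / 1000
  out <- data.frame(
    site_id = site$site_id,
    timestamp = hours[idx],
    pressure_hpa = rep(lev, times = nh),
    t_c = t_sl[idx] + anom[idx] - tcfg$lapse_per_km * zrep / 1000,
    u_ms = (mu$u + au[idx]) * shear,
    v_ms = (mu$v + av[idx]) * shear,
    rh_pct = pmin(pmax(wx$rh$mean + wx$rh$sd * rh_a[idx], 2), 100),
    w_pas = wx$w$sd * w_a[idx],
    cc = pmin(pmax(stats::plogis(1.4 * cc_a[idx] - 0.8), 0), 1),
    z_m = zrep,
    stringsAsFactors = FALSE
  )
  out
}

# stationary AR(1) with marginal sd `sd` (returns zeros when sd == 0)
ar1_series <- function(n, rho, sd) {
  if (sd <= 0) return(numeric(n))
  x <- numeric(n)
  x[1] <- rnorm(1, 0, sd)
  if (n > 1) {
    innov <- rnorm(n - 1, 0, sd * sqrt(1 - rho^2))
    for (i in 2:n) x[i] <- rho * x[i - 1] + innov[i - 1]
  }
  x
}

#' Standard-atmosphere height of a pressure level
#'
#' Barometric relation `z = 44330.77 (1 - (p / 1013.25)^0.190263)` metres;
#' strictly decreasing in pressure.
#'
#' @param pressure_hpa pressure in hPa
#' @return height above sea level, m
#' @export
standard_height_m <- function(pressure_hpa) {
  44330.77 * (1 - (pressure_hpa / 1013.25)^0.1902632)
}
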