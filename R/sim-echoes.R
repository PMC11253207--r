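#' Phenology, temperature and wind multipliers of the intensity model
#'
#' Nightly expected migration intensity is a product of independent terms:
#' a bell-shaped date effect, a monotone saturating temperature effect and a
#' wind-selectivity term with a hard overall-wind-speed cutoff. Each factor
#' equals 1 under neutral conditions (peak date, reference temperature,
#' calm wind), so the configured base rate is the intensity of a neutral
#' peak night.
#'
#' @param phen `list(peak_doy, width_days)`
#' @param doy ordinal date (day of year, Jan 1 = 1)
#' @return multiplier in `(0, 1]`
#' @export
phenology_multiplier <- function(phen, doy) {
  exp(-0.5 * ((doy - phen$peak_doy) / phen$width_days)^2)
}

#' @rdname phenology_multiplier
#' @param temp_effect `list(slope, saturation, reference_c)`
#' @param t_c night-mean temperature, deg C
#' @export
temperature_multiplier <- function(temp_effect, t_c) {
  pmin(exp(temp_effect$slope * (t_c - temp_effect$reference_c)),
       temp_effect$saturation)
}

#' @rdname phenology_multiplier
#' @param sel per-season selectivity `list(tailwind_gain, headwind_penalty,
#'   crosswind_penalty, cutoff_ms)`
#' @param tw tailwind component, m/s (positive supports migration)
#' @param cw crosswind component, m/s (sign ignored)
#' @param s overall wind speed, m/s
#' @export
wind_multiplier <- function(sel, tw, cw, s) {
  ifelse(s >= sel$cutoff_ms, 0,
         exp(ifelse(tw >= 0, sel$tailwind_gain * tw,
                    sel$headwind_penalty * tw)) *
           exp(-sel$crosswind_penalty * abs(cw)))
}

#' Expected number of migrants aloft on one night
#'
#' Interpolates the night's hourly profiles to 500 m above the radar,
#' averages temperature and wind over the night window, and applies the
#' intensity model: `base x phenology x temperature x wind`. Returns 0
#' beyond the hard wind-speed cutoff and is monotone non-decreasing in
#' tailwind below it.
#'
#' @param world a [sim_world()]
#' @param site a [site_config()]
#' @param night a `night_window` row from [solar_night()]
#' @param profiles hourly profile table from [generate_weather()]
#' @return expected birds per night (>= 0), with the night-mean conditions
#'   attached as attribute `"conditions"`
#' @export
true_intensity <- function(world, site, night, profiles) {
  season <- season_of_date(night$night_id)
  cond <- night_mean_conditions(profiles, night, site$elevation + 500)
  dirn <- world$season_direction[[season]]
  unit <- bearing_to_uv(dirn)
  tw <- cond$u * unit$u + cond$v * unit$v
  cw <- cond$u * unit$v - cond$v * unit$u
  doy <- as.numeric(strftime(as.Date(night$night_id), "%j"))
  lambda <- world$base_birds_per_night *
    phenology_multiplier(world$phenology[[season]], doy) *
    temperature_multiplier(world$temp_effect, cond$t) *
    wind_multiplier(world$wind_selectivity[[season]], tw, cw, cond$s)
  attr(lambda, "conditions") <- c(cond, list(tw = tw, cw = cw))
  lambda
}

# night-mean temperature, wind components and mean hourly wind speed at a
# target height; hourly linear interpolation in geopotential height
night_mean_conditions <- function(profiles, night, target_asl) {
  p <- profiles[profiles$timestamp >= night$sunset &
                  profiles$timestamp <= night$sunrise, , drop = FALSE]
  if (nrow(p) == 0L)
    stop("no atmospheric profiles inside the night window ", night$night_id)
  byhr <- split(p, format(p$timestamp, "%Y-%m-%d %H", tz = "UTC"))
  vals <- vapply(byhr, function(h) {
    iv <- interp_to_height(h, target_asl)
    c(iv$t_c, iv$u_ms, iv$v_ms, sqrt(iv$u_ms^2 + iv$v_ms^2))
  }, numeric(4))
  list(t = mean(vals[1, ]), u = mean(vals[2, ]), v = mean(vals[3, ]),
       s = mean(vals[4, ]), n_hours = ncol(vals))
}

#' Generate one night of synthetic radar echoes
#'
#' Migrant counts are Poisson with mean `true_intensity x
#' detection_efficiency`. Migrant headings are wrapped-normal around the
#' seasonal direction, airspeeds normal truncated at zero, and each echo's
#' ground velocity is its air velocity plus the wind interpolated to the
#' echo's own altitude and hour (the analysis stage deliberately uses the
#' fixed 500 m level instead — that mismatch is a realism feature).
#' Bird-classified contaminants (local movers) get uniform directions;
#' non-bird clutter is also emitted so the class filter has work to do.
#' Echoes falling inside a rain event are retained in the echo table — it
#' is the preprocessing stage's job to remove them using the rain log.
#'
#' Hidden ground truth (migrant flag, true heading, true airspeed and the
#' wind vector each echo experienced) is returned as a separate sidecar
#' table which no pipeline stage reads; tests may.
#'
#' @inheritParams true_intensity
#' @return list with data.frames `echoes` (site_id, timestamp,
#'   altitude_agl_m, ground_speed_ms, track_direction_deg, pulse_mode,
#'   is_bird, echo_id), `truth` (echo_id, is_migrant, true_heading_deg,
#'   true_airspeed_ms, wind_u_ms, wind_v_ms), `rain` (site_id, start, end)
#'   and the scalar `intensity`
#' @export
generate_night_echoes <- function(world, site, night, profiles) {
  if (is.null(profiles) || nrow(profiles) == 0L)
    stop("empty profile sequence: generate weather before echoes")
  season <- season_of_date(night$night_id)
  lambda <- true_intensity(world, site, night, profiles)
  seed <- derive_seed(world$rng_seed, "echoes", site$site_id,
                      format(night$night_id))
  night_len <- as.numeric(night$sunrise) - as.numeric(night$sunset)

  with_seed(seed, {
    ## rain log first so the stream layout is stable
    rain <- if (runif(1) < world$rain_prob_per_night) {
      start <- night$sunset + runif(1, 0, 0.7) * night_len
      dur <- runif(1, 0.5, 2.5) * 3600
      data.frame(site_id = site$site_id, start = start,
                 end = pmin(start + dur, night$sunrise))
    } else {
      data.frame(site_id = character(), start = as_utc(character()),
                 end = as_utc(character()))
    }

    mu_det <- as.numeric(lambda) * site$detection_efficiency
    n_mig <- rpois(1, mu_det)
    cf <- world$contaminant_fraction
    n_con <- if (cf > 0) rpois(1, mu_det * cf / (1 - cf)) else 0L
    n_cl <- rpois(1, world$clutter_per_night)
    n_bird <- n_mig + n_con

    mix <- world$altitude_mixture
    draw_alt <- function(n) {
      if (n == 0L) return(numeric(0))
      comp <- sample.int(length(mix$weights), n, replace = TRUE,
                         prob = mix$weights)
      lo <- mix$range[1]; hi <- mix$range[2]
      plo <- pnorm(lo, mix$means[comp], mix$sds[comp])
      phi <- pnorm(hi, mix$means[comp], mix$sds[comp])
      qnorm(runif(n, plo, phi), mix$means[comp], mix$sds[comp])
    }

    ts_bird <- night$sunset + runif(n_bird) * night_len
    alt <- draw_alt(n_bird)
    heading <- c(
      (world$season_direction[[season]] +
         rnorm(n_mig, 0, world$heading_sd_deg)) %% 360,
      runif(n_con, 0, 360))
    airspeed <- rnorm_trunc(n_bird, world$airspeed_mean[[season]],
                            world$airspeed_sd)

    ## clutter: slow, directionless, any altitude
    ts_cl <- night$sunset + runif(n_cl) * night_len
    alt_cl <- runif(n_cl, 0, mix$range[2])
    gs_cl <- runif(n_cl, 0, 12)
    dir_cl <- runif(n_cl, 0, 360)
  })

  ## wind experienced by each bird echo, at its own altitude and hour
  wind <- echo_wind(profiles, ts_bird, site$elevation + alt)
  air <- bearing_to_uv(heading, airspeed)
  gu <- air$u + wind$u
  gv <- air$v + wind$v

  ord <- order(c(ts_bird, ts_cl))
  echoes <- data.frame(
    site_id = site$site_id,
    timestamp = c(ts_bird, ts_cl),
    altitude_agl_m = c(alt, alt_cl),
    ground_speed_ms = c(sqrt(gu^2 + gv^2), gs_cl),
    track_direction_deg = c(uv_to_bearing(gu, gv), dir_cl),
    pulse_mode = ifelse(c(alt, alt_cl) < 800, "short", "long"),
    is_bird = rep(c(TRUE, FALSE), c(n_bird, n_cl)),
    stringsAsFactors = FALSE
  )[ord, , drop = FALSE]
  echoes$echo_id <- sprintf("%s_%s_%04d", site$site_id,
                            format(night$night_id), seq_len(nrow(echoes)))
  rownames(echoes) <- NULL

  truth <- data.frame(
    echo_id = echoes$echo_id,
    is_migrant = rep(c(TRUE, FALSE, FALSE), c(n_mig, n_con, n_cl))[ord],
    true_heading_deg = c(heading, rep(NA_real_, n_cl))[ord],
    true_airspeed_ms = c(airspeed, rep(NA_real_, n_cl))[ord],
    wind_u_ms = c(wind$u, rep(NA_real_, n_cl))[ord],
    wind_v_ms = c(wind$v, rep(NA_real_, n_cl))[ord],
    stringsAsFactors = FALSE
  )
  rownames(truth) <- NULL
  list(echoes = echoes, truth = truth, rain = rain,
       intensity = as.numeric(lambda))
}

# wind (u, v) at given timestamps and heights ASL, nearest profile hour,
# linear interpolation in geopotential height
echo_wind <- function(profiles, timestamps, z_asl) {
  n <- length(timestamps)
  if (n == 0L) return(list(u = numeric(0), v = numeric(0)))
  hours <- sort(unique(profiles$timestamp))
  byhr <- split(profiles, match(profiles$timestamp, hours))
  idx <- if (length(hours) == 1L) rep(1L, n) else
    findInterval(as.numeric(timestamps), as.numeric(hours), all.inside = TRUE)
  ## snap to nearest of the two bracketing hours
  nxt <- pmin(idx + 1L, length(hours))
  use_next <- abs(as.numeric(timestamps) - as.numeric(hours[nxt])) <
    abs(as.numeric(timestamps) - as.numeric(hours[idx]))
  idx[use_next] <- nxt[use_next]
  u <- v <- numeric(n)
  for (h in unique(idx)) {
    sel <- idx == h
    p <- byhr[[as.character(h)]]
    u[sel] <- approx(p$z_m, p$u_ms, xout = z_asl[sel], rule = 2)$y
    v[sel] <- approx(p$z_m, p$v_ms, xout = z_asl[sel], rule = 2)$y
  }
  list(u = u, v = v)
}

#' Simulate a full site-season (weather, nights, echoes, rain)
#'
#' @inheritParams generate_weather
#' @return list: `weather` (hourly profiles), `nights` (night windows),
#'   `echoes`, `truth`, `rain` (stacked over nights) and `intensity`
#'   (per-night expected migrant counts)
#' @export
simulate_site_season <- function(world, site, season, year) {
  season <- check_season(season)
  weather <- generate_weather(world, site, season, year)
  nights <- solar_nights(site$latitude, site$longitude,
                         season_dates(season, year))
  ech <- vector("list", nrow(nights))
  for (i in seq_len(nrow(nights)))
    ech[[i]] <- generate_night_echoes(world, site, nights[i, ], weather)
  list(
    weather = weather,
    nights = nights,
    echoes = do.call(rbind, lapply(ech, `[[`, "echoes")),
    truth = do.call(rbind, lapply(ech, `[[`, "truth")),
    rain = do.call(rbind, lapply(ech, `[[`, "rain")),
    intensity = data.frame(site_id = site$site_id,
                           night_id = nights$night_id,
                           season = season,
                           expected_migrants = vapply(ech, `[[`, 0, "intensity"))
  )
}

#' Simulate every configured site-season of a world
#'
#' @param world a [sim_world()]
#' @return list of stacked tables (`weather`, `nights`, `echoes`, `truth`,
#'   `rain`, `intensity`) plus `sites`, the site metadata as a data.frame
#' @export
simulate_world <- function(world) {
  parts <- list()
  for (site in world$sites)
    for (ss in world$seasons)
      parts[[length(parts) + 1L]] <-
        c(simulate_site_season(world, site, ss$season, ss$year),
          list(.site = site$site_id))
  stack <- function(name) {
    out <- do.call(rbind, lapply(parts, `[[`, name))
    rownames(out) <- NULL
    out
  }
  nights <- do.call(rbind, lapply(parts, function(p) {
    cbind(site_id = p$.site, p$nights)
  }))
  rownames(nights) <- NULL
  list(sites = sites_as_df(world$sites), nights = nights,
       weather = stack("weather"), echoes = stack("echoes"),
       truth = stack("truth"), rain = stack("rain"),
       intensity = stack("intensity"))
}

sites_as_df <- function(sites) {
  do.call(rbind, lapply(sites, function(s)
    data.frame(site_id = s$site_id, latitude = s$latitude,
               longitude = s$longitude, elevation = s$elevation,
               radar_type = s$radar_type,
               detection_efficiency = s$detection_efficiency,
               effective_transect_width_km = s$effective_transect_width_km,
               stringsAsFactors = FALSE)))
}
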