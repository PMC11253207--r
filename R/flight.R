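#' Tailwind component of the wind along a migration direction
#'
#' `TW = s cos(alpha_wind - alpha_migration)`: the projection of the wind
#' vector onto the mean migration direction. With `alpha_wind` stored as
#' the bearing the wind blows TOWARD (this package's convention), wind
#' aligned with migration gives `TW = +s` (tailwind) and opposing wind
#' `TW = -s` (headwind). Some meteorological sources state the same cosine
#' formula with a "from" bearing, which silently negates TW; set
#' `convention = "from"` to audit that reading.
#'
#' @param wind a [wind_vector()]
#' @param alpha_migration mean migration bearing, degrees
#' @param convention `"toward"` (default) or `"from"`: the sense in which
#'   the wind direction enters the cosine
#' @return tailwind component, m/s (positive supports migration)
#' @export
#' @examples
#' tailwind_component(wind_vector(3, 4), 0)  # 4 (the northward component)
tailwind_component <- function(wind, alpha_migration,
                               convention = c("toward", "from")) {
  convention <- match.arg(convention)
  aw <- wind$alpha_wind
  if (convention == "from") aw <- (aw + 180) %% 360
  wind$s * cos((aw - alpha_migration) * pi / 180)
}

#' Crosswind component (perpendicular to the migration direction)
#'
#' Signed: positive when the wind pushes to the right of the migration
#' direction.
#'
#' @inheritParams tailwind_component
#' @return crosswind component, m/s
#' @export
crosswind_component <- function(wind, alpha_migration) {
  unit <- bearing_to_uv(alpha_migration)
  wind$u * unit$v - wind$v * unit$u
}

#' Nightly groundspeed, tailwind and airspeed for one night
#'
#' The nightly groundspeed is the arithmetic mean of the night's bird track
#' ground speeds; nights with fewer than five tracks are excluded (return
#' `NULL`). The tailwind component is computed from the night's wind at the
#' reference flight level against the site-season mean migration direction,
#' and airspeed is `groundspeed - TW` — the scalar decomposition used for
#' season-level speed comparisons (it neglects the crosswind geometry; see
#' the methods vignette for the known sign of that bias).
#'
#' @param echoes filtered bird echoes of one site-night (uses
#'   `ground_speed_ms`)
#' @param night_id the night's identifier
#' @param wind the night's [wind_vector()] at the reference level, or `NULL`
#'   if missing (TW and airspeed then come back `NA`)
#' @param alpha_migration seasonal mean migration bearing for the site
#' @param season season label carried through
#' @param min_tracks minimum bird tracks for a usable night (default 5)
#' @return one-row data.frame (`site_id, night_id, season, n_tracks,
#'   groundspeed, alpha_migration, tw, airspeed`), or `NULL` when the night
#'   fails the track minimum
#' @export
nightly_airspeed <- function(echoes, night_id, wind, alpha_migration,
                             season = NA_character_, min_tracks = 5L) {
  n <- nrow(echoes)
  if (n < min_tracks) return(NULL)
  gs <- mean(echoes$ground_speed_ms)
  if (is.null(wind) || is.na(alpha_migration)) {
    tw <- NA_real_
  } else {
    tw <- tailwind_component(wind, alpha_migration)
  }
  data.frame(
    site_id = echoes$site_id[1], night_id = night_id, season = season,
    n_tracks = n, groundspeed = gs, alpha_migration = alpha_migration,
    tw = tw, airspeed = gs - tw, stringsAsFactors = FALSE)
}

#' Night-by-night flight decomposition for a site-season
#'
#' Computes the site-season mean migration direction (circular mean of all
#' filtered track directions, held fixed for every night), then builds one
#' [nightly_airspeed()] row per night with at least `min_tracks` tracks,
#' using each night's mean wind at the reference flight level from the
#' covariate table (`u`, `v_raw`).
#'
#' @param echoes filtered echo table for one site-season with `night_id`
#' @param covariates covariate table for the same site-season (provides
#'   nightly `u`, `v_raw`)
#' @param season season label
#' @param min_tracks minimum tracks per usable night
#' @return data.frame of nightly flight rows (possibly zero rows)
#' @export
flight_table <- function(echoes, covariates, season, min_tracks = 5L) {
  if (is.null(echoes) || nrow(echoes) == 0L)
    return(empty_flight_table())
  alpha_mig <- circular_mean_direction(echoes$track_direction_deg)
  rows <- list()
  for (nid in sort(unique(echoes$night_id))) {
    e <- echoes[echoes$night_id == nid, , drop = FALSE]
    cv <- covariates[covariates$night_id == nid, , drop = FALSE]
    wind <- if (nrow(cv) == 1L && is.finite(cv$u) && is.finite(cv$v_raw))
      wind_vector(cv$u, cv$v_raw) else NULL
    r <- nightly_airspeed(e, nid, wind, alpha_mig, season, min_tracks)
    if (!is.null(r)) rows[[length(rows) + 1L]] <- r
  }
  if (!length(rows)) return(empty_flight_table())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

empty_flight_table <- function() {
  data.frame(site_id = character(), night_id = character(),
             season = character(), n_tracks = integer(),
             groundspeed = numeric(), alpha_migration = numeric(),
             tw = numeric(), airspeed = numeric(), stringsAsFactors = FALSE)
}
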