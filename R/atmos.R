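#' Interpolate one atmospheric profile to a target height
#'
#' Linear interpolation in geopotential height, independently per variable,
#' at one site-hour. The target is normally the radar's elevation plus
#' 500 m — the reference flight level used for all nightly covariates.
#' Below the lowest level the lowest level's value is used (clamped);
#' likewise above the highest. Clamping is reported via the `"clamped"`
#' attribute.
#'
#' @param profile data.frame for one site-hour: columns `z_m` plus any of
#'   `t_c, u_ms, v_ms, rh_pct, w_pas, cc`; `z_m` must be strictly monotone
#'   (levels sorted by pressure)
#' @param target_m_asl target height, m above sea level
#' @return named list of interpolated values (one per variable present),
#'   with attribute `clamped` (TRUE if the target fell outside the profile)
#' @export
#' @examples
#' p <- data.frame(z_m = c(500, 1500), t_c = c(10, 0))
#' interp_to_height(p, 1000)$t_c  # 5
interp_to_height <- function(profile, target_m_asl) {
  if (nrow(profile) < 2L) stop("profile needs at least two levels")
  z <- profile$z_m
  ord <- order(z)
  z <- z[ord]
  if (any(diff(z) <= 0))
    stop("geopotential heights must be strictly monotone within a profile")
  vars <- intersect(c("t_c", "u_ms", "v_ms", "rh_pct", "w_pas", "cc"),
                    names(profile))
  out <- lapply(vars, function(v)
    approx(z, profile[[v]][ord], xout = target_m_asl, rule = 2)$y)
  names(out) <- vars
  attr(out, "clamped") <- target_m_asl < z[1] || target_m_asl > z[length(z)]
  out
}

#' Nightly atmospheric covariates at 500 m above a radar
#'
#' Interpolates each hourly profile inside the night window to
#' `site elevation + 500 m`, then averages over the night. The overall wind
#' speed `s` is the night mean of the hourly speeds `sqrt(u^2 + v^2)`
#' (computed before averaging the components, so variable wind directions
#' do not deflate it). The north-south component `v` is sign-flipped in
#' autumn so that positive always means wind blowing in the migration
#' direction; the raw northward component is kept as `v_raw`.
#' Night-over-night deltas are `NA` on a season's first night.
#'
#' @param profiles hourly long-format profile table for the site (columns as
#'   in [generate_weather()])
#' @param night a `night_window` row
#' @param site a [site_config()] or one-row site metadata data.frame
#' @param season `"spring"` or `"autumn"`
#' @param previous the previous night's covariate row (or `NULL`)
#' @return one-row data.frame with the 15 modelling covariates:
#'   temperature, u, v (rotated), relative_humidity, vertical_velocity,
#'   cloud_cover, wind_speed, d_temperature, d_u, d_v, latitude, longitude,
#'   elevation, ordinal_date, radar_type (plus `site_id`, `night_id`,
#'   `season`, `v_raw`)
#' @export
nightly_covariates <- function(profiles, night, site, season,
                               previous = NULL) {
  season <- check_season(season)
  target <- site$elevation + 500
  p <- profiles[profiles$timestamp >= night$sunset &
                  profiles$timestamp <= night$sunrise, , drop = FALSE]
  if (nrow(p) == 0L)
    stop("no profiles inside night window ", night$night_id)
  byhr <- split(p, match(p$timestamp, unique(p$timestamp)))
  h <- vapply(byhr, function(hh) {
    iv <- interp_to_height(hh, target)
    c(iv$t_c, iv$u_ms, iv$v_ms, iv$rh_pct, iv$w_pas, iv$cc,
      sqrt(iv$u_ms^2 + iv$v_ms^2))
  }, numeric(7))
  m <- rowMeans(h)
  v_raw <- m[3]
  sign_v <- if (season == "autumn") -1 else 1
  out <- data.frame(
    site_id = site$site_id, night_id = night$night_id, season = season,
    temperature = m[1], u = m[2], v = sign_v * v_raw, v_raw = v_raw,
    relative_humidity = m[4], vertical_velocity = m[5], cloud_cover = m[6],
    wind_speed = m[7],
    d_temperature = NA_real_, d_u = NA_real_, d_v = NA_real_,
    latitude = site$latitude, longitude = site$longitude,
    elevation = site$elevation,
    ordinal_date = as.integer(strftime(as.Date(night$night_id), "%j")),
    radar_type = site$radar_type,
    stringsAsFactors = FALSE
  )
  if (!is.null(previous) && nrow(previous) == 1L) {
    out$d_temperature <- out$temperature - previous$temperature
    out$d_u <- out$u - previous$u
    out$d_v <- out$v - previous$v
  }
  out
}

#' Covariate table for a whole site-season
#'
#' Runs [nightly_covariates()] over consecutive nights, chaining the
#' previous night for the delta covariates.
#'
#' @inheritParams nightly_covariates
#' @param nights data.frame of `night_window` rows (consecutive evenings)
#' @return data.frame, one row per night
#' @export
season_covariates <- function(profiles, nights, site, season) {
  prev <- NULL
  out <- vector("list", nrow(nights))
  for (i in seq_len(nrow(nights))) {
    row <- nightly_covariates(profiles, nights[i, ], site, season, prev)
    out[[i]] <- row
    prev <- row
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Screen pairwise Pearson correlations among predictors
#'
#' Computes all pairwise Pearson correlations among the numeric predictor
#' columns and flags pairs at or above the threshold. Nothing is dropped:
#' the screen documents collinearity, the modelling keeps all covariates.
#' Constant columns have undefined correlations and are reported as such.
#'
#' @param table modelling data.frame
#' @param predictors column names to include (default: all numeric columns)
#' @param threshold flag pairs with `|r| >= threshold` (default 0.7)
#' @return list with `correlations` (matrix), `flagged` (data.frame of
#'   offending pairs) and `constant` (names of zero-variance columns)
#' @export
correlation_screen <- function(table, predictors = NULL, threshold = 0.7) {
  if (is.null(predictors))
    predictors <- names(table)[vapply(table, is.numeric, TRUE)]
  x <- table[predictors]
  if (sum(stats::complete.cases(x)) < 3L)
    stop("need at least 3 complete rows for a correlation screen")
  constant <- predictors[vapply(x, function(col)
    var(col, na.rm = TRUE) == 0 || all(is.na(col)), TRUE)]
  cm <- suppressWarnings(cor(x, use = "pairwise.complete.obs",
                             method = "pearson"))
  ut <- which(upper.tri(cm) & abs(cm) >= threshold & !is.na(cm),
              arr.ind = TRUE)
  flagged <- data.frame(
    var1 = rownames(cm)[ut[, 1]], var2 = colnames(cm)[ut[, 2]],
    r = cm[ut], stringsAsFactors = FALSE)
  list(correlations = cm, flagged = flagged, constant = constant,
       threshold = threshold)
}
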