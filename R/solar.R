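#' Compute the biological night (sunset to next sunrise) at a site
#'
#' Sunset and sunrise are computed with the NOAA solar-position equations
#' (Fourier-series equation of time and solar declination) at a solar
#' elevation of -0.833 degrees, i.e. the refraction-corrected moment the
#' upper edge of the solar disk crosses the horizon. The night is keyed to
#' the calendar date of its evening: `solar_night(lat, lon, "2018-04-15")`
#' runs from sunset on 15 April to sunrise on 16 April, both UTC.
#'
#' Polar latitudes (beyond ~66 degrees) where the sun may not rise or set
#' are rejected: the method targets mid-latitude migration corridors.
#'
#' @param lat latitude, decimal degrees (positive north); must satisfy
#'   `abs(lat) < 66`
#' @param lon longitude, decimal degrees (positive east)
#' @param date evening calendar date (`Date` or "YYYY-MM-DD" string)
#' @return a one-row data.frame of class `night_window` with columns
#'   `night_id` (the evening date), `sunset`, `sunrise` (POSIXct UTC) and
#'   `duration_h`
#' @export
#' @examples
#' solar_night(32.79, 34.99, "2018-04-15")
solar_night <- function(lat, lon, date) {
  if (abs(lat) >= 66)
    stop("solar_night() does not support polar-circle latitudes (|lat| >= 66)")
  date <- as.Date(date)
  sunset <- solar_event_utc(lat, lon, date, rise = FALSE)
  sunrise <- solar_event_utc(lat, lon, date + 1, rise = TRUE)
  out <- data.frame(
    night_id = format(date),
    sunset = sunset,
    sunrise = sunrise,
    duration_h = as.numeric(difftime(sunrise, sunset, units = "hours")),
    stringsAsFactors = FALSE
  )
  class(out) <- c("night_window", class(out))
  out
}

# One solar event (sunrise or sunset) on a given UTC calendar date.
# NOAA low-accuracy algorithm: fractional year -> equation of time and
# declination as truncated Fourier series, then the hour angle at zenith
# 90.833 degrees. Iterated twice so the fractional year is evaluated at the
# event time itself.
solar_event_utc <- function(lat, lon, date, rise) {
  doy <- as.integer(strftime(date, format = "%j", tz = "UTC"))
  rad <- pi / 180
  minutes <- 720 - 4 * lon  # first guess: local solar noon
  for (i in 1:3) {
    gamma <- 2 * pi / 365 * (doy - 1 + (minutes / 60 - 12) / 24)
    eqtime <- 229.18 * (0.000075 + 0.001868 * cos(gamma) - 0.032077 * sin(gamma)
                        - 0.014615 * cos(2 * gamma) - 0.040849 * sin(2 * gamma))
    decl <- 0.006918 - 0.399912 * cos(gamma) + 0.070257 * sin(gamma) -
      0.006758 * cos(2 * gamma) + 0.000907 * sin(2 * gamma) -
      0.002697 * cos(3 * gamma) + 0.00148 * sin(3 * gamma)
    cos_ha <- cos(90.833 * rad) / (cos(lat * rad) * cos(decl)) -
      tan(lat * rad) * tan(decl)
    if (cos_ha > 1 || cos_ha < -1)
      stop("sun does not cross the horizon at this latitude and date")
    ha <- acos(cos_ha) / rad
    if (!rise) ha <- -ha
    minutes <- 720 - 4 * (lon + ha) - eqtime
  }
  as_utc(as.POSIXct(as.numeric(as.POSIXct(date, tz = "UTC")) + minutes * 60,
                    origin = "1970-01-01", tz = "UTC"))
}

#' Night windows for a span of evening dates
#'
#' @param lat,lon site coordinates, decimal degrees
#' @param dates vector of evening dates
#' @return data.frame with one `night_window` row per date
#' @export
solar_nights <- function(lat, lon, dates) {
  dates <- as.Date(dates)
  out <- do.call(rbind, lapply(dates, function(d) solar_night(lat, lon, d)))
  rownames(out) <- NULL
  out
}
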