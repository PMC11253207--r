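#' Convert a bearing and speed to eastward/northward components
#'
#' Directions in this package are geographic bearings: degrees clockwise from
#' north, in the "toward" sense. A bearing of 0 means moving toward the
#' north, 90 toward the east. This is the single conversion used everywhere;
#' no other code does bearing trigonometry directly.
#'
#' @param bearing_deg bearing in degrees clockwise from north ("toward")
#' @param speed speed (any unit); defaults to 1 for a unit vector
#' @return list with components `u` (eastward) and `v` (northward)
#' @seealso [uv_to_bearing()]
#' @export
#' @examples
#' bearing_to_uv(90, 5)  # due east: u = 5, v = 0
bearing_to_uv <- function(bearing_deg, speed = 1) {
  th <- bearing_deg * pi / 180
  list(u = speed * sin(th), v = speed * cos(th))
}

#' Convert eastward/northward components to a "toward" bearing
#'
#' @param u eastward component (m/s)
#' @param v northward component (m/s)
#' @return bearing in degrees clockwise from north, in `[0, 360)`
#' @export
uv_to_bearing <- function(u, v) {
  b <- (atan2(u, v) * 180 / pi) %% 360
  ## floating-point wraparound: a tiny negative angle lands on exactly 360
  ifelse(b >= 360, 0, b)
}

#' Wind vector with polar and component representations
#'
#' Builds a wind vector from its eastward (`u`) and northward (`v`)
#' components. The stored direction `alpha_wind` is the bearing the wind
#' blows TOWARD, so that a wind aligned with the migration direction has a
#' positive tailwind component under [tailwind_component()]. The
#' meteorological "from" bearing is `(alpha_wind + 180) %% 360`.
#'
#' @param u eastward wind component, m/s
#' @param v northward wind component, m/s
#' @return object of class `wind_vector`: list with `u`, `v`, speed `s` and
#'   `alpha_wind` (toward bearing, degrees)
#' @export
#' @examples
#' w <- wind_vector(3, 4)
#' w$s          # 5
#' w$alpha_wind # 36.87 (toward NE)
wind_vector <- function(u, v) {
  stopifnot(is.finite(u), is.finite(v))
  structure(
    list(u = u, v = v, s = sqrt(u^2 + v^2), alpha_wind = uv_to_bearing(u, v)),
    class = "wind_vector"
  )
}

#' @export
print.wind_vector <- function(x, ...) {
  cat(sprintf("wind_vector: u = %.2f, v = %.2f m/s (s = %.2f, toward %.1f deg)\n",
              x$u, x$v, x$s, x$alpha_wind))
  invisible(x)
}

#' Circular mean of a sample of bearings
#'
#' The direction of the vector mean of unit vectors: atan2 of the mean sine
#' and cosine components, mapped to `[0, 360)`. Used for the seasonal mean
#' migration direction per radar site.
#'
#' @param directions_deg bearings in degrees
#' @param na.rm drop missing values first
#' @return mean bearing in degrees, or `NA` (with a warning) when the mean
#'   resultant length is numerically zero (a perfectly balanced sample has no
#'   defined mean direction)
#' @export
#' @examples
#' circular_mean_direction(c(350, 10))  # 0
circular_mean_direction <- function(directions_deg, na.rm = TRUE) {
  if (na.rm) directions_deg <- directions_deg[!is.na(directions_deg)]
  if (length(directions_deg) == 0L) return(NA_real_)
  th <- directions_deg * pi / 180
  ms <- mean(sin(th)); mc <- mean(cos(th))
  if (sqrt(ms^2 + mc^2) < 1e-12) {
    warning("zero resultant length: mean direction undefined")
    return(NA_real_)
  }
  uv_to_bearing(ms, mc)
}

#' Mean resultant length of a sample of bearings
#'
#' Circular concentration measure in `[0, 1]`; 1 when all directions agree.
#'
#' @param directions_deg bearings in degrees
#' @return mean resultant length
#' @export
mean_resultant_length <- function(directions_deg) {
  directions_deg <- directions_deg[!is.na(directions_deg)]
  if (length(directions_deg) == 0L) return(NA_real_)
  th <- directions_deg * pi / 180
  sqrt(mean(sin(th))^2 + mean(cos(th))^2)
}
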