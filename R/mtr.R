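#' Migration traffic rate per elevation bin
#'
#' MTR is the number of birds crossing a theoretical 1 km transect
#' perpendicular to the movement direction per hour (birds km^-1 h^-1).
#' Each detected echo is one transect crossing, so the per-bin rate is
#' `n_bin / (width_km(bin) x window_hours)`.
#'
#' @param echoes filtered echo data.frame (uses `altitude_agl_m`)
#' @param bin_edges altitude bin edges, m AGL (bins are `[e_i, e_{i+1})`,
#'   last bin closed)
#' @param transect_width_km effective transect width per bin, km (scalar or
#'   one per bin); must be positive
#' @param window_hours observation window length, hours (> 0)
#' @return numeric vector of MTR per bin (birds km^-1 h^-1)
#' @export
#' @examples
#' # 50 echoes in one 0.5 km-wide bin over 5 h -> 20 birds/km/h
mtr_per_bin <- function(echoes, bin_edges, transect_width_km = 1,
                        window_hours) {
  stopifnot(length(bin_edges) >= 2, !is.unsorted(bin_edges))
  if (window_hours <= 0) stop("window_hours must be positive")
  nb <- length(bin_edges) - 1L
  width <- rep_len(transect_width_km, nb)
  if (any(width <= 0)) stop("transect widths must be positive")
  alt <- echoes$altitude_agl_m
  alt <- alt[!is.na(alt) & alt >= bin_edges[1] & alt <= bin_edges[nb + 1L]]
  ## [e_i, e_{i+1}) bins, last bin closed at the top edge
  idx <- findInterval(alt, bin_edges, rightmost.closed = TRUE)
  counts <- tabulate(idx, nbins = nb)
  counts / (width * window_hours)
}

#' Nightly MTR from an hours-by-bins rate matrix
#'
#' For each hour the per-bin rates are summed over elevation bins; the
#' nightly value is the mean over hours. Hours flagged as fully covered by
#' rain are excluded from the mean.
#'
#' @param hourly_mtr matrix (hours x bins) of MTR values
#' @param exclude logical vector marking hours to drop (e.g. fully rainy)
#' @return scalar nightly MTR, or `NA` (with a warning) when no valid hour
#'   remains
#' @export
nightly_mtr <- function(hourly_mtr, exclude = NULL) {
  hourly_mtr <- rbind(hourly_mtr)  # tolerate a single-hour vector
  if (!is.null(exclude)) hourly_mtr <- hourly_mtr[!exclude, , drop = FALSE]
  if (nrow(hourly_mtr) == 0L) {
    warning("night has no valid hours: nightly MTR is missing")
    return(NA_real_)
  }
  mean(rowSums(hourly_mtr))
}

#' Rayleigh-test directional proportion of a direction sample
#'
#' Computes the mean resultant length \eqn{\bar R} of the track directions,
#' the Rayleigh statistic \eqn{Z = n \bar R^2} and the standard published
#' approximation to the Rayleigh p-value,
#' \deqn{p = \exp(\sqrt{1 + 4n + 4(n^2 - R^2)} - (1 + 2n)),}
#' with \eqn{R = n \bar R} the resultant length. The directional proportion
#' used to correct MTR for local, non-directional movement is \eqn{\bar R}
#' when the test rejects uniformity at `alpha`, and 0 otherwise: under a
#' mixture of a common-direction point mass (weight f) and uniform noise,
#' \eqn{\bar R} estimates f.
#'
#' @param track_directions_deg bearings in degrees
#' @param alpha significance level of the uniformity test (default 0.05)
#' @return list with `n`, `mean_resultant_length`, `rayleigh_z`,
#'   `rayleigh_p` and `proportion`; all `NA` when no directions are given
#' @export
directional_proportion <- function(track_directions_deg, alpha = 0.05) {
  d <- track_directions_deg[!is.na(track_directions_deg)]
  n <- length(d)
  if (n == 0L)
    return(list(n = 0L, mean_resultant_length = NA_real_,
                rayleigh_z = NA_real_, rayleigh_p = NA_real_,
                proportion = NA_real_))
  rbar <- mean_resultant_length(d)
  z <- n * rbar^2
  R <- n * rbar
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - R^2)) - (1 + 2 * n))
  p <- min(max(p, 0), 1)
  list(n = n, mean_resultant_length = rbar, rayleigh_z = z,
       rayleigh_p = p,
       proportion = if (p < alpha) rbar else 0)
}

#' Per-night MTR profile with directionality correction
#'
#' The night is cut into clock hours anchored at sunset (the final partial
#' hour keeps its true duration). Per hour and altitude bin the traffic
#' rate is computed with [mtr_per_bin()]; hours fully covered by rain are
#' excluded; the nightly MTR is the hour-mean of bin sums. The Rayleigh
#' directional proportion of the night's track directions then scales the
#' nightly MTR to its directional part.
#'
#' @param echoes filtered echo data.frame for one site-night
#' @param night the `night_window` row
#' @param bin_edges altitude bin edges, m AGL; default 50 m bins over
#'   50-1500 m
#' @param transect_width_km transect width per bin, km
#' @param rain merged rain intervals for the night (used only to exclude
#'   fully rainy hours; rainy echoes are assumed already filtered)
#' @param alpha Rayleigh significance level
#' @return one-row data.frame: `site_id, night_id, n_echoes, nightly_mtr,
#'   mean_resultant_length, rayleigh_p, directional_proportion,
#'   directional_mtr`
#' @export
mtr_profile <- function(echoes, night, bin_edges = seq(50, 1500, by = 50),
                        transect_width_km = 1, rain = NULL, alpha = 0.05) {
  hours <- night_hours(night)
  if (!is.null(rain) && nrow(rain) > 0L) rain <- merge_rain_intervals(rain)
  rates <- matrix(0, nrow(hours), length(bin_edges) - 1L)
  excl <- rep(FALSE, nrow(hours))
  for (i in seq_len(nrow(hours))) {
    h0 <- hours$start[i]; h1 <- hours$end[i]
    dur <- as.numeric(h1 - h0, units = "hours")
    if (!is.null(rain) && nrow(rain) > 0L)
      excl[i] <- any(rain$start <= h0 & rain$end >= h1)
    sel <- echoes$timestamp >= h0 &
      (if (i == nrow(hours)) echoes$timestamp <= h1 else echoes$timestamp < h1)
    rates[i, ] <- mtr_per_bin(echoes[sel, , drop = FALSE], bin_edges,
                              transect_width_km, dur)
  }
  m <- nightly_mtr(rates, exclude = excl)
  dp <- directional_proportion(echoes$track_direction_deg, alpha = alpha)
  data.frame(
    site_id = if (nrow(echoes)) echoes$site_id[1] else NA_character_,
    night_id = night$night_id,
    n_echoes = nrow(echoes),
    nightly_mtr = m,
    mean_resultant_length = dp$mean_resultant_length,
    rayleigh_p = dp$rayleigh_p,
    directional_proportion = dp$proportion,
    directional_mtr = if (is.na(m)) NA_real_
                      else if (nrow(echoes) == 0L) 0
                      else dp$proportion * m,
    stringsAsFactors = FALSE
  )
}

# clock hours anchored at sunset; last interval clipped at sunrise
night_hours <- function(night) {
  starts <- seq(from = night$sunset, to = night$sunrise, by = 3600)
  if (starts[length(starts)] >= night$sunrise)
    starts <- starts[-length(starts)]
  ends <- pmin(starts + 3600, night$sunrise)
  data.frame(start = starts, end = ends)
}
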