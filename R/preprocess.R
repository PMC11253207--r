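#' Merge overlapping rain intervals
#'
#' Rain intervals are half-open `[start, end)`. Overlapping or touching
#' intervals are merged into maximal disjoint intervals.
#'
#' @param rain data.frame with POSIXct columns `start`, `end`
#' @return data.frame with disjoint, sorted intervals
#' @export
merge_rain_intervals <- function(rain) {
  if (is.null(rain) || nrow(rain) == 0L) return(rain)
  stopifnot(all(rain$end > rain$start))
  rain <- rain[order(rain$start), , drop = FALSE]
  start <- rain$start[1]; end <- rain$end[1]
  out_s <- c(); out_e <- c()
  for (i in seq_len(nrow(rain))[-1]) {
    if (rain$start[i] <= end) {
      end <- max(end, rain$end[i])
    } else {
      out_s <- c(out_s, start); out_e <- c(out_e, end)
      start <- rain$start[i]; end <- rain$end[i]
    }
  }
  out_s <- c(out_s, start); out_e <- c(out_e, end)
  data.frame(start = as_utc(as.POSIXct(out_s, origin = "1970-01-01", tz = "UTC")),
             end = as_utc(as.POSIXct(out_e, origin = "1970-01-01", tz = "UTC")))
}

#' Filter one night of radar echoes
#'
#' Applies, in order, the filters used before any traffic-rate or speed
#' computation:
#' \enumerate{
#'   \item night window: timestamp within `[sunset, sunrise]` (closed);
#'   \item rain: not inside any rain interval (`[start, end)`, after
#'     merging overlaps);
#'   \item class: `is_bird` must be `TRUE` (the upstream echo-signature
#'     classification is trusted);
#'   \item altitude/pulse-mode window: short-pulse echoes kept at
#'     `[50, 800)` m AGL (small birds are not detectable below 50 m or,
#'     under short pulse, above 800 m), long-pulse echoes at
#'     `[800, 1500]` m AGL. Echoes with missing altitude are dropped.
#' }
#' Filtering is idempotent and never mutates a field; counts removed per
#' filter are attached as attribute `"qc"`.
#'
#' @param echoes echo data.frame (see [generate_night_echoes()] for columns)
#' @param night a `night_window` row
#' @param rain data.frame of rain events (`start`, `end`), possibly empty
#' @return the retained subset of `echoes`, with a `qc` attribute listing
#'   counts removed by each filter
#' @export
filter_echoes <- function(echoes, night, rain = NULL) {
  n0 <- nrow(echoes)
  keep <- echoes$timestamp >= night$sunset & echoes$timestamp <= night$sunrise
  n_night <- sum(!keep)
  e <- echoes[keep, , drop = FALSE]

  n_rain <- 0L
  if (!is.null(rain) && nrow(rain) > 0L) {
    rain <- merge_rain_intervals(rain)
    in_rain <- rep(FALSE, nrow(e))
    for (i in seq_len(nrow(rain)))
      in_rain <- in_rain |
        (e$timestamp >= rain$start[i] & e$timestamp < rain$end[i])
    n_rain <- sum(in_rain)
    e <- e[!in_rain, , drop = FALSE]
  }

  n_class <- sum(!e$is_bird)
  e <- e[e$is_bird, , drop = FALSE]

  alt <- e$altitude_agl_m
  n_na_alt <- sum(is.na(alt))
  in_window <- !is.na(alt) & ifelse(
    e$pulse_mode == "short",
    alt >= 50 & alt < 800,
    alt >= 800 & alt <= 1500)
  n_alt <- sum(!in_window) - n_na_alt
  e <- e[in_window, , drop = FALSE]
  rownames(e) <- NULL

  attr(e, "qc") <- list(
    n_in = n0, n_out = nrow(e),
    removed_outside_night = n_night, removed_rain = n_rain,
    removed_nonbird = n_class, removed_missing_altitude = n_na_alt,
    removed_altitude_window = n_alt)
  e
}

#' Assign echoes to biological nights and filter each night
#'
#' Computes night windows for every evening date in `dates` at the site,
#' assigns echoes to the night whose window contains them and applies
#' [filter_echoes()] per night with that site's rain log.
#'
#' @param echoes echo table for one site
#' @param site a [site_config()] or one-row site metadata data.frame
#' @param dates evening dates to build nights for
#' @param rain rain log (`site_id`, `start`, `end`)
#' @return list with `echoes` (filtered, plus a `night_id` column) and `qc`
#'   (one row of removal counts per night)
#' @export
preprocess_site <- function(echoes, site, dates, rain = NULL) {
  nights <- solar_nights(site$latitude, site$longitude, dates)
  out <- vector("list", nrow(nights)); qc <- vector("list", nrow(nights))
  for (i in seq_len(nrow(nights))) {
    w <- nights[i, ]
    sel <- echoes$timestamp >= w$sunset & echoes$timestamp <= w$sunrise
    f <- filter_echoes(echoes[sel, , drop = FALSE], w, rain)
    q <- attr(f, "qc")
    if (nrow(f)) f$night_id <- w$night_id
    out[[i]] <- f
    qc[[i]] <- data.frame(site_id = site$site_id, night_id = w$night_id,
                          as.data.frame(q), stringsAsFactors = FALSE)
  }
  list(echoes = do.call(rbind, out[vapply(out, nrow, 0L) > 0]),
       nights = nights,
       qc = do.call(rbind, qc))
}
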