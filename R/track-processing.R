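# Cleaning and daily regularization of satellite-tag position data.
#
# Raw Argos fixes carry a location class (3, 2, 1, 0, A, B, Z); class Z is a
# failed position attempt and is dropped. Remaining fixes pass through a
# point-to-point great-circle speed filter, are collapsed to one position per
# calendar day, and gaps are interpolated along the great circle -- except
# that gaps longer than 20 days split the track into segments.

#' Drop location-class Z positions
#'
#' @param positions data.frame with at least `timestamp`, `lon`, `lat`, and
#'   optionally `location_class`. Rows with class `"Z"` are removed; if the
#'   column is absent (e.g. geolocation-derived positions) the input is
#'   returned unchanged.
#' @return The filtered data.frame, original order preserved.
#' @export
drop_class_z <- function(positions) {
  if (!"location_class" %in% names(positions)) return(positions)
  keep <- is.na(positions$location_class) | positions$location_class != "Z"
  positions[keep, , drop = FALSE]
}

#' Greedy forward speed filter
#'
#' Walks the track forward, dropping any fix whose great-circle speed from
#' the last retained fix exceeds `max_speed`. The first fix is always kept,
#' so no retained consecutive pair exceeds the limit.
#'
#' @param positions data.frame with `timestamp` (POSIXct, strictly
#'   increasing), `lon`, `lat`.
#' @param max_speed Maximum plausible speed in m/s (default 3).
#' @return The filtered data.frame.
#' @export
speed_filter <- function(positions, max_speed = 3) {
  n <- nrow(positions)
  if (n <= 1) return(positions)
  tt <- as.numeric(positions$timestamp)
  if (any(diff(tt) <= 0)) stop("timestamps must be strictly increasing")
  keep <- logical(n)
  keep[1] <- TRUE
  last <- 1L
  for (i in 2:n) {
    d_m <- gc_distance_km(positions$lon[last], positions$lat[last],
                          positions$lon[i], positions$lat[i]) * 1000
    dt_s <- tt[i] - tt[last]
    if (d_m / dt_s <= max_speed) {
      keep[i] <- TRUE
      last <- i
    }
  }
  positions[keep, , drop = FALSE]
}

#' Regularize a filtered track to one position per day
#'
#' Each calendar day with at least one fix gets the centroid of that day's
#' fixes. Runs of missing days of length `<= max_gap_days` are filled by
#' great-circle interpolation between the flanking daily positions; longer
#' runs split the track into a new segment (a gap of exactly `max_gap_days`
#' is still interpolated).
#'
#' @param positions data.frame with `timestamp`, `lon`, `lat` and optionally
#'   `animal_id`, already speed-filtered.
#' @param max_gap_days Largest interpolatable gap, in days (default 20).
#' @return data.frame of class `shark_track` with columns `animal_id`,
#'   `segment`, `date`, `lon`, `lat`; consecutive dates within a segment
#'   differ by exactly one day.
#' @export
regularize_daily <- function(positions, max_gap_days = 20) {
  id <- if ("animal_id" %in% names(positions) && nrow(positions) > 0)
    positions$animal_id[1] else "A1"
  if (nrow(positions) == 0) {
    out <- data.frame(animal_id = character(), segment = integer(),
                      date = as.Date(character()), lon = numeric(),
                      lat = numeric())
    class(out) <- c("shark_track", "data.frame")
    return(out)
  }
  day <- as.Date(positions$timestamp, tz = "UTC")
  daily <- aggregate(cbind(lon, lat) ~ day,
                     data = data.frame(day = day, lon = positions$lon,
                                       lat = positions$lat),
                     FUN = mean)
  daily <- daily[order(daily$day), ]
  gaps <- c(1, as.numeric(diff(daily$day)))
  seg_id <- cumsum(gaps > max_gap_days + 1) + 1L

  rows <- vector("list", nrow(daily))
  for (i in seq_len(nrow(daily))) {
    rows[[i]] <- data.frame(segment = seg_id[i], date = daily$day[i],
                            lon = daily$lon[i], lat = daily$lat[i])
    if (i < nrow(daily) && seg_id[i + 1] == seg_id[i] && gaps[i + 1] > 1) {
      n_fill <- gaps[i + 1] - 1
      p <- gc_intermediate(daily$lon[i], daily$lat[i],
                           daily$lon[i + 1], daily$lat[i + 1], n_fill)
      rows[[i]] <- rbind(rows[[i]],
                         data.frame(segment = seg_id[i],
                                    date = daily$day[i] + seq_len(n_fill),
                                    lon = p[, "lon"], lat = p[, "lat"]))
    }
  }
  out <- do.call(rbind, rows)
  out <- cbind(animal_id = id, out)
  rownames(out) <- NULL
  class(out) <- c("shark_track", "data.frame")
  out
}
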