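# Shared fixtures for the suite. Environments are generated once per session
# and memoized; everything is seeded and reproducible.

.fixture_cache <- new.env(parent = emptyenv())

# standard small OMZ environment (0.5-degree grid, basin-scale OMZ)
small_env <- function() {
  if (is.null(.fixture_cache$env))
    .fixture_cache$env <- gen_env_field(env_grid_spec(
      lon_range = c(-30, -10), lat_range = c(2, 22),
      horizontal_resolution = 0.5))
  .fixture_cache$env
}

# compact OMZ patch: small relative to a 90-day walk's diffusion length, so
# the residency null model has power and can be calibrated
patch_env <- function() {
  if (is.null(.fixture_cache$patch))
    .fixture_cache$patch <- gen_env_field(env_grid_spec(
      lon_range = c(-30, -10), lat_range = c(2, 22),
      horizontal_resolution = 0.5, omz_radius = 3))
  .fixture_cache$patch
}

# raw positions helper
raw_positions <- function(lon, lat, hours, classes = NULL,
                          t0 = as.POSIXct("2017-06-01 00:00:00", tz = "UTC")) {
  df <- data.frame(timestamp = t0 + hours * 3600, lon = lon, lat = lat)
  if (!is.null(classes)) df$location_class <- classes
  df
}

# explicit V-shaped ping track (no noise): out `leg` km at `out_head`, turn
# of the given heading deviation, back to `endpoint_gap` km from the start
v_track <- function(leg = 90, out_head = 10, deviation = 173,
                    endpoint_gap = 2, spacing = 7, lead_km = 120,
                    start = c(-25, 10), vessel_id = "VX") {
  t0 <- as.POSIXct("2010-03-01 00:00:00", tz = "UTC")
  pts <- matrix(start, ncol = 2)
  add <- function(bearing, len) {
    d <- seq(spacing, len, by = spacing)
    if (length(d) == 0 || d[length(d)] < len) d <- c(d, len)
    from <- pts[nrow(pts), ]
    pts <<- rbind(pts, gc_destination(from[1], from[2], bearing, d))
  }
  add(out_head, lead_km)                     # approach transit
  v_start <- pts[nrow(pts), ]
  add(out_head, leg)                         # outbound deployment
  apex <- pts[nrow(pts), ]
  back_head <- (out_head + 180 - (180 - deviation)) %% 360
  end_pt <- gc_destination(v_start[1], v_start[2],
                           stats::runif(1, 0, 360), endpoint_gap)
  # haul toward a point near the V start, at the requested turn deviation
  if (deviation >= 170) {
    add(gc_bearing(apex[1], apex[2], end_pt[1], end_pt[2]),
        gc_distance_km(apex[1], apex[2], end_pt[1], end_pt[2]))
  } else {
    add(back_head, leg)
  }
  add((back_head + 20) %% 360, lead_km)      # departure transit
  n <- nrow(pts)
  data.frame(vessel_id = vessel_id, timestamp = t0 + (0:(n - 1)) * 3600,
             lon = pts[, 1], lat = pts[, 2])
}

# match detected sets against ground truth by apex proximity
detector_score <- function(detected, truth, tol_km = 25) {
  matched <- rep(FALSE, nrow(truth))
  used <- rep(FALSE, nrow(detected))
  if (nrow(detected) > 0) for (k in seq_len(nrow(truth))) {
    d <- gc_distance_km(detected$turn_lon, detected$turn_lat,
                        truth$turn_lon[k], truth$turn_lat[k])
    hit <- which(d <= tol_km & !used)
    if (length(hit) > 0) {
      matched[k] <- TRUE
      used[hit[which.min(d[hit])]] <- TRUE
    }
  }
  c(tp = sum(matched), fp = sum(!used), fn = sum(!matched))
}
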