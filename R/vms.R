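# Vessel-monitoring-system analysis: synthetic longliner trips, detection of
# V-shaped longline deployments from GPS pings, 1-degree effort and
# intensity grids, and OMZ-vs-normoxic comparisons.
#
# Detection geometry: a longline deployment traces a 'V' -- the vessel steams
# out 80-100 km laying the line, turns sharply (heading deviation from
# straight-ahead well above 130 degrees), and retraces toward the start to
# haul. The detector scans interior pings for such near-reversals, walks the
# track backward/forward from the turn until the accumulated along-track
# distance exceeds the line length, and accepts the candidate only if the
# two walk endpoints are close together (a proper V).

#' Behavioural specification for the synthetic vessel generator
#'
#' @param longline_length_range Line length draw range, km (within 80-100).
#' @param ping_interval GPS ping interval, hours.
#' @param soak_hours Soak time at the apex between deployment and haul.
#' @param transit_speed,deployment_speed Speeds, km/h.
#' @param endpoint_jitter Max distance (km) between deployment start and
#'   haul end.
#' @param ping_noise_km GPS position noise SD, km (VMS positions are
#'   accurate to a few hundred metres).
#' @param n_sets_per_trip Longline sets per trip (`>= 0`).
#' @param transit_leg_km Typical distance steamed between sets.
#' @param seed Integer seed.
#' @return List of class `vessel_behavior_spec`.
#' @export
vessel_behavior_spec <- function(longline_length_range = c(80, 100),
                                 ping_interval = 1, soak_hours = 8,
                                 transit_speed = 15, deployment_speed = 7,
                                 endpoint_jitter = 4, ping_noise_km = 0.15,
                                 n_sets_per_trip = 3, transit_leg_km = 180,
                                 seed = 1L) {
  stopifnot(longline_length_range[1] >= 80, longline_length_range[2] <= 100,
            longline_length_range[1] <= longline_length_range[2],
            ping_interval > 0, transit_speed > 0, deployment_speed > 0,
            soak_hours >= 0, n_sets_per_trip >= 0)
  structure(list(longline_length_range = longline_length_range,
                 ping_interval = ping_interval, soak_hours = soak_hours,
                 transit_speed = transit_speed,
                 deployment_speed = deployment_speed,
                 endpoint_jitter = endpoint_jitter,
                 ping_noise_km = ping_noise_km,
                 n_sets_per_trip = n_sets_per_trip,
                 transit_leg_km = transit_leg_km, seed = as.integer(seed)),
            class = "vessel_behavior_spec")
}

# Append pings along a leg from `from` on `bearing` over `length_km` at
# `speed`; returns the exact leg end (noise is added later, all at once).
leg_points <- function(from, bearing, length_km, speed, interval_h) {
  step <- speed * interval_h
  d <- seq(step, length_km, by = step)
  if (length(d) == 0) d <- length_km
  else if (d[length(d)] < length_km - 0.2 * step) d <- c(d, length_km)
  else d[length(d)] <- length_km # avoid a near-duplicate final ping
  p <- gc_destination(from[1], from[2], bearing, d)
  list(points = p, hours = d / speed)
}

#' Generate a synthetic longliner trip with ground-truth sets
#'
#' Pings at the spec interval containing `n_sets_per_trip` true V-shaped
#' deployments (outbound leg of the drawn line length, near-reversal at the
#' apex, inbound leg to within `endpoint_jitter` of the start), separated by
#' transit legs, with a slow soak drift at the apex roughly along the
#' outbound heading.
#'
#' @param spec A [vessel_behavior_spec()].
#' @param start `(lon, lat)` trip start.
#' @param vessel_id Identifier.
#' @param start_time Trip start (POSIXct, UTC).
#' @return List with `track` (`vessel_id`, `timestamp`, `lon`, `lat`) and
#'   `sets` (ground truth: one row per deployment with apex and leg
#'   geometry).
#' @export
gen_vessel_track <- function(spec = vessel_behavior_spec(),
                             start = c(-25, 15), vessel_id = "V1",
                             start_time = as.POSIXct("2010-03-01 00:00:00",
                                                     tz = "UTC")) {
  withr_seed(spec$seed, {
    pts <- matrix(start, ncol = 2)
    hours <- 0
    truth <- list()
    cur <- start
    heading <- stats::runif(1, 0, 360)
    add_leg <- function(bearing, len, speed) {
      lp <- leg_points(cur, bearing, len, speed, spec$ping_interval)
      pts <<- rbind(pts, lp$points)
      hours <<- c(hours, hours[length(hours)] + lp$hours)
      cur <<- unname(lp$points[nrow(lp$points), ])
    }
    n_sets <- spec$n_sets_per_trip
    for (s in seq_len(max(n_sets, 1))) {
      if (n_sets == 0 && s > 0) { # transit-only trip
        add_leg(heading, spec$transit_leg_km, spec$transit_speed)
        break
      }
      # transit to the fishing ground
      heading <- (heading + stats::runif(1, -40, 40)) %% 360
      add_leg(heading, spec$transit_leg_km * stats::runif(1, 0.8, 1.2),
              spec$transit_speed)
      # outbound deployment leg, broadly forward of the arrival course so
      # the only near-reversal in a deployment is the V apex
      out_head <- (heading + stats::runif(1, -100, 100)) %% 360
      line_len <- stats::runif(1, spec$longline_length_range[1],
                               spec$longline_length_range[2])
      deploy_start <- cur
      add_leg(out_head, line_len, spec$deployment_speed)
      apex <- cur
      # soak: slow drift roughly along the outbound heading
      if (spec$soak_hours > 0)
        add_leg((out_head + stats::runif(1, -30, 30)) %% 360,
                0.5 * spec$soak_hours, 0.5)
      # inbound haul leg back to a jittered endpoint near the start
      end_pt <- gc_destination(deploy_start[1], deploy_start[2],
                               stats::runif(1, 0, 360),
                               stats::runif(1, 0, spec$endpoint_jitter))
      in_head <- gc_bearing(cur[1], cur[2], end_pt[1], end_pt[2])
      in_len <- gc_distance_km(cur[1], cur[2], end_pt[1], end_pt[2])
      add_leg(in_head, in_len, spec$deployment_speed)
      truth[[length(truth) + 1]] <- data.frame(
        vessel_id = vessel_id,
        turn_lon = apex[1], turn_lat = apex[2],
        start_lon = deploy_start[1], start_lat = deploy_start[2],
        end_lon = cur[1], end_lat = cur[2],
        line_length = line_len,
        outbound_km = line_len, inbound_km = in_len)
      heading <- in_head # steam on broadly along the haul course
    }
    # GPS noise: offset each ping in a random direction
    n <- nrow(pts)
    if (spec$ping_noise_km > 0) {
      off <- abs(stats::rnorm(n, 0, spec$ping_noise_km))
      ang <- stats::runif(n, 0, 360)
      pts <- gc_destination(pts[, 1], pts[, 2], ang, off)
    }
    ts <- start_time + round(hours * 3600)
    track <- data.frame(vessel_id = vessel_id, timestamp = ts,
                        lon = pts[, 1], lat = pts[, 2])
    sets <- if (length(truth) > 0) do.call(rbind, truth)
    else data.frame(vessel_id = character(), turn_lon = numeric(),
                    turn_lat = numeric(), start_lon = numeric(),
                    start_lat = numeric(), end_lon = numeric(),
                    end_lat = numeric(), line_length = numeric(),
                    outbound_km = numeric(), inbound_km = numeric())
    if (nrow(sets) > 0) {
      idx <- vapply(seq_len(nrow(sets)), function(k)
        which.min((track$lon - sets$turn_lon[k])^2 +
                    (track$lat - sets$turn_lat[k])^2), integer(1))
      sets$date <- as.Date(track$timestamp[idx], tz = "UTC")
    }
    list(track = track, sets = sets)
  })
}

#' Detect longline deployments from a vessel GPS track
#'
#' Scans interior pings for heading deviations above `turn_angle_min`
#' (near-reversals), walks backward and forward from each candidate until
#' the accumulated along-track distance exceeds the longline length (the
#' lower bound: the true length of any one line is unknown, and a longer
#' walk can run off the deployment legs), and accepts the candidate when
#' the two walk endpoints are within `endpoint_tol_fraction` of the upper
#' line-length bound (a proper V). Overlapping
#' candidates are resolved by keeping the sharper turn; each ping belongs to
#' at most one set.
#'
#' @param track data.frame with `vessel_id`, `timestamp`, `lon`, `lat`,
#'   strictly time-ordered.
#' @param line_length_bounds Longline length bounds, km (default 80-100).
#' @param turn_angle_min Minimum heading deviation, degrees (default 130).
#' @param endpoint_tol_fraction Endpoint separation tolerance as a fraction
#'   of the upper line-length bound (default 0.25).
#' @return data.frame, one row per detected set: `vessel_id`, `date`,
#'   `turn_lon`, `turn_lat`, `start_lon/lat`, `end_lon/lat`,
#'   `leg_in_km`, `leg_out_km`, `turn_angle`. Empty for transit-only tracks.
#' @export
detect_longline_sets <- function(track, line_length_bounds = c(80, 100),
                                 turn_angle_min = 130,
                                 endpoint_tol_fraction = 0.25) {
  n <- nrow(track)
  empty <- data.frame(vessel_id = character(), date = as.Date(character()),
                      turn_lon = numeric(), turn_lat = numeric(),
                      start_lon = numeric(), start_lat = numeric(),
                      end_lon = numeric(), end_lat = numeric(),
                      leg_in_km = numeric(), leg_out_km = numeric(),
                      turn_angle = numeric())
  if (n < 3) return(empty)
  if (any(diff(as.numeric(track$timestamp)) <= 0))
    stop("timestamps must be strictly increasing")
  seg_d <- gc_distance_km(track$lon[-n], track$lat[-n],
                          track$lon[-1], track$lat[-1])
  seg_b <- gc_bearing(track$lon[-n], track$lat[-n],
                      track$lon[-1], track$lat[-1])
  dev <- bearing_deviation(seg_b[-(n - 1)], seg_b[-1]) # at pings 2..n-1
  cand <- which(dev > turn_angle_min) + 1L
  if (length(cand) == 0) return(empty)
  cand <- cand[order(dev[cand - 1L], decreasing = TRUE)]
  walk_len <- line_length_bounds[1]
  tol_km <- endpoint_tol_fraction * line_length_bounds[2]
  cum <- c(0, cumsum(seg_d)) # along-track distance to each ping
  claimed <- logical(n)
  out <- list()
  for (i in cand) {
    if (claimed[i]) next
    # backward: first ping j with along-track distance from j to i > walk_len
    back <- which(cum[i] - cum[seq_len(i - 1)] > walk_len)
    if (length(back) == 0) next
    j <- max(back)
    # forward: first ping k with distance from i to k > walk_len
    fwd <- which(cum[(i + 1):n] - cum[i] > walk_len)
    if (length(fwd) == 0) next
    k <- i + min(fwd)
    if (any(claimed[j:k])) next
    endpoint_sep <- gc_distance_km(track$lon[j], track$lat[j],
                                   track$lon[k], track$lat[k])
    if (endpoint_sep > tol_km) next
    claimed[j:k] <- TRUE
    out[[length(out) + 1]] <- data.frame(
      vessel_id = track$vessel_id[1],
      date = as.Date(track$timestamp[i], tz = "UTC"),
      turn_lon = track$lon[i], turn_lat = track$lat[i],
      start_lon = track$lon[j], start_lat = track$lat[j],
      end_lon = track$lon[k], end_lat = track$lat[k],
      leg_in_km = cum[i] - cum[j], leg_out_km = cum[k] - cum[i],
      turn_angle = dev[i - 1L])
  }
  if (length(out) == 0) return(empty)
  out <- do.call(rbind, out)
  out[order(out$date, out$turn_lon), ]
}

#' Grid fishing effort by daily vessel centroids
#'
#' Per vessel and calendar day, fishing locations collapse to one centroid;
#' each centroid contributes one effort-day to the half-open 1-degree cell
#' `[lon, lon+1) x [lat, lat+1)` containing it, so total effort-days equal
#' the number of distinct vessel-days.
#'
#' @param locations data.frame of fishing locations with `vessel_id`,
#'   `date`, `lon`, `lat` (e.g. detected set turn points).
#' @param cell_size Cell size in degrees (default 1).
#' @return data.frame with `cell_lon`, `cell_lat` (lower-left corner) and
#'   `effort_days`.
#' @export
fishing_effort_grid <- function(locations, cell_size = 1) {
  if (nrow(locations) == 0)
    return(data.frame(cell_lon = numeric(), cell_lat = numeric(),
                      effort_days = integer()))
  cent <- daily_centroids(locations)
  cl <- floor(wrap_lon(cent$lon) / cell_size) * cell_size
  cb <- floor(cent$lat / cell_size) * cell_size
  key <- paste(cl, cb, sep = "_")
  tab <- table(key)
  parts <- do.call(rbind, strsplit(names(tab), "_"))
  out <- data.frame(cell_lon = as.numeric(parts[, 1]),
                    cell_lat = as.numeric(parts[, 2]),
                    effort_days = as.integer(tab))
  out <- out[order(out$cell_lat, out$cell_lon), ]
  rownames(out) <- NULL
  out
}

daily_centroids <- function(locations) {
  agg <- aggregate(cbind(lon, lat) ~ vessel_id + date, data = locations,
                   FUN = mean)
  agg[order(agg$vessel_id, agg$date), ]
}

#' Fishing intensity: fraction of locations in area-restricted-search clusters
#'
#' A fishing location is area-restricted search (ARS) when the same vessel
#' has another fishing location within `ars_radius` on an adjacent calendar
#' day -- repeated, localised daily deployment rather than broad-scale
#' searching. Intensity per 1-degree cell is the number of ARS locations
#' over the number of locations; cells with no locations are undefined and
#' omitted.
#'
#' @param locations data.frame with `vessel_id`, `date`, `lon`, `lat`.
#' @param ars_radius Clustering radius, km (default 30).
#' @param cell_size Cell size in degrees (default 1).
#' @return data.frame with `cell_lon`, `cell_lat`, `n_locations`,
#'   `n_ars_locations`, `intensity` in `[0, 1]`.
#' @export
fishing_intensity <- function(locations, ars_radius = 30, cell_size = 1) {
  if (nrow(locations) == 0)
    return(data.frame(cell_lon = numeric(), cell_lat = numeric(),
                      n_locations = integer(), n_ars_locations = integer(),
                      intensity = numeric()))
  cent <- daily_centroids(locations)
  cent$ars <- FALSE
  for (v in unique(cent$vessel_id)) {
    idx <- which(cent$vessel_id == v)
    d <- cent[idx, ]
    for (a in seq_len(nrow(d))) {
      adj <- abs(as.numeric(d$date - d$date[a])) == 1
      if (!any(adj)) next
      near <- gc_distance_km(d$lon[a], d$lat[a],
                             d$lon[adj], d$lat[adj]) <= ars_radius
      if (any(near)) cent$ars[idx[a]] <- TRUE
    }
  }
  cl <- floor(wrap_lon(cent$lon) / cell_size) * cell_size
  cb <- floor(cent$lat / cell_size) * cell_size
  key <- paste(cl, cb, sep = "_")
  n_loc <- table(key)
  n_ars <- rowsum(as.numeric(cent$ars), key)
  parts <- do.call(rbind, strsplit(names(n_loc), "_"))
  out <- data.frame(cell_lon = as.numeric(parts[, 1]),
                    cell_lat = as.numeric(parts[, 2]),
                    n_locations = as.integer(n_loc),
                    n_ars_locations = as.integer(n_ars[names(n_loc), 1]))
  out$intensity <- out$n_ars_locations / out$n_locations
  out <- out[order(out$cell_lat, out$cell_lon), ]
  rownames(out) <- NULL
  out
}

#' Flag grid cells as OMZ or normoxic
#'
#' @param grid_cells data.frame with `cell_lon`, `cell_lat` (lower-left).
#' @param env An [env_grid()].
#' @param threshold,ref_depth OMZ definition (DO < threshold at ref_depth).
#' @return `grid_cells` with `mean_do_100` and logical `omz_flag` appended;
#'   cells outside the environment domain get `NA`.
#' @export
flag_omz_cells <- function(grid_cells, env, threshold = 3.5, ref_depth = 100) {
  cx <- grid_cells$cell_lon + 0.5
  cy <- grid_cells$cell_lat + 0.5
  ok <- env_contains(env, cx, cy)
  grid_cells$mean_do_100 <- NA_real_
  if (any(ok))
    grid_cells$mean_do_100[ok] <- env_value_at(env, cx[ok], cy[ok],
                                               ref_depth, "do")
  grid_cells$omz_flag <- grid_cells$mean_do_100 < threshold
  grid_cells
}

#' Compare a fishing metric between OMZ and normoxic cells
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test on per-cell values split
#' by `omz_flag`.
#'
#' @param grid_cells data.frame with an `omz_flag` column and the metric.
#' @param metric Name of the metric column (e.g. `"effort_days"`,
#'   `"intensity"`).
#' @return List with `u_stat`, `p_value`, per-zone `n`, medians and means.
#' @export
compare_zones <- function(grid_cells, metric) {
  x <- grid_cells[[metric]][isTRUE_v(grid_cells$omz_flag)]
  y <- grid_cells[[metric]][!isTRUE_v(grid_cells$omz_flag) &
                              !is.na(grid_cells$omz_flag)]
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2 || length(y) < 2)
    stop("need at least 2 cells per zone")
  if (length(unique(c(x, y))) == 1) { # complete ties: no evidence either way
    return(list(metric = metric, u_stat = length(x) * length(y) / 2,
                p_value = 1, n_omz = length(x), n_normoxic = length(y),
                median_omz = stats::median(x),
                median_normoxic = stats::median(y),
                mean_omz = mean(x), mean_normoxic = mean(y)))
  }
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE))
  list(metric = metric, u_stat = unname(wt$statistic),
       p_value = wt$p.value,
       n_omz = length(x), n_normoxic = length(y),
       median_omz = stats::median(x), median_normoxic = stats::median(y),
       mean_omz = mean(x), mean_normoxic = mean(y))
}
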