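# Correlated-random-walk residency null model: does a shark spend more days
# over the OMZ than expected under null movement with the same empirical
# step-length and bearing distributions?
#
# Replicate tracks start at the real start point, have the same number of
# locations, and draw each move's step length and bearing independently and
# uniformly with replacement from the real track's pools (bearings, not
# turning angles, preserving the track's overall directional structure).

#' Extract step lengths and bearings from a daily track
#'
#' @param track A `shark_track` data.frame (columns `lon`, `lat`), one
#'   segment, at least 2 positions.
#' @return List of class `step_set`: `step_lengths` (km), `bearings`
#'   (degrees in `[0, 360)`), `start` (lon, lat), `n_locations`.
#' @export
extract_steps <- function(track) {
  n <- nrow(track)
  if (n < 2) stop("need at least 2 positions to extract steps")
  i <- seq_len(n - 1)
  structure(list(
    step_lengths = gc_distance_km(track$lon[i], track$lat[i],
                                  track$lon[i + 1], track$lat[i + 1]),
    bearings = gc_bearing(track$lon[i], track$lat[i],
                          track$lon[i + 1], track$lat[i + 1]),
    start = c(track$lon[1], track$lat[1]),
    n_locations = n), class = "step_set")
}

#' Simulate correlated-random-walk replicate tracks
#'
#' @param steps A `step_set` from [extract_steps()].
#' @param n_replicates Number of replicate tracks (default 100).
#' @param seed Integer seed (deterministic per seed).
#' @return 3-D array `[n_locations, 2 (lon, lat), n_replicates]`.
#' @export
simulate_crw <- function(steps, n_replicates = 100, seed = 1L) {
  n_mov <- steps$n_locations - 1
  if (n_mov < 1 || length(steps$step_lengths) == 0)
    stop("empty step set")
  withr_seed(seed, {
    pos <- array(NA_real_, dim = c(steps$n_locations, 2, n_replicates),
                 dimnames = list(NULL, c("lon", "lat"), NULL))
    cur <- matrix(rep(steps$start, each = n_replicates), ncol = 2)
    pos[1, 1, ] <- cur[, 1]; pos[1, 2, ] <- cur[, 2]
    n_pool <- length(steps$step_lengths)
    for (t in seq_len(n_mov)) {
      len <- steps$step_lengths[sample.int(n_pool, n_replicates,
                                           replace = TRUE)]
      brg <- steps$bearings[sample.int(length(steps$bearings), n_replicates,
                                       replace = TRUE)]
      cur <- gc_destination(cur[, 1], cur[, 2], brg, len)
      pos[t + 1, 1, ] <- cur[, 1]; pos[t + 1, 2, ] <- cur[, 2]
    }
    pos
  })
}

#' Fraction of track days spent inside the OMZ
#'
#' @param inside Logical vector, one classification per track day (`NA`s are
#'   excluded from both numerator and denominator).
#' @return Fraction in `[0, 1]`.
#' @export
residency_proportion <- function(inside) {
  inside <- inside[!is.na(inside)]
  if (length(inside) == 0) stop("zero classified days")
  mean(inside)
}

# Classify an n x 2 (lon, lat) matrix against the grid's OMZ mask; positions
# outside the domain count as outside the OMZ.
positions_in_omz <- function(lonlat, mask, grid) {
  ok <- env_contains(grid, lonlat[, 1], lonlat[, 2])
  out <- rep(FALSE, nrow(lonlat))
  if (any(ok)) {
    ij <- env_cell_index(grid, lonlat[ok, 1], lonlat[ok, 2])
    out[ok] <- mask[ij]
  }
  out
}

#' One-sided empirical proportion test
#'
#' Add-one empirical percentile test against the randomization null:
#' `p = (1 + #\{replicates >= real\}) / (n_replicates + 1)`. Ties count
#' against rejection (conservative).
#'
#' @param real Observed residency proportion.
#' @param replicates Replicate residency proportions (`>= 1`).
#' @return p-value in `(0, 1]`.
#' @export
proportion_test <- function(real, replicates) {
  stopifnot(length(replicates) >= 1)
  (1 + sum(replicates >= real)) / (length(replicates) + 1)
}

#' CRW residency test of OMZ association
#'
#' Runs the full null-model test for one track: extract the empirical step
#' pools, simulate replicate correlated random walks, score the fraction of
#' days over the OMZ for the real track and every replicate (against the
#' same static OMZ mask), and compute the one-sided empirical p-value for
#' the hypothesis that the shark spent more days over the OMZ than expected
#' by chance.
#'
#' @param track A `shark_track` data.frame.
#' @param env An [env_grid()].
#' @param n_replicates Number of replicates (default 100).
#' @param seed Integer seed.
#' @param threshold,ref_depth OMZ definition passed to [omz_mask()].
#' @return List of class `crw_ensemble`: `real_proportion`,
#'   `replicate_proportions`, `n_replicates`, `p_value`, `seed`.
#' @export
crw_omz_test <- function(track, env, n_replicates = 100, seed = 1L,
                         threshold = 3.5, ref_depth = 100) {
  mask <- omz_mask(env, threshold, ref_depth)
  steps <- extract_steps(track)
  real <- residency_proportion(
    positions_in_omz(cbind(track$lon, track$lat), mask, env))
  reps <- simulate_crw(steps, n_replicates, seed)
  rep_prop <- vapply(seq_len(n_replicates), function(r)
    residency_proportion(positions_in_omz(reps[, , r], mask, env)),
    numeric(1))
  structure(list(real_proportion = real, replicate_proportions = rep_prop,
                 n_replicates = n_replicates,
                 p_value = proportion_test(real, rep_prop),
                 seed = as.integer(seed)),
            class = "crw_ensemble")
}

#' @export
print.crw_ensemble <- function(x, ...) {
  cat("CRW residency test:", x$n_replicates, "replicates\n",
      " real proportion of days over OMZ:", round(x$real_proportion, 3), "\n",
      " replicate mean:", round(mean(x$replicate_proportions), 3),
      "(range", round(min(x$replicate_proportions), 3), "-",
      round(max(x$replicate_proportions), 3), ")\n",
      " one-sided empirical p:", signif(x$p_value, 3), "\n")
  invisible(x)
}
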