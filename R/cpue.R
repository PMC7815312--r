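# Catch-per-unit-effort analysis: grid logbook catches to 1-degree cells,
# extract latitude transects against DO at 100 m, and estimate the DO of
# peak CPUE with quadratic fits of log10(CPUE) on DO.

#' Grid logbook catch records into 1-degree CPUE cells
#'
#' Cells are half-open 1 x 1 degree boxes keyed by their lower-left corner.
#' Mean CPUE per cell is total biomass over total sets (one set = one day of
#' fishing effort); biomass is conserved exactly.
#'
#' @param records data.frame with `lon`, `lat`, `biomass` (kg) and `n_sets`
#'   (`>= 1`; defaults to 1 per record if absent).
#' @param cell_size Cell size in degrees (default 1).
#' @return data.frame with `cell_lon`, `cell_lat` (lower-left corner),
#'   `total_biomass`, `total_sets`, `mean_cpue` (kg per set).
#' @export
cpue_grid <- function(records, cell_size = 1) {
  if (!"n_sets" %in% names(records)) records$n_sets <- 1L
  stopifnot(all(records$biomass >= 0), all(records$n_sets >= 1))
  cl <- floor(wrap_lon(records$lon) / cell_size) * cell_size
  cb <- floor(records$lat / cell_size) * cell_size
  key <- paste(cl, cb, sep = "_")
  agg <- rowsum(cbind(biomass = records$biomass, sets = records$n_sets), key)
  parts <- do.call(rbind, strsplit(rownames(agg), "_"))
  out <- data.frame(cell_lon = as.numeric(parts[, 1]),
                    cell_lat = as.numeric(parts[, 2]),
                    total_biomass = agg[, "biomass"],
                    total_sets = agg[, "sets"])
  out$mean_cpue <- out$total_biomass / out$total_sets
  out <- out[order(out$cell_lat, out$cell_lon), ]
  rownames(out) <- NULL
  out
}

#' Attach DO at 100 m to CPUE cells
#'
#' @param cells Output of [cpue_grid()].
#' @param env An [env_grid()].
#' @param ref_depth Reference depth, m.
#' @return `cells` with a `do_100` column (cell-centre lookup); cells outside
#'   the grid get `NA`.
#' @export
add_cell_do <- function(cells, env, ref_depth = 100) {
  cx <- cells$cell_lon + 0.5
  cy <- cells$cell_lat + 0.5
  ok <- env_contains(env, cx, cy)
  cells$do_100 <- NA_real_
  if (any(ok))
    cells$do_100[ok] <- env_value_at(env, cx[ok], cy[ok], ref_depth, "do")
  cells
}

#' Latitude transect of CPUE against DO
#'
#' Selects the cells whose centres lie on the given latitude row within
#' `lon_range`, ordered west to east, and appends the cumulative mean CPUE
#' along the transect.
#'
#' @param cells Output of [add_cell_do()] (needs `do_100`).
#' @param latitude Transect latitude at cell centres (e.g. 20.5).
#' @param lon_range Longitude range of the transect (default the west
#'   African OMZ transect span, -46.5 to -15.5).
#' @return data.frame ordered by longitude with `cell_lon`, `do_100`,
#'   `mean_cpue`, `cum_cpue`.
#' @export
transect_profile <- function(cells, latitude, lon_range = c(-46.5, -15.5)) {
  row <- cells[cells$cell_lat + 0.5 == latitude &
                 cells$cell_lon + 0.5 >= lon_range[1] &
                 cells$cell_lon + 0.5 <= lon_range[2], , drop = FALSE]
  if (nrow(row) == 0) stop("no cells on the ", latitude, " transect row")
  row <- row[order(row$cell_lon), ]
  data.frame(cell_lon = row$cell_lon, do_100 = row$do_100,
             mean_cpue = row$mean_cpue, cum_cpue = cumsum(row$mean_cpue))
}

#' Quadratic fit of log10(CPUE) on DO with peak estimation
#'
#' Ordinary least squares of `log10(cpue)` on `(1, do, do^2)`. The DO of
#' peak CPUE is the vertex `-c1 / (2 * c2)`, defined only for concave fits
#' (`c2 < 0`). Zero-CPUE points are excluded by default (log undefined); the
#' optional `offset_kg` mode adds a constant before the log and is not the
#' canonical treatment.
#'
#' @param do,cpue Paired DO (ml/l) and mean CPUE (kg/set) values.
#' @param include_zero_cpue If `TRUE`, keep zero-CPUE points by adding
#'   `offset_kg` to every CPUE before the log.
#' @param offset_kg Offset used when `include_zero_cpue = TRUE` (default 1).
#' @return List of class `cpue_quadratic`: coefficients `c0`, `c1`, `c2`,
#'   `peak_do` (`NA` with `concave = FALSE` when `c2 >= 0`), `n`, `adj_r2`,
#'   `f_stat`, `p_value`, and the underlying `lm` fit.
#' @export
fit_cpue_quadratic <- function(do, cpue, include_zero_cpue = FALSE,
                               offset_kg = 1) {
  keep <- is.finite(do) & is.finite(cpue)
  do <- do[keep]; cpue <- cpue[keep]
  if (include_zero_cpue) cpue <- cpue + offset_kg
  pos <- cpue > 0
  do <- do[pos]; cpue <- cpue[pos]
  if (length(do) < 4)
    stop("need at least 4 points with positive CPUE for a quadratic fit")
  y <- log10(cpue)
  fit <- stats::lm(y ~ do + I(do^2))
  cf <- unname(stats::coef(fit))
  concave <- is.finite(cf[3]) && cf[3] < 0
  sm <- summary(fit)
  fs <- sm$fstatistic
  structure(list(
    c0 = cf[1], c1 = cf[2], c2 = cf[3],
    peak_do = if (concave) quadratic_peak(cf) else NA_real_,
    concave = concave, n = length(do), adj_r2 = sm$adj.r.squared,
    f_stat = unname(fs[1]),
    p_value = if (!is.null(fs))
      unname(stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE)) else NA_real_,
    fit = fit), class = "cpue_quadratic")
}

#' Vertex of a quadratic
#'
#' @param coefs Coefficients `c(c0, c1, c2)` of `c0 + c1 x + c2 x^2` with
#'   `c2 < 0`.
#' @return The `x` of the maximum, `-c1 / (2 c2)`.
#' @export
quadratic_peak <- function(coefs) {
  if (coefs[3] >= 0) stop("peak undefined: quadratic is not concave")
  -coefs[2] / (2 * coefs[3])
}

#' @export
print.cpue_quadratic <- function(x, ...) {
  cat(sprintf("log10(CPUE) = %.4g + %.4g DO %+.4g DO^2  (n = %d)\n",
              x$c0, x$c1, x$c2, x$n))
  cat(sprintf("  adj R^2 = %.3f, F = %.3f, p = %.3g\n",
              x$adj_r2, x$f_stat, x$p_value))
  if (x$concave)
    cat(sprintf("  peak CPUE at DO = %.2f ml/l\n", x$peak_do))
  else cat("  fit is not concave; peak undefined\n")
  invisible(x)
}

#' Generate a synthetic logbook of longline sets
#'
#' Scatters fishing sets over the environment domain; log10 biomass per set
#' is quadratic in local DO at 100 m with its vertex at `peak_do`, plus
#' Gaussian noise. Deterministic per seed.
#'
#' @param env An [env_grid()].
#' @param peak_do DO (ml/l) of peak catch (`0 < peak_do <` max surface DO).
#' @param n_sets Number of sets (`>= 10`).
#' @param seed Integer seed.
#' @param log_cpue_max log10 biomass (kg) at the vertex (default 2.5).
#' @param curvature Quadratic curvature magnitude (default 0.15).
#' @param noise_sd SD of the log10 biomass noise (default 0.15).
#' @param n_vessels Number of vessel ids to spread sets over.
#' @return data.frame with `vessel_id`, `date`, `lon`, `lat`, `biomass`
#'   (kg), `n_sets` (= 1: one set is one day of effort).
#' @export
gen_logbook <- function(env, peak_do = 3.0, n_sets = 2000, seed = 1L,
                        log_cpue_max = 2.5, curvature = 0.15,
                        noise_sd = 0.15, n_vessels = 20) {
  if (n_sets < 10) stop("n_sets < 10 is unfittable downstream")
  max_surf_do <- max(env$fields$do[, , 1], na.rm = TRUE)
  if (peak_do <= 0 || peak_do >= max_surf_do)
    stop("peak_do must lie in (0, max surface DO)")
  withr_seed(seed, {
    lon <- stats::runif(n_sets, min(env$lon), max(env$lon))
    lat <- stats::runif(n_sets, min(env$lat), max(env$lat))
    do100 <- env_value_at(env, lon, lat, 100, "do")
    log_b <- log_cpue_max - curvature * (do100 - peak_do)^2 +
      stats::rnorm(n_sets, 0, noise_sd)
    data.frame(vessel_id = paste0("V", sample.int(n_vessels, n_sets,
                                                  replace = TRUE)),
               date = as.Date("2017-01-01") +
                 sample.int(365, n_sets, replace = TRUE) - 1,
               lon = lon, lat = lat, biomass = 10^log_b, n_sets = 1L)
  })
}
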