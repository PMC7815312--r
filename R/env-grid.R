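# Gridded 3-D ocean environment: regular lon x lat grid with a common set of
# depth levels, holding dissolved oxygen, temperature, salinity, net primary
# production, chlorophyll-a and phytoplankton fields. This is the stage on
# which every other module runs.

ENV_VARS <- c("do", "temp", "sal", "npp", "chl", "phyto")

ENV_UNITS <- c(do = "ml O2 l-1", temp = "degC", sal = "PSU",
               npp = "g l-1 d-1", chl = "umol l-1", phyto = "umol l-1")

#' Construct an environment grid
#'
#' @param lon,lat Cell-centre coordinate vectors (strictly increasing,
#'   regular spacing).
#' @param depth Depth levels in metres, positive downward, strictly
#'   increasing from the surface.
#' @param fields Named list of 3-D arrays `[lon, lat, depth]`; names must be
#'   a subset of `do`, `temp`, `sal`, `npp`, `chl`, `phyto`.
#' @return An object of class `env_grid`.
#' @export
env_grid <- function(lon, lat, depth, fields) {
  stopifnot(length(lon) > 1, length(lat) > 1, length(depth) > 1)
  if (any(diff(lon) <= 0) || any(diff(lat) <= 0))
    stop("lon and lat must be strictly increasing")
  if (any(diff(depth) <= 0)) stop("depth levels must be strictly increasing")
  if (!all(names(fields) %in% ENV_VARS))
    stop("unknown field names: ",
         paste(setdiff(names(fields), ENV_VARS), collapse = ", "))
  dims <- c(length(lon), length(lat), length(depth))
  for (v in names(fields)) {
    if (!identical(dim(fields[[v]]), as.integer(dims)))
      stop("field '", v, "' does not have dim [lon, lat, depth]")
  }
  structure(list(lon = lon, lat = lat, depth = depth, fields = fields),
            class = "env_grid")
}

#' @export
print.env_grid <- function(x, ...) {
  cat("env_grid:", length(x$lon), "x", length(x$lat), "cells,",
      length(x$depth), "depth levels (", min(x$depth), "-", max(x$depth),
      "m )\n  lon", min(x$lon), "to", max(x$lon),
      "; lat", min(x$lat), "to", max(x$lat),
      "\n  fields:", paste(names(x$fields), collapse = ", "), "\n")
  invisible(x)
}

#' Specification for a synthetic OMZ-structured environment
#'
#' Parameters describe two end-member water columns (inside vs outside the
#' oxygen minimum zone) blended radially around `omz_center` by a logistic
#' ramp of horizontal scale `0.15 * omz_radius`, giving the sharp horizontal
#' DO gradient characteristic of OMZ boundaries.
#'
#' @param lon_range,lat_range Domain extents in degrees.
#' @param horizontal_resolution Cell size in degrees (default 0.25).
#' @param depth_levels Depth levels in metres, surface to deep.
#' @param omz_center `(lon, lat)` of the OMZ core.
#' @param omz_radius Radial scale of the OMZ in degrees.
#' @param oxycline_depth_inside,oxycline_depth_outside Depth (m) of the
#'   oxycline midpoint in the two end-member columns.
#' @param do_surface,do_core Surface and deep-core dissolved oxygen (ml/l).
#' @param sst_inside,sst_outside Sea-surface temperature (degC).
#' @param npp_peak_inside,npp_peak_outside Peak net primary production
#'   (g/l/d); the inside default is nine times the outside one, matching the
#'   elevated productivity above OMZ cores.
#' @param seed Integer seed controlling the smooth noise field.
#' @return A list of class `env_grid_spec`.
#' @export
env_grid_spec <- function(lon_range = c(-45, -10), lat_range = c(0, 25),
                          horizontal_resolution = 0.25,
                          depth_levels = c(0, 10, 25, 50, 75, 100, 150, 200,
                                           300, 400, 600, 800, 1200, 1700),
                          omz_center = c(-20, 12), omz_radius = 6,
                          oxycline_depth_inside = 60,
                          oxycline_depth_outside = 400,
                          do_surface = 5.5, do_core = 0.9,
                          sst_inside = 25.5, sst_outside = 21,
                          npp_peak_inside = 0.009, npp_peak_outside = 0.001,
                          seed = 1L) {
  spec <- list(lon_range = lon_range, lat_range = lat_range,
               horizontal_resolution = horizontal_resolution,
               depth_levels = depth_levels, omz_center = omz_center,
               omz_radius = omz_radius,
               oxycline_depth_inside = oxycline_depth_inside,
               oxycline_depth_outside = oxycline_depth_outside,
               do_surface = do_surface, do_core = do_core,
               sst_inside = sst_inside, sst_outside = sst_outside,
               npp_peak_inside = npp_peak_inside,
               npp_peak_outside = npp_peak_outside, seed = as.integer(seed))
  validate_env_grid_spec(spec)
  structure(spec, class = "env_grid_spec")
}

validate_env_grid_spec <- function(spec) {
  if (spec$horizontal_resolution <= 0) stop("resolution must be > 0")
  if (diff(spec$lon_range) <= 0 || diff(spec$lat_range) <= 0)
    stop("degenerate (zero-area) domain")
  if (any(diff(spec$depth_levels) <= 0))
    stop("depth levels must be strictly increasing")
  if (spec$do_core >= spec$do_surface) stop("do_core must be < do_surface")
  if (spec$do_core < 0 || spec$npp_peak_inside < 0 || spec$npp_peak_outside < 0)
    stop("concentrations must be >= 0")
  invisible(spec)
}

# Radial OMZ membership weight in [0, 1]: 1 at the core, 0.5 at omz_radius.
omz_weight <- function(lon, lat, spec) {
  dx <- (lon - spec$omz_center[1]) * cos(spec$omz_center[2] * pi / 180)
  dy <- lat - spec$omz_center[2]
  r <- sqrt(dx^2 + dy^2)
  stats::plogis(-(r - spec$omz_radius) / (0.15 * spec$omz_radius))
}

# Smooth multiplicative noise surface built from a few seeded Fourier modes;
# bounded within 1 +/- amp.
smooth_noise_surface <- function(lon, lat, amp) {
  n_modes <- 4L
  a <- stats::runif(n_modes, -1, 1)
  fx <- stats::runif(n_modes, 0.05, 0.25)
  fy <- stats::runif(n_modes, 0.05, 0.25)
  ph <- stats::runif(n_modes, 0, 2 * pi)
  g <- outer(lon, lat, function(x, y) {
    s <- 0
    for (k in seq_len(n_modes))
      s <- s + a[k] * cos(2 * pi * (fx[k] * x + fy[k] * y) + ph[k])
    s / n_modes
  })
  1 + amp * g
}

#' Generate a synthetic OMZ-structured environment grid
#'
#' Builds smooth 3-D dissolved-oxygen, temperature, salinity, NPP,
#' chlorophyll and phytoplankton fields in which the OMZ column has a shallow
#' oxycline (DO at 100 m well below 3.5 ml/l at the core), warm SST, and
#' elevated NPP, while columns far from the core are normoxic at 100 m. DO is
#' monotone non-increasing with depth everywhere and the output is a pure
#' function of the spec (including its seed).
#'
#' @param spec An [env_grid_spec()].
#' @return An [env_grid()].
#' @export
gen_env_field <- function(spec = env_grid_spec()) {
  validate_env_grid_spec(spec)
  res <- spec$horizontal_resolution
  lon <- seq(spec$lon_range[1] + res / 2, spec$lon_range[2] - res / 2, by = res)
  lat <- seq(spec$lat_range[1] + res / 2, spec$lat_range[2] - res / 2, by = res)
  if (length(lon) < 2 || length(lat) < 2)
    stop("degenerate domain: fewer than 2 cells along an axis")
  z <- spec$depth_levels
  nz <- length(z)

  w <- omz_weight(outer(lon, rep(1, length(lat))),
                  outer(rep(1, length(lon)), lat), spec)

  noise <- withr_seed(spec$seed, {
    list(do = smooth_noise_surface(lon, lat, 0.04),
         sst = smooth_noise_surface(lon, lat, 0.01),
         npp = smooth_noise_surface(lon, lat, 0.10))
  })

  # column parameters blended horizontally
  d_ox <- w * spec$oxycline_depth_inside + (1 - w) * spec$oxycline_depth_outside
  w_ox <- w * 25 + (1 - w) * 80                      # oxycline sharpness (m)
  sst <- (w * spec$sst_inside + (1 - w) * spec$sst_outside) * noise$sst
  d_ml <- w * 35 + (1 - w) * 60                      # mixed-layer base (m)
  npp_pk <- (w * spec$npp_peak_inside + (1 - w) * spec$npp_peak_outside) *
    noise$npp
  z_pk <- w * 80 + (1 - w) * 40                      # NPP peak depth (m)
  sal0 <- 36 * w + 35.5 * (1 - w)

  nx <- length(lon); ny <- length(lat)
  mk <- function() array(NA_real_, dim = c(nx, ny, nz))
  do_f <- mk(); temp_f <- mk(); sal_f <- mk(); npp_f <- mk()
  chl_f <- mk(); phyto_f <- mk()
  t_deep <- 4.5
  for (k in seq_len(nz)) {
    zk <- z[k]
    do_f[, , k] <- spec$do_core +
      (spec$do_surface - spec$do_core) *
      stats::plogis((d_ox - zk) / w_ox) * noise$do
    temp_f[, , k] <- t_deep + (sst - t_deep) *
      exp(-pmax(0, zk - d_ml) / 60)
    sal_f[, , k] <- sal0 - 0.6 * (1 - exp(-zk / 500))
    npp_f[, , k] <- npp_pk * exp(-((zk - z_pk) / 50)^2)
    chl_f[, , k] <- npp_f[, , k] * 300
    phyto_f[, , k] <- npp_f[, , k] * 500
  }
  env_grid(lon, lat, z,
           list(do = do_f, temp = temp_f, sal = sal_f, npp = npp_f,
                chl = chl_f, phyto = phyto_f))
}

# Evaluate a block with a temporary RNG state (restores the caller's state).
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  force(expr)
}

# Nearest-cell indices; errors when the position is outside the domain.
env_cell_index <- function(grid, lon, lat) {
  res_x <- grid$lon[2] - grid$lon[1]
  res_y <- grid$lat[2] - grid$lat[1]
  outside <- lon < grid$lon[1] - res_x / 2 | lon > grid$lon[length(grid$lon)] + res_x / 2 |
    lat < grid$lat[1] - res_y / 2 | lat > grid$lat[length(grid$lat)] + res_y / 2
  if (any(outside)) stop("position outside environment grid domain")
  i <- pmin(pmax(round((lon - grid$lon[1]) / res_x) + 1, 1), length(grid$lon))
  j <- pmin(pmax(round((lat - grid$lat[1]) / res_y) + 1, 1), length(grid$lat))
  cbind(i = as.integer(i), j = as.integer(j))
}

#' Is a position inside the grid domain?
#' @param grid An [env_grid()].
#' @param lon,lat Position(s), degrees.
#' @return Logical vector.
#' @export
env_contains <- function(grid, lon, lat) {
  res_x <- grid$lon[2] - grid$lon[1]
  res_y <- grid$lat[2] - grid$lat[1]
  lon >= grid$lon[1] - res_x / 2 & lon <= grid$lon[length(grid$lon)] + res_x / 2 &
    lat >= grid$lat[1] - res_y / 2 & lat <= grid$lat[length(grid$lat)] + res_y / 2
}

#' Extract the water-column profile at the nearest grid cell
#'
#' @param grid An [env_grid()].
#' @param lon,lat Position, degrees.
#' @return A data.frame with `depth` and one column per field.
#' @export
env_column <- function(grid, lon, lat) {
  ij <- env_cell_index(grid, lon, lat)
  out <- data.frame(depth = grid$depth)
  for (v in names(grid$fields)) out[[v]] <- grid$fields[[v]][ij[1], ij[2], ]
  out
}

#' Field value at the nearest cell, interpolated linearly in depth
#'
#' @param grid An [env_grid()].
#' @param lon,lat Positions (vectors recycle).
#' @param depth Depth in metres (scalar).
#' @param var Field name.
#' @return Numeric vector.
#' @export
env_value_at <- function(grid, lon, lat, depth, var = "do") {
  n <- max(length(lon), length(lat))
  lon <- rep_len(lon, n); lat <- rep_len(lat, n)
  ij <- env_cell_index(grid, lon, lat)
  z <- grid$depth
  if (depth <= z[1]) {
    ks <- c(1L, 1L); wz <- 0
  } else if (depth >= z[length(z)]) {
    ks <- c(length(z), length(z)); wz <- 0
  } else {
    k <- findInterval(depth, z)
    ks <- c(k, k + 1L)
    wz <- (depth - z[k]) / (z[k + 1] - z[k])
  }
  f <- grid$fields[[var]]
  v1 <- f[cbind(ij[, 1], ij[, 2], ks[1])]
  v2 <- f[cbind(ij[, 1], ij[, 2], ks[2])]
  (1 - wz) * v1 + wz * v2
}

#' Logical OMZ mask at a reference depth
#'
#' @param grid An [env_grid()].
#' @param threshold DO threshold in ml/l (default 3.5).
#' @param ref_depth Reference depth in metres (default 100).
#' @return Logical matrix `[lon, lat]`, `TRUE` where DO at `ref_depth` is
#'   strictly below `threshold`.
#' @export
omz_mask <- function(grid, threshold = 3.5, ref_depth = 100) {
  z <- grid$depth
  f <- grid$fields$do
  if (ref_depth %in% z) {
    m <- f[, , which(z == ref_depth)]
  } else {
    k <- findInterval(ref_depth, z)
    wz <- (ref_depth - z[k]) / (z[k + 1] - z[k])
    m <- (1 - wz) * f[, , k] + wz * f[, , k + 1]
  }
  m < threshold
}

#' Fraction of the domain area inside the OMZ mask
#'
#' Cell areas are weighted by `cos(lat)`.
#'
#' @inheritParams omz_mask
#' @return Scalar in `[0, 1]`.
#' @export
omz_area_fraction <- function(grid, threshold = 3.5, ref_depth = 100) {
  m <- omz_mask(grid, threshold, ref_depth)
  wlat <- cos(grid$lat * pi / 180)
  wmat <- matrix(wlat, nrow = nrow(m), ncol = ncol(m), byrow = TRUE)
  sum(wmat[m]) / sum(wmat)
}

#' Write an environment grid to NetCDF
#'
#' Dimensions `lon`, `lat`, `depth`; one variable per field with units in
#' attributes.
#'
#' @param grid An [env_grid()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_env_nc <- function(grid, path) {
  dim_lon <- ncdf4::ncdim_def("lon", "degrees_east", grid$lon)
  dim_lat <- ncdf4::ncdim_def("lat", "degrees_north", grid$lat)
  dim_z <- ncdf4::ncdim_def("depth", "m", grid$depth)
  vars <- lapply(names(grid$fields), function(v)
    ncdf4::ncvar_def(v, ENV_UNITS[[v]], list(dim_lon, dim_lat, dim_z),
                     missval = NA_real_, prec = "double"))
  nc <- ncdf4::nc_create(path, vars)
  on.exit(ncdf4::nc_close(nc))
  for (k in seq_along(vars))
    ncdf4::ncvar_put(nc, vars[[k]], grid$fields[[names(grid$fields)[k]]])
  invisible(path)
}

#' Read an environment grid from NetCDF
#'
#' @param path File written by [write_env_nc()].
#' @return An [env_grid()].
#' @export
read_env_nc <- function(path) {
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  lon <- as.vector(nc$dim$lon$vals)
  lat <- as.vector(nc$dim$lat$vals)
  depth <- as.vector(nc$dim$depth$vals)
  fields <- list()
  for (v in intersect(ENV_VARS, names(nc$var)))
    fields[[v]] <- ncdf4::ncvar_get(nc, v, collapse_degen = FALSE)
  env_grid(lon, lat, depth, fields)
}
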