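# Matching tracks to the gridded environment, oxygen unit conversions,
# partial pressure of oxygen, and OMZ classification.
#
# Oxygen physics used here:
#   * molar volume of O2: 22.392 l/mol, so 1 ml/l = 44.659 umol/l;
#   * 1 mg/l = 22.392/31.9988 = 0.69978 ml/l;
#   * per-kg concentrations divide by surface seawater density (EOS-80);
#   * O2 solubility (air saturation) from the Garcia & Gordon (1992) fit to
#     the Benson & Krause data, ml/l coefficients;
#   * seawater vapour pressure from the Weiss & Price (1980) formulation;
#   * pO2 = (DO / DO_sat) * 0.20946 * (101.325 - pH2O) kPa, i.e. the mole
#     fraction of O2 in dry air times total pressure (1 atm) less vapour
#     pressure, scaled by fractional saturation. Hydrostatic pressure is not
#     applied: values are referenced to surface pressure.

O2_MOLAR_VOLUME <- 22.392     # l/mol
O2_MOLAR_MASS <- 31.9988      # g/mol
O2_MOLE_FRACTION <- 0.20946   # in dry air
ATM_KPA <- 101.325

#' Surface seawater density (EOS-80)
#'
#' Density of seawater at atmospheric pressure from the UNESCO 1983
#' (EOS-80) polynomial.
#'
#' @param temp Temperature, degC.
#' @param sal Practical salinity, PSU.
#' @return Density in kg/m^3.
#' @export
sw_density <- function(temp, sal) {
  t <- temp
  rho_w <- 999.842594 + 6.793952e-2 * t - 9.095290e-3 * t^2 +
    1.001685e-4 * t^3 - 1.120083e-6 * t^4 + 6.536332e-9 * t^5
  A <- 0.824493 - 4.0899e-3 * t + 7.6438e-5 * t^2 - 8.2467e-7 * t^3 +
    5.3875e-9 * t^4
  B <- -5.72466e-3 + 1.0227e-4 * t - 1.6546e-6 * t^2
  C <- 4.8314e-4
  rho_w + A * sal + B * sal^1.5 + C * sal^2
}

#' Oxygen solubility (air saturation concentration)
#'
#' Garcia & Gordon (1992) combined fit to the Benson & Krause data, ml/l
#' coefficient set; valid for open-ocean temperature and salinity.
#'
#' @inheritParams sw_density
#' @return Saturation DO in ml/l.
#' @export
o2_saturation <- function(temp, sal) {
  ts <- log((298.15 - temp) / (273.15 + temp))
  a <- c(2.00907, 3.22014, 4.05010, 4.94457, -0.256847, 3.88767)
  b <- c(-6.24523e-3, -7.37614e-3, -1.03410e-2, -8.17083e-3)
  c0 <- -4.88682e-7
  lnc <- a[1] + a[2] * ts + a[3] * ts^2 + a[4] * ts^3 + a[5] * ts^4 +
    a[6] * ts^5 + sal * (b[1] + b[2] * ts + b[3] * ts^2 + b[4] * ts^3) +
    c0 * sal^2
  exp(lnc)
}

#' Vapour pressure of seawater
#'
#' Weiss & Price (1980) formulation.
#'
#' @inheritParams sw_density
#' @return Vapour pressure in kPa.
#' @export
water_vapor_pressure <- function(temp, sal) {
  tk <- temp + 273.15
  p_atm <- exp(24.4543 - 67.4509 * (100 / tk) - 4.8489 * log(tk / 100) -
                 0.000544 * sal)
  p_atm * ATM_KPA
}

#' Convert dissolved oxygen between units
#'
#' Supported units: `"ml/l"`, `"mg/l"`, `"umol/l"`, `"umol/kg"`. The per-kg
#' conversion uses surface seawater density from `(temp, sal)`. All
#' conversions round-trip to within 1e-9.
#'
#' @param value DO value(s) in `from` units.
#' @param from,to Unit strings.
#' @param temp,sal Temperature (degC) and salinity (PSU); required only for
#'   `umol/kg`.
#' @return Converted value(s).
#' @export
convert_o2_units <- function(value, from, to, temp = NULL, sal = NULL) {
  units <- c("ml/l", "mg/l", "umol/l", "umol/kg")
  if (!(from %in% units) || !(to %in% units))
    stop("unknown oxygen unit; use one of: ", paste(units, collapse = ", "))
  if (from == to) return(value)
  need_rho <- "umol/kg" %in% c(from, to)
  if (need_rho && (is.null(temp) || is.null(sal)))
    stop("temp and sal are required for umol/kg conversions")
  rho_kg_l <- if (need_rho) sw_density(temp, sal) / 1000 else NULL
  # hub unit: umol/l
  to_umol_l <- switch(from,
    "ml/l" = value * 1000 / O2_MOLAR_VOLUME,
    "mg/l" = value / O2_MOLAR_MASS * 1000,
    "umol/l" = value,
    "umol/kg" = value * rho_kg_l)
  switch(to,
    "ml/l" = to_umol_l * O2_MOLAR_VOLUME / 1000,
    "mg/l" = to_umol_l * O2_MOLAR_MASS / 1000,
    "umol/l" = to_umol_l,
    "umol/kg" = to_umol_l / rho_kg_l)
}

#' Partial pressure of oxygen implied by DO, temperature and salinity
#'
#' Linear in DO at fixed `(temp, sal)`; equals the atmospheric O2 partial
#' pressure (about 20.9 kPa) when DO is at air saturation.
#'
#' @param do Dissolved oxygen, ml/l (`>= 0`).
#' @inheritParams sw_density
#' @return pO2 in kPa.
#' @export
po2_from_do <- function(do, temp, sal) {
  if (any(do < 0, na.rm = TRUE)) stop("negative DO is not physical")
  sat <- o2_saturation(temp, sal)
  if (any(sat <= 0, na.rm = TRUE)) stop("invalid (temp, sal): non-positive solubility")
  (do / sat) * O2_MOLE_FRACTION * (ATM_KPA - water_vapor_pressure(temp, sal))
}

#' Box-average the environment around a position
#'
#' Averages every field over the grid pixels whose centres fall inside the
#' closed box `position +/- (lon_halfwidth, lat_halfwidth)`, per depth level.
#' On the native 0.25-degree grid the defaults select a 5 x 3 pixel
#' neighbourhood (1.25 degrees of latitude by 0.75 of longitude), absorbing
#' geolocation error. Pixels with missing values are excluded from that
#' variable's mean; a box clipped by the domain edge averages the remaining
#' pixels.
#'
#' @param grid An [env_grid()].
#' @param lon,lat Position, degrees (must be inside the domain).
#' @param lat_halfwidth,lon_halfwidth Box half-widths, degrees.
#' @return An `env_sample`: list with per-depth profiles (`do`, `temp`,
#'   `sal`, `npp`, `chl`, `phyto`, `po2`, over `depth`) and scalar summaries
#'   (`sst`, `do_100`, `temp_100`, `sal_surface`, `sal_100`, `npp_100`,
#'   `chl_surface`, `chl_100`, `phyto_surface`, `phyto_100`).
#' @export
box_average <- function(grid, lon, lat, lat_halfwidth = 0.625,
                        lon_halfwidth = 0.375) {
  if (!env_contains(grid, lon, lat))
    stop("position outside environment grid domain")
  ii <- which(grid$lon >= lon - lon_halfwidth & grid$lon <= lon + lon_halfwidth)
  jj <- which(grid$lat >= lat - lat_halfwidth & grid$lat <= lat + lat_halfwidth)
  if (length(ii) == 0 || length(jj) == 0) {
    ij <- env_cell_index(grid, lon, lat) # tiny box: fall back to nearest pixel
    ii <- ij[1]; jj <- ij[2]
  }
  prof <- list(depth = grid$depth)
  for (v in names(grid$fields)) {
    block <- grid$fields[[v]][ii, jj, , drop = FALSE]
    prof[[v]] <- apply(block, 3, function(m) {
      m <- m[is.finite(m)]
      if (length(m) == 0) NA_real_ else mean(m)
    })
  }
  sample_from_profiles(prof)
}

at_depth <- function(depth, values, d) {
  if (all(is.na(values))) return(NA_real_)
  stats::approx(depth, values, xout = d, rule = 2)$y
}

sample_from_profiles <- function(prof) {
  s <- prof
  if (!is.null(prof$do) && !is.null(prof$temp) && !is.null(prof$sal))
    s$po2 <- po2_from_do(prof$do, prof$temp, prof$sal)
  s$sst <- prof$temp[1]
  s$do_100 <- at_depth(prof$depth, prof$do, 100)
  s$temp_100 <- at_depth(prof$depth, prof$temp, 100)
  s$sal_surface <- prof$sal[1]
  s$sal_100 <- at_depth(prof$depth, prof$sal, 100)
  s$npp_100 <- at_depth(prof$depth, prof$npp, 100)
  s$chl_surface <- prof$chl[1]
  s$chl_100 <- at_depth(prof$depth, prof$chl, 100)
  s$phyto_surface <- prof$phyto[1]
  s$phyto_100 <- at_depth(prof$depth, prof$phyto, 100)
  class(s) <- "env_sample"
  s
}

#' Classify OMZ membership from an environmental sample
#'
#' A position counts as inside the OMZ area when DO at the reference depth is
#' strictly below the threshold ("decreased below" 3.5 ml/l); a value exactly
#' at the threshold is outside. Missing DO propagates as `NA`.
#'
#' @param sample An `env_sample` from [box_average()], or a numeric DO value
#'   at the reference depth.
#' @param threshold DO threshold, ml/l (default 3.5).
#' @param ref_depth Reference depth, m (default 100; used when `sample` is an
#'   `env_sample`).
#' @return Logical (`NA` when DO is missing).
#' @export
classify_omz <- function(sample, threshold = 3.5, ref_depth = 100) {
  do_ref <- if (inherits(sample, "env_sample"))
    at_depth(sample$depth, sample$do, ref_depth) else sample
  ifelse(is.na(do_ref), NA, do_ref < threshold)
}

#' Match every track day to the environment
#'
#' Box-averages the environment around each daily position and appends the
#' scalar covariates plus the OMZ classification.
#'
#' @param track A `shark_track` from [regularize_daily()] (columns `date`,
#'   `lon`, `lat`).
#' @param grid An [env_grid()].
#' @param threshold,ref_depth Passed to [classify_omz()].
#' @inheritParams box_average
#' @return `track` with columns `sst`, `temp_100`, `sal_surface`, `sal_100`,
#'   `do_100`, `npp_100`, `chl_surface`, `chl_100`, `phyto_surface`,
#'   `phyto_100`, `po2_100`, `inside_omz` appended.
#' @export
match_environment <- function(track, grid, threshold = 3.5, ref_depth = 100,
                              lat_halfwidth = 0.625, lon_halfwidth = 0.375) {
  cols <- c("sst", "temp_100", "sal_surface", "sal_100", "do_100", "npp_100",
            "chl_surface", "chl_100", "phyto_surface", "phyto_100")
  for (cc in c(cols, "po2_100")) track[[cc]] <- NA_real_
  track$inside_omz <- NA
  for (i in seq_len(nrow(track))) {
    s <- box_average(grid, track$lon[i], track$lat[i],
                     lat_halfwidth, lon_halfwidth)
    for (cc in cols) track[[cc]][i] <- s[[cc]]
    track$po2_100[i] <- at_depth(s$depth, s$po2, ref_depth)
    track$inside_omz[i] <- classify_omz(s, threshold, ref_depth)
  }
  track
}
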