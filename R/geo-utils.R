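# Great-circle helpers on a spherical Earth, R = 6371 km. All functions
# take/return decimal degrees, longitudes in [-180, 180), distances in km,
# bearings in degrees clockwise from north in [0, 360).

EARTH_RADIUS_KM <- 6371

#' Great-circle (haversine) distance in kilometres
#'
#' @param lon1,lat1,lon2,lat2 Coordinates in decimal degrees; vectors recycle.
#' @return Numeric vector of distances in km.
#' @export
gc_distance_km <- function(lon1, lat1, lon2, lat2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = EARTH_RADIUS_KM)
}

#' Initial great-circle bearing
#'
#' @inheritParams gc_distance_km
#' @return Bearing in degrees clockwise from north, in `[0, 360)`.
#' @export
gc_bearing <- function(lon1, lat1, lon2, lat2) {
  b <- geosphere::bearing(cbind(lon1, lat1), cbind(lon2, lat2))
  b[is.na(b)] <- 0 # coincident points: bearing undefined, report 0
  (b + 360) %% 360
}

#' Destination point along a great circle
#'
#' @param lon,lat Start coordinates (degrees).
#' @param bearing Initial bearing, degrees clockwise from north.
#' @param distance_km Distance travelled in km.
#' @return Matrix with columns `lon`, `lat`.
#' @export
gc_destination <- function(lon, lat, bearing, distance_km) {
  p <- geosphere::destPoint(cbind(lon, lat), bearing, distance_km,
                            r = EARTH_RADIUS_KM)
  colnames(p) <- c("lon", "lat")
  p
}

#' Intermediate points on a great circle
#'
#' Returns `n` points strictly between the two endpoints, equally spaced in
#' arc length. Longitudes are continuous across the antimeridian.
#'
#' @inheritParams gc_distance_km
#' @param n Number of intermediate points.
#' @return Matrix with columns `lon`, `lat` (`n` rows).
#' @export
gc_intermediate <- function(lon1, lat1, lon2, lat2, n) {
  p <- geosphere::gcIntermediate(c(lon1, lat1), c(lon2, lat2), n = n,
                                 addStartEnd = FALSE)
  p <- matrix(p, ncol = 2)
  colnames(p) <- c("lon", "lat")
  p
}

#' Normalize longitudes to [-180, 180)
#' @param lon Longitudes in degrees.
#' @return Normalized longitudes.
#' @export
wrap_lon <- function(lon) {
  ((lon + 180) %% 360) - 180
}

# Absolute angular difference between two bearings, in [0, 180].
bearing_deviation <- function(b1, b2) {
  abs(((b2 - b1 + 180) %% 360) - 180)
}
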