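# Spherical geometry helpers shared by the simulator, track processing and
# raster sampling. All distances in metres on a sphere of mean Earth radius.

EARTH_RADIUS_M <- 6371008.8

#' Great-circle distance between points
#'
#' Haversine distance on a sphere of mean Earth radius (6371008.8 m).
#' Inputs are recycled to a common length.
#'
#' @param lon1,lat1,lon2,lat2 Coordinates in decimal degrees (WGS84).
#' @return Numeric vector of distances in metres.
#' @export
haversine_m <- function(lon1, lat1, lon2, lat2) {
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  a <- pmin(1, pmax(0, a))
  2 * EARTH_RADIUS_M * asin(sqrt(a))
}

#' Initial great-circle bearing
#'
#' Geographic bearing from point 1 to point 2, degrees clockwise from North
#' in \code{[0, 360)}.
#'
#' @inheritParams haversine_m
#' @return Numeric vector of bearings in degrees.
#' @export
bearing_deg <- function(lon1, lat1, lon2, lat2) {
  to_rad <- pi / 180
  dlon <- (lon2 - lon1) * to_rad
  y <- sin(dlon) * cos(lat2 * to_rad)
  x <- cos(lat1 * to_rad) * sin(lat2 * to_rad) -
    sin(lat1 * to_rad) * cos(lat2 * to_rad) * cos(dlon)
  (atan2(y, x) * 180 / pi) %% 360
}

#' Project lon/lat to local planar metres
#'
#' Azimuthal-equidistant projection centred on a reference point (typically
#' the breeding colony). Distances from the centre are exact on the sphere;
#' distortion elsewhere is far below 0.1 percent within a few hundred km,
#' which is all a central-place foraging range needs. The colony itself
#' projects to (0, 0), x points east and y points north.
#'
#' @param lon,lat Points to project, decimal degrees.
#' @param center Length-2 numeric, \code{c(lon, lat)} of the projection
#'   centre.
#' @return A two-column matrix \code{x}, \code{y} in metres.
#' @seealso [xy_to_lonlat()] for the inverse.
#' @export
lonlat_to_xy <- function(lon, lat, center) {
  stopifnot(length(center) == 2, all(is.finite(center)))
  if (any(abs(lat) >= 89.5)) {
    stop("latitudes at or near the poles are outside the projection domain")
  }
  if (diff(range(lon)) > 6) {
    warning("fixes span more than 6 degrees of longitude; ",
            "projection distortion may be noticeable")
  }
  to_rad <- pi / 180
  lon0 <- center[1] * to_rad
  lat0 <- center[2] * to_rad
  lonr <- lon * to_rad
  latr <- lat * to_rad
  cosc <- sin(lat0) * sin(latr) + cos(lat0) * cos(latr) * cos(lonr - lon0)
  cosc <- pmin(1, pmax(-1, cosc))
  c_ang <- acos(cosc)
  k <- ifelse(c_ang < 1e-12, 1, c_ang / sin(c_ang))
  x <- EARTH_RADIUS_M * k * cos(latr) * sin(lonr - lon0)
  y <- EARTH_RADIUS_M * k *
    (cos(lat0) * sin(latr) - sin(lat0) * cos(latr) * cos(lonr - lon0))
  cbind(x = x, y = y)
}

#' Inverse azimuthal-equidistant projection
#'
#' @param x,y Planar coordinates in metres as produced by [lonlat_to_xy()].
#' @param center Length-2 numeric \code{c(lon, lat)} used for the forward
#'   projection.
#' @return A two-column matrix \code{lon}, \code{lat} in degrees.
#' @export
xy_to_lonlat <- function(x, y, center) {
  to_rad <- pi / 180
  lon0 <- center[1] * to_rad
  lat0 <- center[2] * to_rad
  rho <- sqrt(x^2 + y^2)
  c_ang <- rho / EARTH_RADIUS_M
  lat <- ifelse(
    rho < 1e-9, lat0,
    asin(cos(c_ang) * sin(lat0) + (y / pmax(rho, 1e-9)) * sin(c_ang) * cos(lat0))
  )
  lon <- ifelse(
    rho < 1e-9, lon0,
    lon0 + atan2(x * sin(c_ang),
                 rho * cos(lat0) * cos(c_ang) - y * sin(lat0) * sin(c_ang))
  )
  cbind(lon = lon / to_rad, lat = lat / to_rad)
}

# Circular mean of bearings in degrees, result in [0, 360).
circular_mean_deg <- function(deg) {
  if (length(deg) == 0) return(NA_real_)
  r <- deg * pi / 180
  (atan2(mean(sin(r)), mean(cos(r))) * 180 / pi) %% 360
}
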