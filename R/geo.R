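.check_coords <- function(lat, lon) {
  if (any(!is.finite(lat)) || any(!is.finite(lon)) ||
      any(abs(lat) > 90) || any(abs(lon) > 180)) {
    stop("invalid coordinates: need finite |lat| <= 90 and |lon| <= 180")
  }
  invisible(TRUE)
}

#' Great-circle distance between points
#'
#' Haversine distance on a sphere of radius 6371.0088 km (IUGG mean Earth
#' radius). Arguments are recycled to a common length.
#'
#' @param lat1,lon1 first point(s), decimal degrees.
#' @param lat2,lon2 second point(s), decimal degrees.
#' @return distance(s) in kilometres.
#' @examples
#' great_circle_distance(0, 0, 1, 0)  # one degree of latitude, ~111.195 km
#' @export
great_circle_distance <- function(lat1, lon1, lat2, lon2) {
  .check_coords(lat1, lon1)
  .check_coords(lat2, lon2)
  rad <- pi / 180
  dlat <- (lat2 - lat1) * rad
  dlon <- (lon2 - lon1) * rad
  a <- sin(dlat / 2)^2 + cos(lat1 * rad) * cos(lat2 * rad) * sin(dlon / 2)^2
  2 * .EARTH_RADIUS_KM * asin(sqrt(pmin(a, 1)))
}

#' Initial bearing from one point toward another
#'
#' @inheritParams great_circle_distance
#' @return bearing(s) in degrees clockwise from true north, in [0, 360).
#' @export
initial_bearing <- function(lat1, lon1, lat2, lon2) {
  .check_coords(lat1, lon1)
  .check_coords(lat2, lon2)
  rad <- pi / 180
  p1 <- lat1 * rad; p2 <- lat2 * rad
  dl <- (lon2 - lon1) * rad
  y <- sin(dl) * cos(p2)
  x <- cos(p1) * sin(p2) - sin(p1) * cos(p2) * cos(dl)
  (atan2(y, x) / rad) %% 360
}

#' Destination point along a great circle
#'
#' @param lat,lon start point, decimal degrees.
#' @param bearing_deg initial bearing, degrees clockwise from north.
#' @param distance_km distance travelled, km.
#' @return data.frame with columns `lat`, `lon`.
#' @export
destination_point <- function(lat, lon, bearing_deg, distance_km) {
  .check_coords(lat, lon)
  rad <- pi / 180
  d <- distance_km / .EARTH_RADIUS_KM
  th <- bearing_deg * rad
  p1 <- lat * rad
  l1 <- lon * rad
  p2 <- asin(sin(p1) * cos(d) + cos(p1) * sin(d) * cos(th))
  l2 <- l1 + atan2(sin(th) * sin(d) * cos(p1), cos(d) - sin(p1) * sin(p2))
  data.frame(lat = p2 / rad, lon = ((l2 / rad + 180) %% 360) - 180)
}

# Azimuthal-equidistant projection about an origin: exact geodesic distance
# and bearing mapped to planar polar coordinates. Returns metres.
project_aeqd <- function(lat, lon, origin_lat, origin_lon) {
  d <- great_circle_distance(origin_lat, origin_lon, lat, lon) * 1000
  b <- initial_bearing(origin_lat, origin_lon, lat, lon) * pi / 180
  b[d == 0] <- 0
  cbind(x = d * sin(b), y = d * cos(b))
}

# Inverse of project_aeqd (metres back to lat/lon).
unproject_aeqd <- function(x, y, origin_lat, origin_lon) {
  d <- sqrt(x^2 + y^2) / 1000
  b <- (atan2(x, y) * 180 / pi) %% 360
  out <- destination_point(origin_lat, origin_lon, b, d)
  out$lat[d == 0] <- origin_lat
  out$lon[d == 0] <- origin_lon
  out
}
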