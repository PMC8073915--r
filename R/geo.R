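# Spherical geodesy. All distances use the IUGG mean Earth radius
# 6371.0088 km on a sphere; at the scale of 100-1000 km migration legs the
# difference from ellipsoidal geodesics is below 0.5% and immaterial here.

EARTH_RADIUS_KM <- 6371.0088

.check_coords <- function(lat, lon) {
  if (any(!is.finite(lat)) || any(!is.finite(lon)))
    .stopf("non-finite coordinates")
  if (any(lat < -90 | lat > 90))
    .stopf("latitude out of [-90, 90]")
  if (any(lon < -180 | lon > 180))
    .stopf("longitude out of [-180, 180]")
  invisible(TRUE)
}

#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6371.0088 km. Vectorised over
#' all four coordinate arguments.
#'
#' @param lat1,lon1 start coordinates, decimal degrees WGS84
#' @param lat2,lon2 end coordinates, decimal degrees WGS84
#' @return distance in km, `>= 0`
#' @examples
#' geodesic_km(0, 0, 0, 1)   # one equatorial degree, ~111.2 km
#' @export
geodesic_km <- function(lat1, lon1, lat2, lon2) {
  .check_coords(lat1, lon1)
  .check_coords(lat2, lon2)
  n <- max(length(lat1), length(lat2))
  p1 <- cbind(rep_len(lon1, n), rep_len(lat1, n))
  p2 <- cbind(rep_len(lon2, n), rep_len(lat2, n))
  geosphere::distHaversine(p1, p2, r = EARTH_RADIUS_KM * 1000) / 1000
}

#' Initial bearing (forward azimuth) between two points
#'
#' Degrees clockwise from true north, in `[0, 360)`. Undefined for
#' coincident or antipodal point pairs, which raise an error.
#'
#' @inheritParams geodesic_km
#' @return bearing in degrees
#' @export
initial_bearing <- function(lat1, lon1, lat2, lon2) {
  .check_coords(lat1, lon1)
  .check_coords(lat2, lon2)
  d <- geodesic_km(lat1, lon1, lat2, lon2)
  half <- pi * EARTH_RADIUS_KM
  if (any(d < 1e-9))
    .stopf("bearing undefined for coincident points")
  if (any(abs(d - half) < 1e-3))
    .stopf("bearing undefined for antipodal points")
  n <- max(length(lat1), length(lat2))
  b <- geosphere::bearing(cbind(rep_len(lon1, n), rep_len(lat1, n)),
                          cbind(rep_len(lon2, n), rep_len(lat2, n)))
  b %% 360
}

#' Destination point given start, bearing and distance
#'
#' @inheritParams geodesic_km
#' @param bearing_deg forward azimuth, degrees clockwise from north
#' @param dist_km distance along the great circle, km
#' @return matrix with columns `lon`, `lat`
#' @export
destination_point <- function(lat1, lon1, bearing_deg, dist_km) {
  .check_coords(lat1, lon1)
  p <- geosphere::destPoint(cbind(lon1, lat1), bearing_deg, dist_km * 1000,
                            r = EARTH_RADIUS_KM * 1000)
  colnames(p) <- c("lon", "lat")
  p
}

# equally spaced points along the great circle (start and end included)
.gc_path <- function(lat1, lon1, lat2, lon2, n_points) {
  if (n_points < 2) n_points <- 2
  p <- geosphere::gcIntermediate(c(lon1, lat1), c(lon2, lat2),
                                 n = n_points - 2, addStartEnd = TRUE)
  colnames(p) <- c("lon", "lat")
  p
}

# smallest absolute angular difference between two bearings, degrees in [0, 180]
.angle_diff <- function(a, b) {
  d <- abs((a - b) %% 360)
  pmin(d, 360 - d)
}
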