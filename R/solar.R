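# Solar ephemeris: NOAA's low-precision solar position equations
# (Meeus-derived, as used in the NOAA sunrise/sunset calculator).
# Sunrise/sunset are taken at zenith 90.833 degrees, i.e. the sun's upper
# limb on the horizon under standard atmospheric refraction. Accuracy is a
# small fraction of a minute over 1950-2100, well inside the +/-2 min
# contract of these routines.

# Julian day number at 00:00 UT of a Date
.julian_day <- function(date) {
  as.numeric(date) + 2440587.5
}

# solar declination (deg) and equation of time (minutes) at Julian centuries jc
.solar_basis <- function(jc) {
  L0 <- (280.46646 + jc * (36000.76983 + 0.0003032 * jc)) %% 360
  M  <- 357.52911 + jc * (35999.05029 - 0.0001537 * jc)
  e  <- 0.016708634 - jc * (0.000042037 + 0.0000001267 * jc)
  Mr <- .deg2rad(M)
  C  <- sin(Mr) * (1.914602 - jc * (0.004817 + 0.000014 * jc)) +
        sin(2 * Mr) * (0.019993 - 0.000101 * jc) +
        sin(3 * Mr) * 0.000289
  true_long <- L0 + C
  omega <- 125.04 - 1934.136 * jc
  lambda <- true_long - 0.00569 - 0.00478 * sin(.deg2rad(omega))
  eps0 <- 23 + (26 + (21.448 - jc * (46.815 + jc * (0.00059 - jc * 0.001813))) / 60) / 60
  eps  <- eps0 + 0.00256 * cos(.deg2rad(omega))
  decl <- .rad2deg(asin(sin(.deg2rad(eps)) * sin(.deg2rad(lambda))))
  y <- tan(.deg2rad(eps / 2))^2
  L0r <- .deg2rad(L0)
  eqtime <- 4 * .rad2deg(
    y * sin(2 * L0r) - 2 * e * sin(Mr) + 4 * e * y * sin(Mr) * cos(2 * L0r) -
      0.5 * y^2 * sin(4 * L0r) - 1.25 * e^2 * sin(2 * Mr))
  list(decl = decl, eqtime = eqtime)
}

# hour angle (deg) of the sun at the given zenith, or NA outside [-1, 1]
.hour_angle <- function(lat, decl, zenith) {
  latr <- .deg2rad(lat); dr <- .deg2rad(decl)
  cosH <- (cos(.deg2rad(zenith)) - sin(latr) * sin(dr)) / (cos(latr) * cos(dr))
  ifelse(abs(cosH) > 1, NA_real_, .rad2deg(acos(cosH)))
}

#' Sunrise and sunset for a date and location
#'
#' NOAA solar-position computation at zenith 90.833 degrees (upper limb,
#' standard refraction). The returned events bracket local solar noon of
#' `date`, so for far-eastern longitudes the sunrise can fall on the
#' previous UTC day. At polar latitudes the regime is flagged and no event
#' times are returned.
#'
#' @param lat,lon location in decimal degrees
#' @param date a `Date` (or coercible), years 1950-2100
#' @return list with `date`, `lat`, `lon`, `sunrise_utc`, `sunset_utc`
#'   (`POSIXct` UTC or `NA`), `regime` one of `"normal"`, `"polar_day"`,
#'   `"polar_night"`, and `day_length_min`
#' @export
sun_times <- function(lat, lon, date) {
  .check_coords(lat, lon)
  date <- as.Date(date)
  yr <- as.integer(format(date, "%Y"))
  if (yr < 1950 || yr > 2100) .stopf("date outside supported years 1950-2100")
  jd <- .julian_day(date)
  zen <- 90.833

  # iterate: evaluate declination/eqtime at progressively better event times
  noon_min <- 720 - 4 * lon            # first guess, minutes UTC
  for (i in 1:2) {
    b <- .solar_basis((jd + noon_min / 1440 - 2451545) / 36525)
    noon_min <- 720 - 4 * lon - b$eqtime
  }
  b_noon <- .solar_basis((jd + noon_min / 1440 - 2451545) / 36525)
  ha0 <- .hour_angle(lat, b_noon$decl, zen)
  if (is.na(ha0)) {
    # polar regime: sign of (declination vs latitude) decides day or night
    up <- sin(.deg2rad(lat)) * sin(.deg2rad(b_noon$decl)) >
          cos(.deg2rad(zen))  # sun above horizon at solar noon
    return(list(date = date, lat = lat, lon = lon,
                sunrise_utc = as.POSIXct(NA, tz = "UTC"),
                sunset_utc = as.POSIXct(NA, tz = "UTC"),
                regime = if (up) "polar_day" else "polar_night",
                day_length_min = if (up) 1440 else 0))
  }
  rise_min <- noon_min - 4 * ha0
  set_min  <- noon_min + 4 * ha0
  for (i in 1:2) {
    br <- .solar_basis((jd + rise_min / 1440 - 2451545) / 36525)
    ha <- .hour_angle(lat, br$decl, zen)
    if (!is.na(ha)) rise_min <- 720 - 4 * lon - br$eqtime - 4 * ha
    bs <- .solar_basis((jd + set_min / 1440 - 2451545) / 36525)
    ha <- .hour_angle(lat, bs$decl, zen)
    if (!is.na(ha)) set_min <- 720 - 4 * lon - bs$eqtime + 4 * ha
  }
  midnight <- as.POSIXct(paste(date, "00:00:00"), tz = "UTC")
  list(date = date, lat = lat, lon = lon,
       sunrise_utc = midnight + rise_min * 60,
       sunset_utc = midnight + set_min * 60,
       regime = "normal",
       day_length_min = set_min - rise_min)
}

# the sunrise/sunset instance nearest to time t at (lat, lon).
# Returns a POSIXct, or +/-Inf-like sentinels for polar regimes:
#  polar_day: sunrise at -Inf, sunset at +Inf (sun always up)
#  polar_night: sunrise at +Inf, sunset at -Inf (sun never up)
.nearest_event <- function(lat, lon, t, type = c("sunrise", "sunset")) {
  type <- match.arg(type)
  d0 <- as.Date(t, tz = "UTC")
  best <- NULL; best_gap <- Inf; regime <- "normal"
  for (d in c(-1, 0, 1)) {
    st <- sun_times(lat, lon, d0 + d)
    if (st$regime != "normal") { regime <- st$regime; next }
    ev <- if (type == "sunrise") st$sunrise_utc else st$sunset_utc
    gap <- abs(as.numeric(difftime(ev, t, units = "mins")))
    if (gap < best_gap) { best <- ev; best_gap <- gap }
  }
  if (!is.null(best)) return(best)
  up <- regime == "polar_day"
  if (type == "sunrise") { if (up) -Inf else Inf } else { if (up) Inf else -Inf }
}

#' Daylight minutes within a 12-h track segment
#'
#' Daylight is the time between sunrise and sunset evaluated at the
#' segment's endpoint locations: a day segment contributes the overlap of
#' `[t0, t1]` with `[sunrise at start location, sunset at end location]`;
#' a night segment contributes evening daylight before sunset at the start
#' location plus morning daylight after sunrise at the end location. Each
#' sunrise/sunset instance is the one nearest the relevant endpoint time.
#'
#' @param segment a one-row data frame (or list) with `t_start`, `t_end`,
#'   `lat_start`, `lon_start`, `lat_end`, `lon_end` and `phase`
#' @return daylight minutes, clipped to `[0, segment duration]`
#' @export
daylight_overlap <- function(segment) {
  t0 <- segment$t_start; t1 <- segment$t_end
  if (t1 <= t0) .stopf("segment must have positive duration")
  dur <- as.numeric(difftime(t1, t0, units = "mins"))
  n0 <- as.numeric(t0); n1 <- as.numeric(t1)
  if (identical(segment$phase, "day")) {
    sr <- .nearest_event(segment$lat_start, segment$lon_start, t0, "sunrise")
    ss <- .nearest_event(segment$lat_end, segment$lon_end, t1, "sunset")
    mins <- (min(n1, as.numeric(ss)) - max(n0, as.numeric(sr))) / 60
    .clip(mins, 0, dur)
  } else {
    ss <- .nearest_event(segment$lat_start, segment$lon_start, t0, "sunset")
    sr <- .nearest_event(segment$lat_end, segment$lon_end, t1, "sunrise")
    evening <- .clip((as.numeric(ss) - n0) / 60, 0, dur)
    morning <- .clip((n1 - as.numeric(sr)) / 60, 0, dur)
    .clip(evening + morning, 0, dur)
  }
}

#' Add daylight minutes to a segment table
#'
#' @param segments a segment table from [build_segments()]
#' @return `segments` with a `daylight_min` column
#' @export
add_daylight <- function(segments) {
  segments$daylight_min <- vapply(seq_len(nrow(segments)), function(i)
    daylight_overlap(segments[i, , drop = FALSE]), numeric(1))
  segments
}
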