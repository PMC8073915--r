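# Gridded surface wind fields (eastward U, northward V on a regular
# lat/lon lattice at 6-hourly steps) and the wind covariates derived from
# them. Direction follows the oceanographic "toward" convention (the
# direction the air is moving to), with 0 deg = north; a helper converts
# to the meteorological "from" convention.

#' Construct a wind grid
#'
#' @param lats ascending latitudes, degrees, regular spacing
#' @param lons ascending longitudes, degrees, regular spacing
#' @param times POSIXct UTC timestamps, strictly increasing, 6-hourly
#' @param U,V eastward/northward wind (m/s), arrays of dim
#'   `(time, lat, lon)`
#' @return a `wind_grid` object
#' @export
wind_grid <- function(lats, lons, times, U, V) {
  .check_regular <- function(x, nm) {
    if (length(x) > 1) {
      d <- diff(x)
      if (any(d <= 0) || max(abs(d - d[1])) > 1e-6)
        .stopf("%s must be strictly increasing and regularly spaced", nm)
    }
  }
  .check_regular(lats, "lats"); .check_regular(lons, "lons")
  tn <- as.numeric(times)
  if (length(tn) > 1) {
    d <- diff(tn)
    if (any(d <= 0) || max(abs(d - 6 * 3600)) > 1)
      .stopf("times must be strictly increasing at 6-h spacing")
  }
  dims <- c(length(times), length(lats), length(lons))
  if (!identical(dim(U), as.integer(dims)) || !identical(dim(V), as.integer(dims)))
    .stopf("U and V must have dim (time=%d, lat=%d, lon=%d)",
           dims[1], dims[2], dims[3])
  structure(list(lats = lats, lons = lons, times = times, U = U, V = V),
            class = "wind_grid")
}

#' Read a wind grid from the plain CSV dialect
#'
#' Expects columns `time` (ISO-8601 UTC), `lat`, `lon`, `u`, `v`, one row
#' per lattice node, forming a complete time x lat x lon lattice.
#'
#' @param path CSV path
#' @return a [wind_grid()]
#' @export
read_wind_csv <- function(path) {
  if (!file.exists(path)) .stopf("wind file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time", "lat", "lon", "u", "v")
  miss <- setdiff(need, names(df))
  if (length(miss)) .stopf("wind CSV missing column(s): %s",
                           paste(miss, collapse = ", "))
  t <- .parse_utc(df$time)
  times <- sort(unique(t)); lats <- sort(unique(df$lat)); lons <- sort(unique(df$lon))
  if (nrow(df) != length(times) * length(lats) * length(lons))
    .stopf("wind CSV does not form a complete lattice")
  it <- match(t, times); ila <- match(df$lat, lats); ilo <- match(df$lon, lons)
  U <- V <- array(NA_real_, c(length(times), length(lats), length(lons)))
  U[cbind(it, ila, ilo)] <- df$u
  V[cbind(it, ila, ilo)] <- df$v
  wind_grid(lats, lons, times, U, V)
}

#' Write a wind grid to the plain CSV dialect
#' @param grid a [wind_grid()]
#' @param path output path
#' @export
write_wind_csv <- function(grid, path) {
  g <- expand.grid(ilo = seq_along(grid$lons), ila = seq_along(grid$lats),
                   it = seq_along(grid$times))
  df <- data.frame(time = .format_utc(grid$times[g$it]),
                   lat = grid$lats[g$ila], lon = grid$lons[g$ilo],
                   u = grid$U[cbind(g$it, g$ila, g$ilo)],
                   v = grid$V[cbind(g$it, g$ila, g$ilo)])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

.axis_frac <- function(x, axis, nm) {
  if (x < axis[1] - 1e-9 || x > axis[length(axis)] + 1e-9)
    .stopf("query outside grid envelope on axis '%s' (%.4f not in [%.4f, %.4f])",
           nm, x, axis[1], axis[length(axis)])
  x <- .clip(x, axis[1], axis[length(axis)])
  i <- findInterval(x, axis, rightmost.closed = TRUE)
  i <- min(i, length(axis) - 1L)
  if (length(axis) == 1L) return(list(i = 1L, w = 0))
  list(i = i, w = (x - axis[i]) / (axis[i + 1] - axis[i]))
}

#' Trilinear interpolation of the wind field
#'
#' Bilinear in space and linear in time, applied independently to U and V.
#' Exact at grid nodes and on fields affine in (lat, lon, t).
#'
#' @param grid a [wind_grid()]
#' @param lat,lon query location, degrees
#' @param t query time, POSIXct UTC
#' @return named vector `c(u, v)` in m/s
#' @export
interp_uv <- function(grid, lat, lon, t) {
  ft <- .axis_frac(as.numeric(t), as.numeric(grid$times), "time")
  fa <- .axis_frac(lat, grid$lats, "lat")
  fo <- .axis_frac(lon, grid$lons, "lon")
  take <- function(A) {
    acc <- 0
    for (dt in 0:1) for (da in 0:1) for (do in 0:1) {
      w <- (if (dt) ft$w else 1 - ft$w) *
           (if (da) fa$w else 1 - fa$w) *
           (if (do) fo$w else 1 - fo$w)
      if (w > 0)
        acc <- acc + w * A[min(ft$i + dt, dim(A)[1]),
                           min(fa$i + da, dim(A)[2]),
                           min(fo$i + do, dim(A)[3])]
    }
    acc
  }
  c(u = take(grid$U), v = take(grid$V))
}

#' Tailwind assistance along an optimal travel direction
#'
#' The component of the wind vector projected onto the optimal direction:
#' `Ta = u sin(theta) + v cos(theta)` with `theta` the optimal direction in
#' degrees clockwise from north. Positive when the wind flows along the
#' optimal direction of travel, negative for headwind. No airspeed enters.
#'
#' @param u,v wind components, m/s (eastward, northward)
#' @param optimal_deg optimal travel direction, degrees in `[0, 360)`
#' @return tailwind assistance, m/s
#' @export
tailwind <- function(u, v, optimal_deg) {
  th <- .deg2rad(optimal_deg)
  u * sin(th) + v * cos(th)
}

#' Wind speed and direction from U/V components
#'
#' @param u,v wind components, m/s
#' @return list with `u`, `v`, `speed` (m/s), `dir_toward` (degrees
#'   clockwise from north that the air moves toward; `NA` with
#'   `undefined = TRUE` for calm air), and `dir_from`
#' @export
speed_dir <- function(u, v) {
  speed <- sqrt(u^2 + v^2)
  dir <- ifelse(speed == 0, NA_real_, .rad2deg(atan2(u, v)) %% 360)
  list(u = u, v = v, speed = speed, dir_toward = dir,
       dir_from = (dir + 180) %% 360, undefined = speed == 0)
}

#' Optimal crossing direction for a waterbody and destination
#'
#' The assumed preferred flight direction over each waterbody: westward
#' (270) across the Caribbean Sea, northwest (315) across the Gulf of
#' Honduras, and across the Gulf of Mexico 315/0/45 for birds bound for
#' Texas, Manitoba or Florida respectively.
#'
#' @param waterbody `"caribbean"`, `"gulf_of_honduras"` or
#'   `"gulf_of_mexico"`
#' @param destination `"texas"`, `"manitoba"` or `"florida"` (only used
#'   for the Gulf of Mexico)
#' @return direction in degrees clockwise from north
#' @export
assign_optimal_direction <- function(waterbody, destination = NULL) {
  switch(waterbody,
    caribbean = 270,
    gulf_of_honduras = 315,
    gulf_of_mexico = {
      if (is.null(destination)) .stopf("destination needed for gulf_of_mexico")
      switch(destination, texas = 315, manitoba = 0, florida = 45,
             .stopf("unknown destination '%s'", destination))
    },
    .stopf("unknown waterbody '%s'", waterbody))
}

.sector_index <- function(deg, n_sectors) {
  w <- 360 / n_sectors
  (floor(((deg %% 360) + w / 2) / w) %% n_sectors) + 1L
}

.sector_names <- function(n_sectors) {
  sprintf("%.1f", (seq_len(n_sectors) - 1) * 360 / n_sectors)
}

#' Windrose frequency table
#'
#' Bins wind samples by direction sector (sector 1 centred on north) and
#' speed class.
#'
#' @param samples a [speed_dir()] result (or list with `speed`,
#'   `dir_toward`)
#' @param n_sectors number of equal direction sectors (16 gives the
#'   22.5-degree compass rose)
#' @param speed_breaks interior speed class breaks, m/s
#' @return integer matrix, sectors (rows, named by centre bearing) by
#'   speed classes; frequencies sum to the sample count
#' @export
windrose_table <- function(samples, n_sectors = 16, speed_breaks = c(2, 4, 6, 8)) {
  if (n_sectors < 1 || n_sectors != round(n_sectors))
    .stopf("n_sectors must be a positive integer")
  breaks <- c(0, sort(speed_breaks), Inf)
  labs <- paste0("[", breaks[-length(breaks)], ",", breaks[-1], ")")
  tab <- matrix(0L, n_sectors, length(labs),
                dimnames = list(.sector_names(n_sectors), labs))
  keep <- !is.na(samples$dir_toward)
  if (any(keep)) {
    si <- .sector_index(samples$dir_toward[keep], n_sectors)
    ci <- findInterval(samples$speed[keep], breaks, rightmost.closed = FALSE)
    for (k in seq_along(si)) tab[si[k], ci[k]] <- tab[si[k], ci[k]] + 1L
  }
  tab
}

#' Histogram of flight bearings by compass sector
#'
#' @param bearings bearings in degrees (any real; reduced mod 360)
#' @param n_sectors number of equal sectors
#' @return named integer vector of sector counts (sector 1 centred north)
#' @export
bearing_histogram <- function(bearings, n_sectors = 16) {
  if (n_sectors < 1 || n_sectors != round(n_sectors))
    .stopf("n_sectors must be a positive integer")
  counts <- integer(n_sectors)
  names(counts) <- .sector_names(n_sectors)
  if (length(bearings)) {
    si <- .sector_index(bearings, n_sectors)
    for (k in si) counts[k] <- counts[k] + 1L
  }
  counts
}
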