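# Land/water mask: named simple polygons in lon/lat degrees. Everything
# outside the water polygons is land. Point-in-polygon uses the even-odd
# ray-casting rule in lon/lat space, which is adequate for the regional,
# non-polar masks this analysis works with.

#' Construct a land/water mask
#'
#' @param polygons named list of water polygons, each a data frame or
#'   matrix with columns `lon`, `lat` (ring need not be explicitly closed)
#' @return a `land_water_mask` object
#' @export
land_water_mask <- function(polygons) {
  if (is.null(names(polygons)) || anyDuplicated(names(polygons)))
    .stopf("water polygons must have unique names")
  polys <- lapply(polygons, function(p) {
    p <- as.matrix(as.data.frame(p)[, c("lon", "lat")])
    storage.mode(p) <- "double"
    # drop an explicit closing vertex
    n <- nrow(p)
    if (n >= 2 && all(p[1, ] == p[n, ])) p <- p[-n, , drop = FALSE]
    if (nrow(p) < 3) .stopf("polygon must have at least 3 vertices")
    p
  })
  for (nm in names(polys))
    if (.self_intersects(polys[[nm]]))
      .stopf("polygon '%s' is self-intersecting", nm)
  structure(list(water_polygons = polys), class = "land_water_mask")
}

# proper intersection of two planar segments (shared endpoints excluded)
.seg_intersects <- function(ax, ay, bx, by, cx, cy, dx, dy) {
  cross <- function(ox, oy, px, py, qx, qy)
    (px - ox) * (qy - oy) - (py - oy) * (qx - ox)
  d1 <- cross(cx, cy, dx, dy, ax, ay)
  d2 <- cross(cx, cy, dx, dy, bx, by)
  d3 <- cross(ax, ay, bx, by, cx, cy)
  d4 <- cross(ax, ay, bx, by, dx, dy)
  (((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &
     ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0)))
}

.self_intersects <- function(ring) {
  n <- nrow(ring)
  a <- cbind(ring, ring[c(2:n, 1), , drop = FALSE])  # edges
  for (i in seq_len(n - 2)) {
    js <- (i + 2):n
    js <- js[!(i == 1 & js == n)]   # skip adjacent edges
    if (!length(js)) next
    hit <- .seg_intersects(a[i, 1], a[i, 2], a[i, 3], a[i, 4],
                           a[js, 1], a[js, 2], a[js, 3], a[js, 4])
    if (any(hit)) return(TRUE)
  }
  FALSE
}

# even-odd point-in-polygon, vectorised over points; boundary counts as out
.in_ring <- function(lon, lat, ring) {
  n <- nrow(ring)
  x1 <- ring[, 1]; y1 <- ring[, 2]
  x2 <- ring[c(2:n, 1), 1]; y2 <- ring[c(2:n, 1), 2]
  inside <- rep(FALSE, length(lon))
  for (e in seq_len(n)) {
    crosses <- ((y1[e] > lat) != (y2[e] > lat))
    if (any(crosses)) {
      xint <- x1[e] + (lat[crosses] - y1[e]) / (y2[e] - y1[e]) * (x2[e] - x1[e])
      flip <- lon[crosses] < xint
      inside[crosses][flip] <- !inside[crosses][flip]
    }
  }
  inside
}

#' Which water polygon (if any) contains each point
#'
#' @param mask a [land_water_mask()]
#' @param lon,lat point coordinates, degrees
#' @return character vector of polygon names, `NA` for points on land
#' @export
water_polygon_at <- function(mask, lon, lat) {
  out <- rep(NA_character_, length(lon))
  for (nm in names(mask$water_polygons)) {
    hit <- is.na(out) & .in_ring(lon, lat, mask$water_polygons[[nm]])
    out[hit] <- nm
  }
  out
}

#' Is each point over water?
#' @inheritParams water_polygon_at
#' @return logical vector
#' @export
is_water <- function(mask, lon, lat) !is.na(water_polygon_at(mask, lon, lat))

#' Read a land/water mask from GeoJSON
#'
#' Accepts a FeatureCollection of Polygon features, each carrying a
#' `name` property.
#'
#' @param path GeoJSON path
#' @return a [land_water_mask()]
#' @export
read_mask_geojson <- function(path) {
  if (!file.exists(path)) .stopf("mask file not found: %s", path)
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  feats <- gj$features
  if (is.null(feats)) .stopf("%s is not a GeoJSON FeatureCollection", path)
  polys <- list()
  for (f in feats) {
    if (!identical(f$geometry$type, "Polygon"))
      .stopf("only Polygon features are supported (got %s)", f$geometry$type)
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]], function(v)
      c(lon = v[[1]], lat = v[[2]])))
    nm <- f$properties$name %||% sprintf("water_%d", length(polys) + 1)
    polys[[nm]] <- ring
  }
  land_water_mask(polys)
}

#' Write a land/water mask to GeoJSON
#' @param mask a [land_water_mask()]
#' @param path output path
#' @export
write_mask_geojson <- function(mask, path) {
  feats <- lapply(names(mask$water_polygons), function(nm) {
    ring <- mask$water_polygons[[nm]]
    ring <- rbind(ring, ring[1, ])
    list(type = "Feature",
         properties = list(name = nm),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                           function(i) c(ring[i, 1], ring[i, 2])))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Classify track segments as land or water flights
#'
#' The great circle between the endpoint fixes is sampled every `step_km`;
#' each step is attributed to water when its midpoint falls inside a water
#' polygon. A segment is a water flight when more than `majority` of its
#' distance is over water.
#'
#' @param segments segment table from [build_segments()]
#' @param mask a [land_water_mask()]
#' @param step_km sampling step along the great circle, km
#' @param majority water-fraction threshold for calling a segment `water`
#' @return `segments` with columns `surface` (`"land"`/`"water"`),
#'   `water_km`, and `waterbody` (polygon holding the most water distance,
#'   `NA` for pure land segments)
#' @export
classify_surface <- function(segments, mask, step_km = 1, majority = 0.5) {
  n <- nrow(segments)
  segments$surface <- "land"
  segments$water_km <- 0
  segments$waterbody <- NA_character_
  for (i in seq_len(n)) {
    d <- segments$distance_km[i]
    if (d <= 0) next
    ns <- max(1L, ceiling(d / step_km))
    path <- .gc_path(segments$lat_start[i], segments$lon_start[i],
                     segments$lat_end[i], segments$lon_end[i], ns + 1L)
    mid_lon <- (path[-1, "lon"] + path[-nrow(path), "lon"]) / 2
    mid_lat <- (path[-1, "lat"] + path[-nrow(path), "lat"]) / 2
    wb <- water_polygon_at(mask, mid_lon, mid_lat)
    step_len <- d / ns
    wkm <- sum(!is.na(wb)) * step_len
    segments$water_km[i] <- wkm
    if (wkm / d > majority) segments$surface[i] <- "water"
    if (any(!is.na(wb))) {
      tab <- table(wb[!is.na(wb)])
      segments$waterbody[i] <- names(tab)[which.max(tab)]
    }
  }
  segments
}
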