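# Departure points and the cross/detour covariates.
#
# A departure point is the last over-land fix before a bird either launches
# a water crossing (decision "cross") or, while coasting a waterbody that
# blocks its preferred direction, turns sharply away from that direction
# (decision "detour"). Crossings are read off the segment surface
# classification (maximal runs of water segments); detours are detected
# with three configurable geometric conditions since real detours were
# identified by eye in the field literature.

#' Distance from a point to the nearest water polygon, km
#'
#' Point-to-boundary distance consistent with the planar lon/lat polygon
#' edges used for membership tests: each edge is treated as a straight
#' line in an equirectangular projection about the query point (good to a
#' small fraction of a percent at coastal-buffer scales).
#'
#' @param mask a [land_water_mask()]
#' @param lon,lat point, degrees
#' @return named numeric vector, distance per polygon
#' @export
point_to_water_km <- function(mask, lon, lat) {
  kx <- KM_PER_DEG_LAT * cos(.deg2rad(lat))
  ky <- KM_PER_DEG_LAT
  vapply(mask$water_polygons, function(ring) {
    if (.in_ring(lon, lat, ring)) return(0)
    n <- nrow(ring)
    x1 <- (ring[, 1] - lon) * kx; y1 <- (ring[, 2] - lat) * ky
    x2 <- x1[c(2:n, 1)]; y2 <- y1[c(2:n, 1)]
    dx <- x2 - x1; dy <- y2 - y1
    tt <- .clip(-(x1 * dx + y1 * dy) / pmax(dx^2 + dy^2, 1e-12), 0, 1)
    min(sqrt((x1 + tt * dx)^2 + (y1 + tt * dy)^2))
  }, numeric(1))
}

# length of the intersection of the ray (lon,lat,bearing) with each water
# polygon, by sampling every step_km out to max_range_km
.ray_water_km <- function(mask, lon, lat, bearing, max_range_km = 2500,
                          step_km = 5) {
  d <- seq(step_km / 2, max_range_km, by = step_km)
  p <- destination_point(lat, lon, bearing, d)
  wb <- water_polygon_at(mask, p[, "lon"], p[, "lat"])
  out <- vapply(names(mask$water_polygons),
                function(nm) sum(wb == nm, na.rm = TRUE) * step_km, numeric(1))
  out
}

# resolve the optimal crossing direction for (waterbody, destination):
# config$optimal_dirs may map a waterbody to a single bearing or to a
# per-destination list; otherwise fall back to the named-waterbody rule
.optimal_dir <- function(config, waterbody, destination) {
  od <- config$optimal_dirs
  if (!is.null(od) && !is.null(od[[waterbody]])) {
    e <- od[[waterbody]]
    if (is.numeric(e) && length(e) == 1) return(e)
    if (!is.null(destination) && !is.null(e[[destination]])) return(e[[destination]])
    .stopf("no optimal direction for waterbody '%s', destination '%s'",
           waterbody, destination %||% "<none>")
  }
  assign_optimal_direction(waterbody, destination)
}

#' Identify departure points from classified segments
#'
#' Crossing events are maximal runs of water segments; the departure is
#' the last land fix preceding the run (the start fix of the first water
#' segment). Detour events are land fixes that (i) lie within
#' `coastal_buffer_km` of a water polygon, (ii) whose ray along the bird's
#' optimal direction intersects that polygon for at least `min_block_km`,
#' and (iii) whose realised next bearing deviates from the optimal
#' direction by at least `detour_angle_deg`. A fix qualifying as both is a
#' crossing (actual water entry dominates); consecutive detour fixes at
#' the same waterbody collapse to the first.
#'
#' @param segments surface-classified segments (all birds)
#' @param mask a [land_water_mask()]
#' @param config a [pipeline_config()] (or plain list) carrying
#'   `destinations` (named by bird id), `optimal_dirs`,
#'   `coastal_buffer_km`, `min_block_km`, `detour_angle_deg`
#' @return data frame of departures: `bird_id`, `t`, `lat`, `lon`,
#'   `waterbody`, `decision`, `night`, `optimal_deg`, and for crossings
#'   `run_end_t` (end of the water run)
#' @export
identify_departures <- function(segments, mask, config = pipeline_config()) {
  buffer <- config$coastal_buffer_km %||% 50
  min_block <- config$min_block_km %||% 100
  min_angle <- config$detour_angle_deg %||% 60
  out <- list()
  for (id in unique(segments$bird_id)) {
    dest <- config$destinations[[id]]
    if (is.null(dest) && is.null(config$optimal_dirs))
      .stopf("no destination configured for bird %s", id)
    s <- segments[segments$bird_id == id, , drop = FALSE]
    s <- s[order(s$t_start), , drop = FALSE]
    r <- rle(s$surface == "water")
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    last_detour <- list(i = -10L, waterbody = "")
    for (k in seq_along(r$values)) {
      if (r$values[k]) {
        # crossing run
        i0 <- starts[k]; i1 <- ends[k]
        wkm <- tapply(s$water_km[i0:i1], s$waterbody[i0:i1], sum)
        wb <- names(wkm)[which.max(wkm)]
        out[[length(out) + 1]] <- data.frame(
          bird_id = id, t = s$t_start[i0],
          lat = s$lat_start[i0], lon = s$lon_start[i0],
          waterbody = wb, decision = "cross",
          night = s$phase[i0] == "night",
          optimal_deg = .optimal_dir(config, wb, dest),
          run_end_t = s$t_end[i1], stringsAsFactors = FALSE)
      } else {
        for (i in starts[k]:ends[k]) {
          if (s$distance_km[i] < 1) next   # no realised movement to judge
          near <- point_to_water_km(mask, s$lon_start[i], s$lat_start[i])
          cands <- names(near)[near <= buffer]
          if (!length(cands)) next
          realized <- initial_bearing(s$lat_start[i], s$lon_start[i],
                                      s$lat_end[i], s$lon_end[i])
          hit <- NULL
          for (nm in cands[order(near[cands])]) {
            od <- .optimal_dir(config, nm, dest)
            span <- .ray_water_km(mask, s$lon_start[i], s$lat_start[i], od)
            if (span[[nm]] >= min_block &&
                .angle_diff(realized, od) >= min_angle) { hit <- c(nm, od); break }
          }
          if (is.null(hit)) next
          if (last_detour$i == i - 1L && last_detour$waterbody == hit[1]) {
            last_detour$i <- i     # same episode, keep only the first fix
            next
          }
          last_detour <- list(i = i, waterbody = hit[1])
          out[[length(out) + 1]] <- data.frame(
            bird_id = id, t = s$t_start[i],
            lat = s$lat_start[i], lon = s$lon_start[i],
            waterbody = hit[1], decision = "detour",
            night = s$phase[i] == "night",
            optimal_deg = as.numeric(hit[2]),
            run_end_t = as.POSIXct(NA, tz = "UTC"), stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out))
    return(data.frame(bird_id = character(), t = .parse_utc(character()),
                      lat = numeric(), lon = numeric(), waterbody = character(),
                      decision = character(), night = logical(),
                      optimal_deg = numeric(),
                      run_end_t = .parse_utc(character())))
  res <- do.call(rbind, out)
  res <- res[order(res$bird_id, res$t), , drop = FALSE]
  rownames(res) <- NULL
  res
}

.exclusion <- function(msg) {
  structure(class = c("nightcross_exclusion", "error", "condition"),
            list(message = msg, call = NULL))
}

#' Water-crossing distance from a departure point
#'
#' The geodesic distance from the departure fix to the first subsequent
#' over-land fix on the far side of the waterbody (the straight path
#' crosses it) after which motion continues away from the waterbody in the
#' migration direction (next bearing within 90 degrees of the optimal
#' direction). For detours this is the hypothetical crossing the bird
#' declined.
#'
#' @param departure one row of [identify_departures()]
#' @param subsequent_fixes the bird's fixes after the departure time
#' @param mask a [land_water_mask()]
#' @param step_km sampling step when testing whether the straight path
#'   crosses the waterbody
#' @return list with `km` and the selected far-side `fix` (one-row data
#'   frame); a `nightcross_exclusion` error when no fix qualifies
#' @export
crossing_distance <- function(departure, subsequent_fixes, mask, step_km = 5) {
  f <- subsequent_fixes[subsequent_fixes$t > departure$t, , drop = FALSE]
  f <- f[order(f$t), , drop = FALSE]
  n <- nrow(f)
  for (k in seq_len(n)) {
    if (is_water(mask, f$lon[k], f$lat[k])) next
    d <- geodesic_km(departure$lat, departure$lon, f$lat[k], f$lon[k])
    if (d < 1) next
    ns <- max(2L, ceiling(d / step_km))
    path <- .gc_path(departure$lat, departure$lon, f$lat[k], f$lon[k], ns)
    wb <- water_polygon_at(mask, path[, "lon"], path[, "lat"])
    if (!any(wb == departure$waterbody, na.rm = TRUE)) next
    # motion away from the waterbody: bearing to the next moving fix
    onward <- NA_real_
    for (m in seq_len(n - k) + k) {
      if (geodesic_km(f$lat[k], f$lon[k], f$lat[m], f$lon[m]) >= 1) {
        onward <- initial_bearing(f$lat[k], f$lon[k], f$lat[m], f$lon[m])
        break
      }
    }
    if (is.na(onward) || .angle_diff(onward, departure$optimal_deg) > 90) next
    return(list(km = d, fix = f[k, , drop = FALSE]))
  }
  stop(.exclusion(sprintf(
    "no qualifying far-side land fix for bird %s departure at %s",
    departure$bird_id, .format_utc(departure$t))))
}

#' Shortest land-constrained (circumnavigation) distance
#'
#' Length of the shortest polyline between two over-land points that does
#' not cross any water polygon: a visibility graph over the two endpoints
#' and the water-polygon vertices, with water-avoiding straight edges
#' weighted by geodesic length.
#'
#' @param p_from,p_to numeric `c(lon, lat)`, both on land
#' @param mask a [land_water_mask()]
#' @return distance in km
#' @export
circumnavigation_distance <- function(p_from, p_to, mask) {
  if (is_water(mask, p_from[1], p_from[2]) || is_water(mask, p_to[1], p_to[2]))
    .stopf("circumnavigation endpoints must be on land")
  nodes <- rbind(p_from, p_to)
  for (ring in mask$water_polygons) nodes <- rbind(nodes, .offset_ring(ring))
  n <- nrow(nodes)
  edges <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (.edge_over_land(nodes[i, ], nodes[j, ], mask)) {
      w <- geodesic_km(nodes[i, 2], nodes[i, 1], nodes[j, 2], nodes[j, 1])
      edges[i, j] <- edges[j, i] <- max(w, 1e-9)
    }
  }
  g <- igraph::graph_from_adjacency_matrix(edges, mode = "undirected",
                                           weighted = TRUE)
  d <- igraph::distances(g, v = 1, to = 2)[1, 1]
  if (!is.finite(d))
    .stopf("no land-constrained path exists between the points")
  d
}

# push ring vertices a few metres outward (along the bisector of the two
# adjacent edges' outward normals) so that visibility edges can run along
# the polygon boundary without being flagged as over water
.offset_ring <- function(ring, eps = 1e-4) {
  n <- nrow(ring)
  # polygon orientation via the shoelace sum
  nxt <- c(2:n, 1); prv <- c(n, 1:(n - 1))
  area2 <- sum(ring[, 1] * ring[nxt, 2] - ring[nxt, 1] * ring[, 2])
  ccw <- area2 > 0
  out <- ring
  for (i in seq_len(n)) {
    e1 <- ring[i, ] - ring[prv[i], ]   # incoming edge
    e2 <- ring[nxt[i], ] - ring[i, ]   # outgoing edge
    nrm <- function(e) {               # outward normal
      v <- if (ccw) c(e[2], -e[1]) else c(-e[2], e[1])
      v / max(sqrt(sum(v^2)), 1e-12)
    }
    d <- nrm(e1) + nrm(e2)
    d <- d / max(sqrt(sum(d^2)), 1e-12)
    out[i, ] <- ring[i, ] + eps * d
  }
  out
}

# a straight (planar lon/lat) edge stays over land when it properly
# crosses no polygon edge and none of its interior sample points falls
# strictly inside a polygon
.edge_over_land <- function(a, b, mask) {
  if (all(a == b)) return(FALSE)
  for (ring in mask$water_polygons) {
    m <- nrow(ring)
    nx <- c(2:m, 1)
    hit <- .seg_intersects(a[1], a[2], b[1], b[2],
                           ring[, 1], ring[, 2], ring[nx, 1], ring[nx, 2])
    if (any(hit)) return(FALSE)
  }
  for (tt in c(0.1, 0.25, 0.5, 0.75, 0.9)) {
    p <- a + tt * (b - a)
    if (is_water(mask, p[1], p[2])) return(FALSE)
  }
  TRUE
}

#' Water:land distance-savings ratio
#'
#' Water-crossing distance divided by the land-constrained
#' circumnavigation distance between the same endpoints. Values near one
#' mean crossing saves little distance.
#'
#' @param cross_km,land_km distances in km, both positive
#' @return the ratio
#' @export
water_land_ratio <- function(cross_km, land_km) {
  if (any(cross_km <= 0) || any(land_km <= 0))
    .stopf("distances must be positive")
  cross_km / land_km
}

#' Scale and centre a covariate
#'
#' `(x - mean) / sd` with the sample (divisor `n - 1`) standard deviation.
#'
#' @param x numeric, `n >= 2`, non-constant
#' @return standardised vector with attributes `center` and `scale`
#' @export
scale_center <- function(x) {
  if (length(x) < 2) .stopf("scale_center needs at least two values")
  s <- stats::sd(x)
  if (s == 0) .stopf("scale_center undefined for constant input")
  structure((x - mean(x)) / s, center = mean(x), scale = s)
}

#' Attach model covariates to departure points
#'
#' For each departure: the tailwind assistance interpolated from the wind
#' grid at the departure fix and time, the water-crossing distance to the
#' far-side fix, the circumnavigation distance between the same endpoints,
#' and their ratio. Departures with no qualifying far-side fix are
#' excluded, with the reason recorded in the `"exclusions"` attribute.
#'
#' @param departures output of [identify_departures()]
#' @param fixes the full fix table (for far-side search)
#' @param wind a [wind_grid()]
#' @param mask a [land_water_mask()]
#' @return departures with `tailwind_ms`, `cross_km`, `circ_km`, `ratio`
#' @export
departure_covariates <- function(departures, fixes, wind, mask) {
  n <- nrow(departures)
  departures$tailwind_ms <- NA_real_
  departures$cross_km <- departures$circ_km <- departures$ratio <- NA_real_
  excl <- character()
  for (i in seq_len(n)) {
    dep <- departures[i, , drop = FALSE]
    uv <- interp_uv(wind, dep$lat, dep$lon, dep$t)
    departures$tailwind_ms[i] <- tailwind(uv[["u"]], uv[["v"]], dep$optimal_deg)
    sub <- fixes[fixes$bird_id == dep$bird_id, , drop = FALSE]
    res <- tryCatch(crossing_distance(dep, sub, mask),
                    nightcross_exclusion = function(e) e)
    if (inherits(res, "nightcross_exclusion")) {
      excl <- c(excl, conditionMessage(res)); next
    }
    circ <- tryCatch(circumnavigation_distance(
      c(dep$lon, dep$lat), c(res$fix$lon, res$fix$lat), mask),
      error = function(e) NA_real_)
    if (!is.finite(circ)) {
      excl <- c(excl, sprintf("no land path for bird %s departure at %s",
                              dep$bird_id, .format_utc(dep$t)))
      next
    }
    departures$cross_km[i] <- res$km
    departures$circ_km[i] <- circ
    departures$ratio[i] <- water_land_ratio(res$km, circ)
  }
  keep <- !is.na(departures$ratio)
  out <- departures[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "exclusions") <- excl
  out
}
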