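# shared fixtures and independent oracles, all built in code

# --- sunrise/sunset benchmarks -------------------------------------------
# Computed with an independent Michalsky (1988) solar-position
# implementation scanning solar altitude at minute resolution for the
# -0.833 degree horizon crossing; spot-checked against published
# almanac values (e.g. Greenwich summer-solstice 04:43/21:21 BST).
solar_benchmarks <- function() {
  data.frame(
    lat = c(0, 51.4778, 40.7128, 29.76, -23.55, 64.13, 19.43, -33.87, 10, 45),
    lon = c(0, 0, -74.006, -95.37, -46.63, -21.9, -99.13, 151.21, -75, 10),
    date = as.Date(c("2018-03-20", "2018-06-21", "2018-03-12", "2018-04-01",
                     "2018-01-15", "2019-12-21", "2019-04-15", "2020-06-21",
                     "2018-03-25", "2021-09-22")),
    sunrise = c("2018-03-20T06:04:13Z", "2018-06-21T03:42:43Z",
                "2018-03-12T11:12:33Z", "2018-04-01T12:10:53Z",
                "2018-01-15T08:33:10Z", "2019-12-21T11:21:40Z",
                "2019-04-15T12:19:06Z", "2020-06-20T21:00:02Z",
                "2018-03-25T11:01:16Z", "2021-09-22T05:07:06Z"),
    sunset = c("2018-03-20T18:10:44Z", "2018-06-21T20:20:51Z",
               "2018-03-12T22:59:33Z", "2018-04-02T00:40:10Z",
               "2018-01-15T21:58:33Z", "2019-12-21T15:29:25Z",
               "2019-04-16T00:54:18Z", "2020-06-21T06:53:55Z",
               "2018-03-25T23:10:42Z", "2021-09-22T17:17:23Z"),
    stringsAsFactors = FALSE)
}

utc <- function(x) as.POSIXct(sub("Z$", "", sub("T", " ", x)), tz = "UTC")

# --- minute-grid daylight oracle -----------------------------------------
# brute-force integration of the daylight indicator over minute midpoints,
# using the endpoint-location sunrise/sunset events nearest the endpoints
oracle_daylight <- function(seg) {
  nearest <- function(lat, lon, t, type) {
    best <- NA; bg <- Inf
    for (d in -1:1) {
      st <- sun_times(lat, lon, as.Date(t, tz = "UTC") + d)
      if (st$regime != "normal") next
      ev <- if (type == "sunrise") st$sunrise_utc else st$sunset_utc
      g <- abs(as.numeric(difftime(ev, t, units = "mins")))
      if (g < bg) { best <- as.numeric(ev); bg <- g }
    }
    best
  }
  mins <- seq(as.numeric(seg$t_start) + 30, as.numeric(seg$t_end) - 30, by = 60)
  if (seg$phase == "day") {
    sr <- nearest(seg$lat_start, seg$lon_start, seg$t_start, "sunrise")
    ss <- nearest(seg$lat_end, seg$lon_end, seg$t_end, "sunset")
    sum(mins >= sr & mins <= ss)
  } else {
    ss <- nearest(seg$lat_start, seg$lon_start, seg$t_start, "sunset")
    sr <- nearest(seg$lat_end, seg$lon_end, seg$t_end, "sunrise")
    sum(mins <= ss | mins >= sr)
  }
}

random_segment <- function() {
  lat0 <- runif(1, -40, 45); lon0 <- runif(1, -100, -50)
  phase <- sample(c("day", "night"), 1)
  base <- as.POSIXct("2018-03-01", tz = "UTC") + runif(1, 0, 40) * 86400
  t0 <- base + (if (phase == "day") 6 else 18) * 3600 + lon0 / 15 * 3600
  list(t_start = t0, t_end = t0 + 12 * 3600,
       lat_start = lat0, lon_start = lon0,
       lat_end = lat0 + runif(1, -3, 3), lon_end = lon0 + runif(1, -6, 6),
       phase = phase)
}

# --- simple masks and segment rows ---------------------------------------
rect_ring <- function(lon0, lon1, lat0, lat1)
  cbind(lon = c(lon0, lon1, lon1, lon0), lat = c(lat0, lat0, lat1, lat1))

square_mask <- function() land_water_mask(list(sq = rect_ring(-1, 1, 9, 11)))

seg_row <- function(bird = "B1", t0, hours = 12, lat0, lon0, lat1, lon1,
                    phase = "day", slot0 = "0600") {
  d <- geodesic_km(lat0, lon0, lat1, lon1)
  data.frame(bird_id = bird, t_start = t0, t_end = t0 + hours * 3600,
             lat_start = lat0, lon_start = lon0, lat_end = lat1,
             lon_end = lon1, slot_start = slot0, slot_end = "x",
             phase = phase, duration_h = hours, distance_km = d,
             stringsAsFactors = FALSE)
}

# small complete wind lattice with values from a supplied function f(t,lat,lon)
fn_wind_grid <- function(f_u, f_v, lats = seq(0, 10, 2.5),
                         lons = seq(-10, 0, 2.5),
                         times = seq(as.POSIXct("2018-03-01", tz = "UTC"),
                                     by = 6 * 3600, length.out = 5)) {
  U <- V <- array(0, c(length(times), length(lats), length(lons)))
  for (i in seq_along(times)) for (j in seq_along(lats))
    for (k in seq_along(lons)) {
      U[i, j, k] <- f_u(as.numeric(times[i]), lats[j], lons[k])
      V[i, j, k] <- f_v(as.numeric(times[i]), lats[j], lons[k])
    }
  wind_grid(lats, lons, times, U, V)
}

# --- lattice Dijkstra oracle for land-constrained shortest paths ----------
# dense grid search with knight-and-longer moves, followed by greedy
# line-of-sight shortcutting; independent of the visibility-graph route
oracle_circumnav <- function(p1, p2, mask, h = 0.2) {
  all_lon <- c(p1[1], p2[1], unlist(lapply(mask$water_polygons, function(r) r[, 1])))
  all_lat <- c(p1[2], p2[2], unlist(lapply(mask$water_polygons, function(r) r[, 2])))
  lons <- seq(min(all_lon) - 0.6, max(all_lon) + 0.6, by = h)
  lats <- seq(min(all_lat) - 0.6, max(all_lat) + 0.6, by = h)
  g <- expand.grid(lon = lons, lat = lats)
  land <- !is_water(mask, g$lon, g$lat)
  nodes <- rbind(p1, p2, as.matrix(g[land, ]))
  n <- nrow(nodes)
  land_edge <- function(a, b) {
    tt <- seq(0.05, 0.95, by = 0.1)
    px <- a[1] + tt * (b[1] - a[1]); py <- a[2] + tt * (b[2] - a[2])
    !any(is_water(mask, px, py))
  }
  # lattice neighbours: coprime offsets up to 3 cells
  offs <- expand.grid(di = -3:3, dj = -3:3)
  offs <- offs[!(offs$di == 0 & offs$dj == 0), ]
  keep <- mapply(function(a, b) {
    g <- function(x, y) if (y == 0) abs(x) else g(y, x %% y)
    g(abs(a), abs(b)) == 1
  }, offs$di, offs$dj)
  offs <- offs[keep, ]
  idx <- matrix(NA_integer_, length(lons), length(lats))
  gi <- round((nodes[-(1:2), 1] - lons[1]) / h) + 1
  gj <- round((nodes[-(1:2), 2] - lats[1]) / h) + 1
  idx[cbind(gi, gj)] <- seq_len(n - 2) + 2L
  ef <- et <- integer(0); ew <- numeric(0)
  for (o in seq_len(nrow(offs))) {
    gi2 <- gi + offs$di[o]; gj2 <- gj + offs$dj[o]
    ok <- gi2 >= 1 & gi2 <= length(lons) & gj2 >= 1 & gj2 <= length(lats)
    to <- rep(NA_integer_, length(gi)); to[ok] <- idx[cbind(gi2[ok], gj2[ok])]
    ok <- ok & !is.na(to)
    from <- seq_len(n - 2) + 2L
    valid <- which(ok)
    valid <- valid[vapply(valid, function(v)
      land_edge(nodes[from[v], ], nodes[to[v], ]), logical(1))]
    ef <- c(ef, from[valid]); et <- c(et, to[valid])
    ew <- c(ew, geodesic_km(nodes[from[valid], 2], nodes[from[valid], 1],
                            nodes[to[valid], 2], nodes[to[valid], 1]))
  }
  # hook the two endpoints to nearby lattice nodes
  for (s in 1:2) {
    near <- which(abs(nodes[-(1:2), 1] - nodes[s, 1]) <= 2.5 * h &
                    abs(nodes[-(1:2), 2] - nodes[s, 2]) <= 2.5 * h) + 2L
    near <- near[vapply(near, function(v)
      land_edge(nodes[s, ], nodes[v, ]), logical(1))]
    ef <- c(ef, rep(s, length(near))); et <- c(et, near)
    ew <- c(ew, geodesic_km(nodes[s, 2], nodes[s, 1],
                            nodes[near, 2], nodes[near, 1]))
  }
  gr <- igraph::graph_from_data_frame(
    data.frame(from = ef, to = et, weight = ew), directed = FALSE,
    vertices = data.frame(name = seq_len(n)))
  sp <- igraph::shortest_paths(gr, from = "1", to = "2", weights = NULL,
                               output = "vpath")$vpath[[1]]
  if (length(sp) == 0) stop("oracle: no path")
  path <- nodes[as.integer(igraph::as_ids(sp)), , drop = FALSE]
  # greedy line-of-sight smoothing
  i <- 1; sm <- path[1, , drop = FALSE]
  while (i < nrow(path)) {
    j <- nrow(path)
    while (j > i + 1 && !land_edge(path[i, ], path[j, ])) j <- j - 1
    sm <- rbind(sm, path[j, ]); i <- j
  }
  # rubber-band refinement: random shortcut splices between points along
  # the polyline until the path is taut around the obstacles
  plen <- function(p) sum(geodesic_km(p[-nrow(p), 2], p[-nrow(p), 1],
                                      p[-1, 2], p[-1, 1]))
  interp_at <- function(p, s) {     # point at arc-fraction s, with its edge
    d <- geodesic_km(p[-nrow(p), 2], p[-nrow(p), 1], p[-1, 2], p[-1, 1])
    cs <- cumsum(d); target <- s * cs[length(cs)]
    e <- which(cs >= target)[1]
    f <- (target - c(0, cs)[e]) / d[e]
    list(pt = p[e, ] + f * (p[e + 1, ] - p[e, ]), edge = e, frac = f)
  }
  for (it in 1:800) {
    if (nrow(sm) < 2) break
    ss <- sort(runif(2))
    a <- interp_at(sm, ss[1]); b <- interp_at(sm, ss[2])
    if (a$edge == b$edge) next
    if (!land_edge(a$pt, b$pt)) next
    sm <- rbind(sm[seq_len(a$edge), , drop = FALSE], a$pt, b$pt,
                sm[-seq_len(b$edge), , drop = FALSE])
  }
  plen(sm)
}
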