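t0 <- as.POSIXct("2018-03-20 11:00:00", tz = "UTC")

# a northbound track through the square water polygon (lon [-1,1], lat [9,11])
crossing_track <- function() {
  lat <- c(7, 8.5, 8.95, 9.6, 10.3, 11.05, 11.5, 12.5)
  segs <- do.call(rbind, lapply(seq_len(length(lat) - 1), function(i)
    seg_row(t0 = t0 + (i - 1) * 12 * 3600, lat0 = lat[i], lon0 = 0,
            lat1 = lat[i + 1], lon1 = 0,
            phase = if (i %% 2 == 0) "night" else "day")))
  classify_surface(segs, square_mask())
}

cfg_sq <- pipeline_config(optimal_dirs = list(sq = 0),
                          destinations = list(B1 = "texas"))

test_that("a run of water segments yields one crossing departure", {
  segs <- crossing_track()
  expect_identical(segs$surface, c("land", "land", "water", "water", "water",
                                   "land", "land"))
  deps <- identify_departures(segs, square_mask(), cfg_sq)
  expect_equal(nrow(deps), 1)
  expect_identical(deps$decision, "cross")
  expect_equal(deps$lat, 8.95)            # last land fix before the run
  expect_identical(deps$waterbody, "sq")
  expect_false(deps$night)                # run starts on a day segment
})

test_that("a sharp coastal turn inside the buffer is a detour", {
  m <- square_mask()
  approach <- seg_row(t0 = t0, lat0 = 7.5, lon0 = 0, lat1 = 8.7, lon1 = 0)
  turn <- seg_row(t0 = t0 + 12 * 3600, lat0 = 8.7, lon0 = 0,
                  lat1 = 8.7, lon1 = -1.5, phase = "night")
  onward <- seg_row(t0 = t0 + 24 * 3600, lat0 = 8.7, lon0 = -1.5,
                    lat1 = 9.5, lon1 = -1.6)
  segs <- classify_surface(rbind(approach, turn, onward), m)
  deps <- identify_departures(segs, m, cfg_sq)
  det <- deps[deps$decision == "detour", ]
  expect_equal(nrow(det), 1)
  expect_equal(det$lat, 8.7)
  expect_true(det$night)
  # a track nowhere near water produces no departures
  far <- classify_surface(seg_row(t0 = t0, lat0 = 20, lon0 = 0,
                                  lat1 = 22, lon1 = 0), m)
  expect_equal(nrow(identify_departures(far, m, cfg_sq)), 0)
})

test_that("shallow turns and out-of-buffer fixes are not detours", {
  m <- square_mask()
  # 30-degree deviation only
  shallow <- classify_surface(rbind(
    seg_row(t0 = t0, lat0 = 8.7, lon0 = 2.5, lat1 = 9.9, lon1 = 3.2)), m)
  expect_equal(nrow(identify_departures(shallow, m, cfg_sq)), 0)
  # right angle but 200 km south of the coast
  away <- classify_surface(rbind(
    seg_row(t0 = t0, lat0 = 7.2, lon0 = 0, lat1 = 7.2, lon1 = -1.5)), m)
  expect_equal(nrow(identify_departures(away, m, cfg_sq)), 0)
})

test_that("crossing distance picks the first qualifying far-side fix", {
  segs <- crossing_track()
  deps <- identify_departures(segs, square_mask(), cfg_sq)
  fx <- data.frame(bird_id = "B1",
                   t = t0 + (1:7) * 12 * 3600,
                   lat = c(8.5, 8.95, 9.6, 10.3, 11.05, 11.5, 12.5), lon = 0)
  res <- crossing_distance(deps[1, ], fx, square_mask())
  expect_equal(res$fix$lat, 11.05)
  expect_equal(res$km, geodesic_km(8.95, 0, 11.05, 0), tolerance = 1e-9)
})

test_that("a detour's hypothetical crossing is measured over water", {
  dep <- data.frame(bird_id = "B1", t = t0, lat = 8.7, lon = 0,
                    waterbody = "sq", decision = "detour", night = FALSE,
                    optimal_deg = 0)
  fx <- data.frame(bird_id = "B1", t = t0 + (1:4) * 12 * 3600,
                   lat = c(8.7, 11.4, 11.8, 12.6), lon = c(-1.3, -1.3, 0, 0))
  res <- crossing_distance(dep, fx, square_mask())
  expect_equal(res$fix$lat, 11.4)   # first land fix beyond the waterbody
  expect_equal(res$km, geodesic_km(8.7, 0, 11.4, -1.3), tolerance = 1e-9)
})

test_that("departures without a far-side fix raise an exclusion", {
  dep <- data.frame(bird_id = "B1", t = t0, lat = 8.7, lon = 0,
                    waterbody = "sq", decision = "cross", night = FALSE,
                    optimal_deg = 0)
  fx <- data.frame(bird_id = "B1", t = t0 + (1:2) * 12 * 3600,
                   lat = c(8.6, 8.5), lon = 0)   # never reaches the far side
  expect_error(crossing_distance(dep, fx, square_mask()),
               class = "nightcross_exclusion")
})

test_that("circumnavigation reduces to the geodesic when unobstructed", {
  m <- square_mask()
  expect_equal(circumnavigation_distance(c(3, 8), c(3, 12), m),
               geodesic_km(8, 3, 12, 3), tolerance = 1e-6)
})

test_that("circumnavigation rounds the obstacle and is symmetric", {
  m <- square_mask()
  d <- circumnavigation_distance(c(0, 8.9), c(0, 11.1), m)
  expect_gt(d, geodesic_km(8.9, 0, 11.1, 0))
  expect_equal(circumnavigation_distance(c(0, 11.1), c(0, 8.9), m), d,
               tolerance = 1e-9)
  # brute-force lattice search agrees within 1%
  set.seed(123)
  o <- oracle_circumnav(c(0, 8.9), c(0, 11.1), m)
  expect_lt(abs(d - o) / o, 0.01)
  expect_error(circumnavigation_distance(c(0, 10), c(0, 12), m), "on land")
})

test_that("the distance-savings ratio behaves as documented", {
  expect_equal(water_land_ratio(871, 937), 0.9296, tolerance = 1e-4)
  expect_equal(water_land_ratio(500, 1000), 0.5)
  expect_equal(water_land_ratio(700, 700), 1)
  expect_error(water_land_ratio(0, 10), "positive")
  expect_error(water_land_ratio(10, -1), "positive")
  # ratio < 1 exactly when crossing is shorter than circumnavigating
  expect_lt(water_land_ratio(400, 600), 1)
  expect_gt(water_land_ratio(700, 600), 1)
})

test_that("scale_center standardises to mean 0, sample SD 1", {
  expect_equal(as.numeric(scale_center(c(1, 3))),
               c(-0.7071068, 0.7071068), tolerance = 1e-6)
  z <- scale_center(c(2, 4, 6, 8))
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  zz <- scale_center(as.numeric(z))
  expect_equal(as.numeric(zz), as.numeric(z), tolerance = 1e-12)
  expect_error(scale_center(rep(2, 5)), "constant")
  expect_error(scale_center(3), "two values")
})
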