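sched2 <- function(id = "B1") tag_schedule(id, -5, c("0600", "1800"), "texas")

write_fix_csv <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(c("bird_id,timestamp,lat,lon", lines), f)
  f
}

test_that("fix reading parses, sorts and assigns schedule slots", {
  sch <- list(B1 = sched2())
  expect_equal(nrow(read_fixes(write_fix_csv(character()), sch)), 0)
  # 23:00 UTC is 18:00 CDT -> slot 1800
  fx <- read_fixes(write_fix_csv("B1,2018-03-12T23:00:00Z,10.0,-75.0"), sch)
  expect_identical(fx$slot, "1800")
  # out-of-order rows come back sorted by time
  fx <- read_fixes(write_fix_csv(c("B1,2018-03-13T11:00:00Z,11.0,-75.0",
                                   "B1,2018-03-12T23:00:00Z,10.0,-75.0")), sch)
  expect_true(all(diff(as.numeric(fx$t)) > 0))
  expect_identical(fx$slot, c("1800", "0600"))
})

test_that("malformed rows, unknown birds and off-schedule fixes are handled", {
  sch <- list(B1 = sched2())
  expect_error(read_fixes(write_fix_csv("B1,2018-03-12T23:00:00Z,95.0,-75.0"),
                          sch), "line 2")
  expect_error(read_fixes(write_fix_csv("B1,not-a-time,10,-75"), sch), "line 2")
  expect_error(read_fixes(write_fix_csv("B9,2018-03-12T23:00:00Z,10,-75"),
                          sch), "B9")
  expect_warning(
    fx <- read_fixes(write_fix_csv("B1,2018-03-12T20:30:00Z,10,-75"), sch),
    "tolerance")
  expect_identical(fx$slot, "adhoc")
})

test_that("schedule normalisation marks interior fixes and is idempotent", {
  sch3 <- tag_schedule("B2", -5, c("0000", "0600", "1800"), "texas")
  t <- utc(c("2018-03-12T23:00:00Z", "2018-03-13T05:00:00Z",
             "2018-03-13T11:00:00Z"))
  fx <- data.frame(bird_id = "B2", t = t, lat = c(10, 10.5, 11),
                   lon = -75, slot = c("1800", "0000", "0600"))
  n1 <- normalize_schedule(fx, sch3)
  expect_identical(n1$waypoint, c(FALSE, TRUE, FALSE))
  expect_identical(normalize_schedule(n1, sch3), n1)
  # 2-slot schedules pass through unchanged
  fx2 <- data.frame(bird_id = "B1", t = t[c(1, 3)], lat = c(10, 11),
                    lon = -75, slot = c("1800", "0600"))
  expect_false(any(normalize_schedule(fx2, sched2())$waypoint))
  # the 0400/1000/1600 programme folds 1000 into the day interval
  sch3b <- tag_schedule("B3", -5, c("0400", "1000", "1600"), "texas")
  t2 <- utc(c("2018-03-13T09:00:00Z", "2018-03-13T15:00:00Z",
              "2018-03-13T21:00:00Z"))
  fx3 <- data.frame(bird_id = "B3", t = t2, lat = c(10, 10.5, 11), lon = -75,
                    slot = c("0400", "1000", "1600"))
  expect_identical(normalize_schedule(fx3, sch3b)$waypoint,
                   c(FALSE, TRUE, FALSE))
})

test_that("slots that do not bracket a 12-h night window are rejected", {
  expect_error(tag_schedule("Bx", -5, c("0600", "1600")), "night window")
  expect_error(tag_schedule("Bx", -5, c("0600", "1000", "1600")),
               "night window")
  # 0000 sits inside the 1600->0400 night window, so this one is coherent
  expect_identical(tag_schedule("Bx", -5, c("0000", "0400", "1600"))$night_window,
                   c("1600", "0400"))
})

test_that("segments are phased by start slot with waypoint path distance", {
  sch3 <- tag_schedule("B2", -5, c("0000", "0600", "1800"), "texas")
  t <- utc(c("2018-03-12T11:00:00Z", "2018-03-12T23:00:00Z",
             "2018-03-13T05:00:00Z", "2018-03-13T11:00:00Z"))
  fx <- data.frame(bird_id = "B2", t = t, lat = c(9, 10, 10.5, 11),
                   lon = c(-75, -75, -74, -75),
                   slot = c("0600", "1800", "0000", "0600"))
  segs <- build_segments(normalize_schedule(fx, sch3), sch3)
  expect_equal(nrow(segs), 2)
  expect_identical(segs$phase, c("day", "night"))
  # night distance follows the dog-leg through the 0000 waypoint
  leg <- geodesic_km(10, -75, 10.5, -74) + geodesic_km(10.5, -74, 11, -75)
  expect_equal(segs$distance_km[2], leg, tolerance = 1e-9)
  expect_gt(leg, geodesic_km(10, -75, 11, -75))
})

test_that("gaps break the segment chain and are logged", {
  fx <- data.frame(bird_id = "B1",
                   t = utc(c("2018-03-12T23:00:00Z", "2018-03-14T11:00:00Z")),
                   lat = c(10, 12), lon = -75, slot = c("1800", "0600"))
  segs <- build_segments(normalize_schedule(fx, sched2()), sched2())
  expect_equal(nrow(segs), 0)
  expect_equal(nrow(attr(segs, "gaps")), 1)
  expect_equal(attr(segs, "gaps")$gap_h, 36)
})

test_that("a gap-free 2-slot track yields n-1 segments, max 2 per day", {
  n <- 9
  t <- utc("2018-03-12T11:00:00Z") + (0:(n - 1)) * 12 * 3600
  fx <- data.frame(bird_id = "B1", t = t, lat = seq(5, 13, length.out = n),
                   lon = -75, slot = rep(c("0600", "1800"), length.out = n))
  segs <- build_segments(normalize_schedule(fx, sched2()), sched2())
  expect_equal(nrow(segs), n - 1)
  per_day <- table(as.Date(segs$t_start, tz = "UTC"))
  expect_true(all(per_day <= 2))
  expect_identical(unique(segs$phase[segs$slot_start == "1800"]), "night")
})

test_that("migration trimming removes stationary termini only", {
  t0 <- utc("2018-03-01T11:00:00Z")
  # 4 stationary days (9 fixes within 5 km) then steady northward movement
  lat <- c(10 + runif(9, 0, 0.03), seq(10.5, 16, length.out = 10))
  fx <- data.frame(bird_id = "B1", t = t0 + (0:18) * 12 * 3600, lat = lat,
                   lon = -75, slot = "x")
  tr <- trim_migration(fx)
  expect_equal(nrow(tr), 10)
  expect_equal(tr$lat[1], lat[10])
  # a track that never pauses is untouched
  fx2 <- data.frame(bird_id = "B1", t = t0 + (0:9) * 12 * 3600,
                    lat = seq(5, 12, length.out = 10), lon = -75, slot = "x")
  expect_identical(trim_migration(fx2), fx2)
  # fully stationary track empties with a warning
  fx3 <- data.frame(bird_id = "B1", t = t0 + (0:9) * 12 * 3600,
                    lat = 10 + runif(10, 0, 0.02), lon = -75, slot = "x")
  expect_warning(tr3 <- trim_migration(fx3), "stationary")
  expect_equal(nrow(tr3), 0)
})

test_that("trimming never removes interior fixes", {
  t0 <- utc("2018-03-01T11:00:00Z")
  set.seed(2)
  # stationary head and tail around a moving middle with a mid-track pause
  lat <- c(rep(5, 8) + runif(8, 0, 0.01), seq(5.5, 11.5, length.out = 8),
           rep(11.8, 3) + runif(3, 0, 0.01), seq(12, 15, length.out = 5),
           rep(16, 8) + runif(8, 0, 0.01))
  fx <- data.frame(bird_id = "B1", t = t0 + seq_along(lat) * 12 * 3600,
                   lat = lat, lon = -75, slot = "x")
  tr <- trim_migration(fx)
  expect_equal(tr$lat, lat[9:24])   # mid-track pause retained
})
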