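test_that("world construction is deterministic with sane geometry", {
  w1 <- make_world(42)
  w2 <- make_world(42)
  expect_identical(w1$wind$U, w2$wind$U)
  expect_identical(w1$mask$water_polygons, w2$mask$water_polygons)
  # feasible crossing widths span the intended range
  widths <- c()
  for (nm in names(w1$mask$water_polygons)) {
    ring <- w1$mask$water_polygons[[nm]]
    for (lon in seq(min(ring[, "lon"]) + 0.5, max(ring[, "lon"]) - 0.5,
                    length.out = 10)) {
      g <- nightcross:::.crossing_geometry(
        w1$mask, c(lon, min(ring[, "lat"]) - 0.1), nm, 0)
      widths <- c(widths, g$width_km)
    }
  }
  expect_gt(min(widths), 90)
  expect_lt(max(widths), 1200)
  # wind field mean tracks the configured mean vector
  expect_lt(abs(mean(w1$wind$U) - w1$params$wind_mean[["u"]]), 0.5)
  expect_lt(abs(mean(w1$wind$V) - w1$params$wind_mean[["v"]]), 0.5)
})

test_that("track simulation is reproducible and physically bounded", {
  w <- make_world(42)
  s1 <- simulate_tracks(w, seed = 4)
  s2 <- simulate_tracks(w, seed = 4)
  expect_identical(s1$fixes, s2$fixes)
  expect_identical(s1$truth, s2$truth)
  # every fix inside the wind envelope
  expect_true(all(s1$fixes$lat >= min(w$wind$lats) &
                    s1$fixes$lat <= max(w$wind$lats)))
  expect_true(all(s1$fixes$lon >= min(w$wind$lons) &
                    s1$fixes$lon <= max(w$wind$lons)))
  # no bird outruns a plausible airspeed between consecutive fixes
  for (id in unique(s1$fixes$bird_id)) {
    f <- s1$fixes[s1$fixes$bird_id == id, ]
    n <- nrow(f)
    v <- geodesic_km(f$lat[-n], f$lon[-n], f$lat[-1], f$lon[-1]) /
      as.numeric(difftime(f$t[-1], f$t[-n], units = "hours"))
    expect_lt(max(v), 90)
  }
})

test_that("long crossings necessarily span a night interval", {
  w <- make_world(42)
  sim <- simulate_tracks(w, seed = 4)
  fx <- sim$fixes
  fx$slot <- NA_character_
  for (id in unique(fx$bird_id)) {
    sch <- sim$schedules[[id]]
    i <- which(fx$bird_id == id)
    lm <- nightcross:::.local_minutes(fx$t[i], sch$utc_offset)
    sm <- nightcross:::.slot_minutes(sch$daily_slots)
    d <- abs(outer(lm, sm, "-")); d <- pmin(d, 1440 - d)
    fx$slot[i] <- sch$daily_slots[apply(d, 1, which.min)]
  }
  segs <- classify_surface(build_all_segments(fx, sim$schedules), w$mask,
                           step_km = 2)
  for (id in unique(segs$bird_id)) {
    s <- segs[segs$bird_id == id, ]
    r <- rle(s$surface == "water")
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    for (k in which(r$values)) {
      span_h <- as.numeric(difftime(s$t_end[ends[k]], s$t_start[starts[k]],
                                    units = "hours"))
      if (span_h > 12)
        expect_true(any(s$phase[starts[k]:ends[k]] == "night"))
    }
  }
})

test_that("decision-level simulation follows the logistic law", {
  # a fair coin under zero coefficients and no bird heterogeneity
  dep <- simulate_departures(2000, c(0, 0, 0, 0), 0, 20, seed = 5)
  expect_lt(abs(mean(dep$decision == "cross") - 0.5), 3 * sqrt(0.25 / 2000))
  # a strongly negative intercept makes detours dominate
  dep2 <- simulate_departures(500, c(-4, 0, 0, 0), 0, 20, seed = 5)
  expect_lt(mean(dep2$decision == "cross"), 0.1)
  # determinism
  expect_identical(simulate_departures(50, seed = 9),
                   simulate_departures(50, seed = 9))
})

test_that("pipeline covariates match generator truth at departure points", {
  w <- make_world(42)
  sim <- simulate_tracks(w, seed = 1)
  cfg <- pipeline_config(destinations = lapply(sim$schedules, `[[`,
                                               "destination"),
                         optimal_dirs = w$optimal_dirs)
  fx <- sim$fixes
  fx$slot <- NA_character_
  for (id in unique(fx$bird_id)) {
    sch <- sim$schedules[[id]]
    i <- which(fx$bird_id == id)
    lm <- nightcross:::.local_minutes(fx$t[i], sch$utc_offset)
    sm <- nightcross:::.slot_minutes(sch$daily_slots)
    d <- abs(outer(lm, sm, "-")); d <- pmin(d, 1440 - d)
    fx$slot[i] <- sch$daily_slots[apply(d, 1, which.min)]
  }
  segs <- classify_surface(build_all_segments(fx, sim$schedules), w$mask,
                           step_km = 2)
  deps <- identify_departures(segs, w$mask, cfg)
  depcov <- departure_covariates(deps, fx, w$wind, w$mask)
  truth <- sim$truth
  n_checked_tw <- 0; n_checked_ratio <- 0
  for (i in seq_len(nrow(truth))) {
    j <- which(depcov$bird_id == truth$bird_id[i] &
                 abs(as.numeric(difftime(depcov$t, truth$t[i],
                                         units = "hours"))) < 1)
    if (!length(j)) next
    expect_lt(abs(depcov$tailwind_ms[j[1]] - truth$tailwind_ms[i]), 0.1)
    n_checked_tw <- n_checked_tw + 1
    if (truth$decision[i] == "cross") {
      expect_lt(abs(depcov$ratio[j[1]] - truth$ratio[i]), 0.05)
      n_checked_ratio <- n_checked_ratio + 1
    }
  }
  expect_gt(n_checked_tw, 10)
  expect_gt(n_checked_ratio, 5)
})

test_that("the pipeline recovers the generator's departures", {
  w <- make_world(42)
  cf <- departure_confusion(w, seed = 2)
  expect_gte(cf$recall, 0.95)
  expect_gt(cf$truth_n, 10)
})

test_that("the recovery harness scores bias, RMSE and coverage", {
  rep <- recovery_experiment(seeds = 1:3, n_departures = 150,
                             chains = 1, iter = 600)
  expect_equal(rep$n_ok, 3)
  expect_true(all(is.finite(rep$bias)))
  expect_true(all(rep$coverage >= 0 & rep$coverage <= 1))
  expect_output(print(rep), "Recovery over 3 replicates")
})
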