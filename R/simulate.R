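# Synthetic world: a self-contained geography (two water barriers between
# rectangular landmasses), a 2.5-degree / 6-hourly wind grid, and
# migratory tracks whose coastal cross/detour decisions follow a known
# logistic law. Everything the pipeline consumes can be generated here,
# so each stage is testable end-to-end with known truth.
#
# The world lives in real lon/lat coordinates (centred near 15 N, 75 W)
# so the geodesic and solar code paths run unmodified. The "sea" barrier
# narrows from ~1100 km in the east to ~150 km in the west, giving the
# spread of feasible crossing widths; the "gulf" further north spans
# ~500-900 km.

KM_PER_DEG_LAT <- 111.195  # 2 pi R / 360 at R = 6371.0088

#' Build the synthetic world
#'
#' Deterministic given `seed`: the land/water mask, a wind grid with a
#' configurable mean vector plus temporally autocorrelated noise, and the
#' reference covariate moments used to put the decision law on the
#' standardised scale.
#'
#' @param seed integer seed
#' @param sea_width_km crossing-width range (west, east) of the southern
#'   barrier, km
#' @param gulf_width_km crossing-width range of the northern barrier, km
#' @param wind_mean mean wind vector `c(u, v)`, m/s
#' @param wind_sd marginal SD of the wind noise, m/s
#' @param wind_ar1 lag-1 autocorrelation of the 6-hourly wind noise
#' @param start_date first simulation day
#' @param n_days days covered by the wind grid
#' @return a `synthetic_world` list: `mask`, `wind`, `optimal_dirs`,
#'   `ref` (covariate reference moments), `params`
#' @export
make_world <- function(seed = 42, sea_width_km = c(150, 1100),
                       gulf_width_km = c(500, 900),
                       wind_mean = c(u = -2, v = -1), wind_sd = 2,
                       wind_ar1 = 0.75,
                       start_date = as.Date("2018-03-01"), n_days = 60) {
  set.seed(seed)
  sea <- rbind(c(-88, 10), c(-62, 10),
               c(-62, 10 + sea_width_km[2] / KM_PER_DEG_LAT),
               c(-88, 10 + sea_width_km[1] / KM_PER_DEG_LAT))
  gulf <- rbind(c(-84, 22), c(-58, 22),
                c(-58, 22 + gulf_width_km[2] / KM_PER_DEG_LAT),
                c(-84, 22 + gulf_width_km[1] / KM_PER_DEG_LAT))
  colnames(sea) <- colnames(gulf) <- c("lon", "lat")
  mask <- land_water_mask(list(sea = sea, gulf = gulf))

  lats <- seq(0, 42.5, by = 2.5)
  lons <- seq(-95, -55, by = 2.5)
  t0 <- as.POSIXct(paste(start_date - 1, "00:00:00"), tz = "UTC")
  times <- seq(t0, by = 6 * 3600, length.out = (n_days + 2) * 4)
  nt <- length(times); na <- length(lats); no <- length(lons)
  gen_component <- function(mu) {
    eps <- array(0, c(nt, na, no))
    eps[1, , ] <- stats::rnorm(na * no, 0, wind_sd)
    innov_sd <- wind_sd * sqrt(1 - wind_ar1^2)
    for (k in 2:nt)
      eps[k, , ] <- wind_ar1 * eps[k - 1, , ] + stats::rnorm(na * no, 0, innov_sd)
    mu + eps
  }
  wind <- wind_grid(lats, lons, times,
                    U = gen_component(wind_mean[["u"]]),
                    V = gen_component(wind_mean[["v"]]))

  optimal_dirs <- list(sea = 0, gulf = 0)  # both barriers crossed northward

  # reference covariate moments: tailwind from the wind parameters, ratio
  # from crossing/circumnavigation geometry sampled along both coasts
  ratios <- c()
  for (nm in names(mask$water_polygons)) {
    ring <- mask$water_polygons[[nm]]
    south <- min(ring[, "lat"])
    for (lon in seq(min(ring[, "lon"]) + 1, max(ring[, "lon"]) - 1,
                    length.out = 12)) {
      p0 <- c(lon, south - 0.1)
      cr <- .crossing_geometry(mask, p0, nm, 0)
      circ <- tryCatch(circumnavigation_distance(p0, cr$landing, mask),
                       error = function(e) NA)
      if (is.finite(circ)) ratios <- c(ratios, cr$km / circ)
    }
  }
  ref <- list(tailwind = c(mean = tailwind(wind_mean[["u"]], wind_mean[["v"]], 0),
                           sd = wind_sd),
              ratio = c(mean = mean(ratios), sd = stats::sd(ratios)))
  structure(list(mask = mask, wind = wind, optimal_dirs = optimal_dirs,
                 ref = ref,
                 params = list(seed = seed, sea_width_km = sea_width_km,
                               gulf_width_km = gulf_width_km,
                               wind_mean = wind_mean, wind_sd = wind_sd,
                               wind_ar1 = wind_ar1, start_date = start_date,
                               n_days = n_days)),
            class = "synthetic_world")
}

# crossing geometry from a coastal point along bearing od: width of the
# named waterbody on the ray, the landing point `overshoot_km` beyond the
# far coast, and the full crossing distance
.crossing_geometry <- function(mask, p0, waterbody, od, overshoot_km = 30,
                               step_km = 2, max_range_km = 1400) {
  d <- seq(step_km / 2, max_range_km, by = step_km)
  pts <- destination_point(p0[2], p0[1], od, d)
  wb <- water_polygon_at(mask, pts[, "lon"], pts[, "lat"])
  in_w <- which(wb == waterbody)
  if (!length(in_w)) .stopf("ray from (%.2f, %.2f) misses %s", p0[1], p0[2],
                            waterbody)
  exit_d <- d[max(in_w)] + step_km / 2
  landing <- drop(destination_point(p0[2], p0[1], od, exit_d + overshoot_km))
  list(width_km = length(in_w) * step_km,
       km = geodesic_km(p0[2], p0[1], landing["lat"], landing["lon"]),
       landing = c(landing[["lon"]], landing[["lat"]]))
}

#' Default tag schedules for the synthetic cohort
#'
#' Mirrors the field deployment mix: most tags on the 0600/1800 CDT
#' 2-slot programme, two on 0400/1600 EDT, and one of each 3-slot
#' programme. Destinations are mostly `texas`, with `florida` and
#' `manitoba` represented.
#'
#' @param n_birds number of birds
#' @return named list of [tag_schedule()] objects
#' @export
default_schedules <- function(n_birds = 11) {
  ids <- sprintf("B%02d", seq_len(n_birds))
  dests <- rep(c("texas", "florida", "manitoba"), c(8, 2, 1))
  dests <- rep_len(dests, n_birds)
  out <- lapply(seq_len(n_birds), function(i) {
    if (n_birds >= 11 && i == 10)
      tag_schedule(ids[i], -5, c("0000", "0600", "1800"), dests[i])
    else if (n_birds >= 11 && i == 11)
      tag_schedule(ids[i], -5, c("0400", "1000", "1600"), dests[i])
    else if (i %% 5 == 4)
      tag_schedule(ids[i], -4, c("0400", "1600"), dests[i])
    else
      tag_schedule(ids[i], -5, c("0600", "1800"), dests[i])
  })
  names(out) <- ids
  out
}

.slot_times_utc <- function(schedule, start_date, n_days) {
  days <- start_date + seq_len(n_days + 1) - 1
  sm <- .slot_minutes(schedule$daily_slots)
  t <- as.POSIXct(outer(as.numeric(as.POSIXct(paste(days, "00:00:00"),
                                              tz = "UTC")),
                        (sm - schedule$utc_offset * 60) * 60, "+"),
                  origin = "1970-01-01", tz = "UTC")
  sort(t)
}

# is the 12-h (or partial) interval starting at this slot a night interval?
.night_slot <- function(slot, schedule) {
  slot %in% c(schedule$night_window[1],
              intersect(schedule$daily_slots, "0000"))
}

#' Simulate migratory tracks with known crossing decisions
#'
#' Each bird starts on the southern landmass and migrates north toward its
#' destination on fixed fix schedules. Over land it flies at day/night
#' speeds drawn from configurable distributions; at each coastal encounter
#' the cross/detour outcome is drawn from the logistic law
#' `logit p = b0 + b1 tailwind_s + b2 ratio_s + b3 night + u_bird`, with
#' covariates standardised against the world's reference moments.
#' Crossing birds traverse the water at a per-crossing speed (day and
#' night alike) and land just beyond the far coast; detouring birds turn
#' 90 degrees and coast around the barrier. Every decision is recorded
#' with its true covariates.
#'
#' @param world a [make_world()] object
#' @param n_birds number of birds (default 11)
#' @param true_beta decision-law coefficients
#'   `(intercept, tailwind, ratio, night)` on the standardised scale
#' @param sigma_bird SD of the per-bird random intercept
#' @param seed integer seed
#' @param schedules named list of [tag_schedule()] (default
#'   [default_schedules()])
#' @param land_day_kmh,land_night_kmh mean and SD of over-land speeds
#' @param water_kmh_range per-crossing water speed range, km/h
#' @param heading_sd_deg per-interval heading noise, degrees
#' @return list with `fixes` (bird_id, t, lat, lon), `truth` (one row per
#'   decision: time, location, waterbody, decision, raw covariates,
#'   night), `schedules`, `u` (the bird intercepts) and the generating
#'   parameters
#' @export
simulate_tracks <- function(world, n_birds = 11, true_beta = c(2, 1, -2, -1),
                            sigma_bird = 0.5, seed = 1,
                            schedules = default_schedules(n_birds),
                            land_day_kmh = c(20, 2), land_night_kmh = c(4, 1),
                            water_kmh_range = c(25, 70),
                            heading_sd_deg = 8) {
  set.seed(seed)
  mask <- world$mask; wind <- world$wind
  start_date <- world$params$start_date
  n_days <- world$params$n_days - 10
  ids <- names(schedules)
  dests <- list(texas = c(-80, 38), florida = c(-62, 36), manitoba = c(-72, 40))
  u <- stats::rnorm(length(ids), 0, sigma_bird)
  names(u) <- ids
  fixes <- list(); truth <- list()

  for (bi in seq_along(ids)) {
    id <- ids[bi]; sch <- schedules[[id]]
    dest <- dests[[sch$destination]]
    pos <- c(stats::runif(1, -86, -64), stats::runif(1, 2, 6))
    t_start_offset <- sample(0:8, 1)
    slots <- .slot_times_utc(sch, start_date + t_start_offset, n_days)
    mode <- "travel"; cross_info <- NULL; detour_info <- NULL
    pending <- NULL    # waterbody met at the end of the previous interval
    rest <- -1L        # intervals still to rest at the coast before deciding
    arrived <- FALSE
    fixes[[length(fixes) + 1]] <- data.frame(
      bird_id = id, t = slots[1], lat = pos[2], lon = pos[1])
    for (si in seq_len(length(slots) - 1)) {
      if (arrived) break
      t0 <- slots[si]; t1 <- slots[si + 1]
      h <- as.numeric(difftime(t1, t0, units = "hours"))
      lm0 <- .local_minutes(t0, sch$utc_offset)
      slot0 <- sch$daily_slots[which.min(pmin(abs(.slot_minutes(sch$daily_slots) - lm0),
                                              1440 - abs(.slot_minutes(sch$daily_slots) - lm0)))]
      night <- .night_slot(slot0, sch)

      if (!is.null(pending)) {
        # birds may rest at the coast for 0-2 intervals before deciding,
        # so crossings start on a mix of day and night intervals
        if (rest < 0L) rest <- sample(0:2, 1)
        if (rest > 0L) {
          rest <- rest - 1L
          fixes[[length(fixes) + 1]] <- data.frame(
            bird_id = id, t = t1, lat = pos[2], lon = pos[1])
          next
        }
        rest <- -1L
      }
      if (!is.null(pending)) {
        # decision at this fix, for the interval that starts now; corner
        # grazes (barrier does not really block the optimal direction)
        # are skirted without a recorded decision
        wb <- pending; od <- world$optimal_dirs[[wb]]
        geomx <- tryCatch(.crossing_geometry(mask, pos, wb, od),
                          error = function(e) NULL)
        if (is.null(geomx) || geomx$width_km < 100) {
          ring <- mask$water_polygons[[wb]]
          west <- pos[1] - min(ring[, "lon"]) < max(ring[, "lon"]) - pos[1]
          mode <- "detour"
          detour_info <- list(bearing = if (west) 270 else 90,
                              clear_lon = if (west) min(ring[, "lon"]) - 0.4
                                          else max(ring[, "lon"]) + 0.4,
                              west = west, waterbody = wb)
          pending <- NULL
        }
      }
      if (!is.null(pending)) {
        wb <- pending; od <- world$optimal_dirs[[wb]]
        uv <- interp_uv(wind, pos[2], pos[1], t0)
        tw <- tailwind(uv[["u"]], uv[["v"]], od)
        circ <- circumnavigation_distance(pos, geomx$landing, mask)
        ratio <- geomx$km / circ
        z_tw <- (tw - world$ref$tailwind[["mean"]]) / world$ref$tailwind[["sd"]]
        z_ra <- (ratio - world$ref$ratio[["mean"]]) / world$ref$ratio[["sd"]]
        p <- stats::plogis(true_beta[1] + true_beta[2] * z_tw +
                           true_beta[3] * z_ra + true_beta[4] * night + u[id])
        cross <- stats::rbinom(1, 1, p) == 1
        truth[[length(truth) + 1]] <- data.frame(
          bird_id = id, t = t0, lat = pos[2], lon = pos[1], waterbody = wb,
          decision = if (cross) "cross" else "detour",
          tailwind_ms = tw, ratio = ratio, cross_km = geomx$km,
          circ_km = circ, night = night, p_cross = p,
          stringsAsFactors = FALSE)
        if (cross) {
          mode <- "cross"
          cross_info <- list(landing = geomx$landing,
                             speed = stats::runif(1, water_kmh_range[1],
                                                  water_kmh_range[2]))
        } else {
          ring <- mask$water_polygons[[wb]]
          west <- pos[1] - min(ring[, "lon"]) < max(ring[, "lon"]) - pos[1]
          mode <- "detour"
          detour_info <- list(bearing = if (west) 270 else 90,
                              clear_lon = if (west) min(ring[, "lon"]) - 0.4
                                          else max(ring[, "lon"]) + 0.4,
                              west = west, waterbody = wb)
        }
        pending <- NULL
      }

      if (mode == "cross") {
        budget <- cross_info$speed * h
        remaining <- geodesic_km(pos[2], pos[1],
                                 cross_info$landing[2], cross_info$landing[1])
        if (budget >= remaining) {
          pos <- cross_info$landing
          mode <- "travel"
        } else {
          b <- initial_bearing(pos[2], pos[1],
                               cross_info$landing[2], cross_info$landing[1])
          pos <- drop(destination_point(pos[2], pos[1], b, budget))[c("lon", "lat")]
          pos <- unname(pos)
        }
      } else if (mode == "detour") {
        sp <- if (night) land_night_kmh else land_day_kmh
        budget <- max(0.5, stats::rnorm(1, sp[1], sp[2])) * h
        while (budget > 0) {
          step <- min(10, budget); budget <- budget - step
          nxt <- drop(destination_point(pos[2], pos[1], detour_info$bearing, step))
          if (is_water(mask, nxt[["lon"]], nxt[["lat"]])) break
          pos <- unname(nxt[c("lon", "lat")])
          cleared <- if (detour_info$west) pos[1] < detour_info$clear_lon
                     else pos[1] > detour_info$clear_lon
          if (cleared) { mode <- "travel"; break }
        }
      } else {
        sp <- if (night) land_night_kmh else land_day_kmh
        budget <- max(0.5, stats::rnorm(1, sp[1], sp[2])) * h
        heading_noise <- stats::rnorm(1, 0, heading_sd_deg)
        while (budget > 0) {
          to_dest <- geodesic_km(pos[2], pos[1], dest[2], dest[1])
          if (to_dest < 60) { arrived <- TRUE; break }
          step <- min(10, budget, to_dest); budget <- budget - step
          b <- (initial_bearing(pos[2], pos[1], dest[2], dest[1]) +
                  heading_noise) %% 360
          nxt <- drop(destination_point(pos[2], pos[1], b, step))
          wb <- water_polygon_at(mask, nxt[["lon"]], nxt[["lat"]])
          if (!is.na(wb)) { pending <- wb; break }
          pos <- unname(nxt[c("lon", "lat")])
        }
      }
      fixes[[length(fixes) + 1]] <- data.frame(
        bird_id = id, t = t1, lat = pos[2], lon = pos[1])
      if (arrived) break
    }
  }
  fixes <- do.call(rbind, fixes)
  fixes <- fixes[order(fixes$bird_id, fixes$t), , drop = FALSE]
  rownames(fixes) <- NULL
  truth <- if (length(truth)) do.call(rbind, truth) else NULL
  list(fixes = fixes, truth = truth, schedules = schedules, u = u,
       params = list(true_beta = true_beta, sigma_bird = sigma_bird,
                     seed = seed))
}

#' Simulate decision-level departures from the crossing law
#'
#' Draws `n` coastal decisions directly (no track geometry): tailwind and
#' ratio covariates from their field-scale distributions, standardised
#' against the realised sample exactly as the fitting routine will, then
#' outcomes from the logistic law with per-bird random intercepts. Used
#' for parameter-recovery and coverage experiments.
#'
#' @param n number of departures
#' @param true_beta coefficients `(intercept, tailwind, ratio, night)` on
#'   the standardised scale
#' @param sigma_bird random-intercept SD
#' @param n_birds number of birds decisions are spread over
#' @param seed optional integer seed
#' @return data frame ready for [fit_crossing_model()]; attribute
#'   `"truth"` records the generating parameters and intercepts
#' @export
simulate_departures <- function(n = 200, true_beta = c(2, 1, -2, -1),
                                sigma_bird = 0.5, n_birds = 20, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  bird <- sample.int(n_birds, n, replace = TRUE)
  u <- stats::rnorm(n_birds, 0, sigma_bird)
  tailwind_ms <- stats::rnorm(n, -1, 2.5)
  ratio <- stats::runif(n, 0.35, 1.15)
  night <- stats::rbinom(n, 1, 0.4) == 1
  eta <- true_beta[1] + true_beta[2] * as.numeric(scale_center(tailwind_ms)) +
    true_beta[3] * as.numeric(scale_center(ratio)) +
    true_beta[4] * as.numeric(night) + u[bird]
  y <- stats::rbinom(n, 1, stats::plogis(eta))
  out <- data.frame(bird_id = sprintf("S%02d", bird),
                    tailwind_ms = tailwind_ms, ratio = ratio, night = night,
                    decision = ifelse(y == 1, "cross", "detour"),
                    stringsAsFactors = FALSE)
  attr(out, "truth") <- list(beta = true_beta, sigma_bird = sigma_bird, u = u)
  out
}

#' Parameter-recovery experiment for the crossing model
#'
#' For each seed, simulates departures from the known law, fits the model,
#' and scores the posterior against truth: per-coefficient bias, RMSE and
#' 95%-interval coverage. Optionally also runs the full track pipeline
#' (segments, surfaces, departures) per seed and reports the
#' departure-identification confusion counts against generator truth.
#'
#' @param seeds integer seeds, one replicate each
#' @param n_departures departures per replicate
#' @param true_beta,sigma_bird generating parameters
#' @param n_birds birds per replicate
#' @param chains,iter MCMC size per fit (reduced relative to the
#'   analysis defaults; adequate for interval coverage at this n)
#' @param track_recall also run the track-level pipeline per seed
#' @param world synthetic world for the track stage (built once if `NULL`
#'   and `track_recall` is set)
#' @return a `recovery_report` list: `estimates` (per seed x coefficient),
#'   `bias`, `rmse`, `coverage`, `failed` (seed and stage of any failure),
#'   and `confusion` when `track_recall` is set
#' @export
recovery_experiment <- function(seeds, n_departures = 200,
                                true_beta = c(2, 1, -2, -1), sigma_bird = 0.5,
                                n_birds = 20, chains = 2, iter = 800,
                                track_recall = FALSE, world = NULL) {
  est <- cover <- matrix(NA_real_, length(seeds), 4,
                         dimnames = list(NULL, FIXED_EFFECT_NAMES))
  failed <- list(); confusion <- NULL
  if (track_recall && is.null(world)) world <- make_world()
  if (track_recall)
    confusion <- data.frame(seed = seeds, truth_n = NA_real_, matched = NA_real_,
                            extra = NA_real_, recall = NA_real_)
  for (k in seq_along(seeds)) {
    res <- tryCatch({
      dep <- simulate_departures(n_departures, true_beta, sigma_bird, n_birds,
                                 seed = seeds[k])
      fit <- fit_crossing_model(dep, chains = chains, iter = iter,
                                seed = seeds[k] + 1)
      s <- fit$summary[FIXED_EFFECT_NAMES, , drop = FALSE]
      list(est = s[, "Estimate"],
           cover = as.numeric(s[, "l-95% CI"] <= true_beta &
                                true_beta <= s[, "u-95% CI"]))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed[[length(failed) + 1]] <- data.frame(seed = seeds[k],
                                                 stage = "model_fit",
                                                 message = conditionMessage(res))
      next
    }
    est[k, ] <- res$est; cover[k, ] <- res$cover
    if (track_recall) {
      tr <- tryCatch(
        departure_confusion(world, seed = seeds[k], true_beta = true_beta,
                            sigma_bird = sigma_bird),
        error = function(e) e)
      if (inherits(tr, "error")) {
        failed[[length(failed) + 1]] <- data.frame(seed = seeds[k],
                                                   stage = "track_pipeline",
                                                   message = conditionMessage(tr))
      } else {
        confusion[k, c("truth_n", "matched", "extra", "recall")] <-
          c(tr$truth_n, tr$matched, tr$extra, tr$recall)
      }
    }
  }
  ok <- stats::complete.cases(est)
  structure(list(
    seeds = seeds, true_beta = true_beta,
    estimates = est,
    bias = colMeans(est[ok, , drop = FALSE]) - true_beta,
    rmse = sqrt(colMeans((est[ok, , drop = FALSE] -
                            matrix(true_beta, sum(ok), 4, byrow = TRUE))^2)),
    coverage = colMeans(cover[ok, , drop = FALSE]),
    n_ok = sum(ok),
    failed = if (length(failed)) do.call(rbind, failed) else NULL,
    confusion = confusion), class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("Recovery over %d replicates (n ok = %d)\n",
              length(x$seeds), x$n_ok))
  print(round(rbind(truth = x$true_beta, bias = x$bias, rmse = x$rmse,
                    coverage = x$coverage), 3))
  if (!is.null(x$confusion))
    cat(sprintf("Departure recall: mean %.3f\n",
                mean(x$confusion$recall, na.rm = TRUE)))
  invisible(x)
}

#' Departure identification confusion against generator truth
#'
#' Simulates tracks in the world, runs the segment/surface/departure
#' stages, and matches recovered departures to the generator's decisions
#' (same bird, time within 12 h, same decision).
#'
#' @param world a [make_world()] object
#' @param seed track-simulation seed
#' @param ... passed to [simulate_tracks()]
#' @return list with `truth_n`, `matched`, `extra` (recovered departures
#'   matching no truth decision) and `recall`
#' @export
departure_confusion <- function(world, seed = 1, ...) {
  sim <- simulate_tracks(world, seed = seed, ...)
  cfg <- pipeline_config(
    destinations = lapply(sim$schedules, `[[`, "destination"),
    optimal_dirs = world$optimal_dirs)
  # assign slots the same way read_fixes would
  fx <- sim$fixes
  fx$slot <- NA_character_
  for (id in unique(fx$bird_id)) {
    sch <- sim$schedules[[id]]
    i <- which(fx$bird_id == id)
    lm <- .local_minutes(fx$t[i], sch$utc_offset)
    sm <- .slot_minutes(sch$daily_slots)
    d <- abs(outer(lm, sm, "-")); d <- pmin(d, 1440 - d)
    fx$slot[i] <- sch$daily_slots[apply(d, 1, which.min)]
  }
  segs <- build_all_segments(fx, sim$schedules)
  segs <- classify_surface(segs, world$mask, step_km = 2)
  deps <- identify_departures(segs, world$mask, cfg)
  truth <- sim$truth
  if (is.null(truth) || nrow(truth) == 0)
    return(list(truth_n = 0, matched = 0, extra = nrow(deps), recall = NA_real_))
  matched <- 0
  used <- rep(FALSE, nrow(deps))
  for (i in seq_len(nrow(truth))) {
    j <- which(!used & deps$bird_id == truth$bird_id[i] &
                 deps$decision == truth$decision[i] &
                 abs(as.numeric(difftime(deps$t, truth$t[i], units = "hours"))) <= 12)
    if (length(j)) { matched <- matched + 1; used[j[1]] <- TRUE }
  }
  list(truth_n = nrow(truth), matched = matched, extra = sum(!used),
       recall = matched / nrow(truth))
}
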