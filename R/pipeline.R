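# End-to-end orchestration: validated inputs in, plain-CSV artifacts out,
# with a manifest recording the configuration, seed and row counts at
# every stage so any stage can be diffed and re-entered.

#' Pipeline configuration
#'
#' @param fixes,schedules,mask,wind,out_dir input paths and output
#'   directory
#' @param surface_majority water-fraction threshold for water segments
#' @param coastal_buffer_km,min_block_km,detour_angle_deg detour-detection
#'   thresholds (see [identify_departures()])
#' @param stationary_radius_km,stationary_days migration trimming
#'   thresholds (see [trim_migration()])
#' @param step_km great-circle sampling step for surface classification
#' @param slot_tol_min slot-matching tolerance, minutes
#' @param chains,iter,seed model settings
#' @param destinations named list/vector, destination per bird id
#'   (defaults to the `destination` field of the schedules)
#' @param optimal_dirs optional waterbody -> bearing map overriding
#'   [assign_optimal_direction()]
#' @return a `pipeline_config` list
#' @export
pipeline_config <- function(fixes = NULL, schedules = NULL, mask = NULL,
                            wind = NULL, out_dir = NULL,
                            surface_majority = 0.5, coastal_buffer_km = 50,
                            min_block_km = 100, detour_angle_deg = 60,
                            stationary_radius_km = 30, stationary_days = 3,
                            step_km = 1, slot_tol_min = 30,
                            chains = 4, iter = 2000, seed = 42,
                            destinations = NULL, optimal_dirs = NULL) {
  thr <- c(surface_majority = surface_majority,
           coastal_buffer_km = coastal_buffer_km, min_block_km = min_block_km,
           detour_angle_deg = detour_angle_deg,
           stationary_radius_km = stationary_radius_km,
           stationary_days = stationary_days, step_km = step_km,
           slot_tol_min = slot_tol_min, chains = chains, iter = iter)
  if (any(thr <= 0)) .stopf("all thresholds must be positive (%s)",
                            paste(names(thr)[thr <= 0], collapse = ", "))
  structure(list(paths = list(fixes = fixes, schedules = schedules,
                              mask = mask, wind = wind, out_dir = out_dir),
                 surface_majority = surface_majority,
                 coastal_buffer_km = coastal_buffer_km,
                 min_block_km = min_block_km,
                 detour_angle_deg = detour_angle_deg,
                 stationary_radius_km = stationary_radius_km,
                 stationary_days = stationary_days, step_km = step_km,
                 slot_tol_min = slot_tol_min, chains = chains, iter = iter,
                 seed = seed, destinations = destinations,
                 optimal_dirs = optimal_dirs),
            class = "pipeline_config")
}

#' Validate pipeline input files
#'
#' Schema checks for every input, report-only: per file a pass/fail with
#' the first offending record.
#'
#' @param config a [pipeline_config()]
#' @return data frame with columns `file`, `path`, `ok`, `detail`
#' @export
validate_inputs <- function(config) {
  check <- function(fun) {
    tryCatch({ fun(); c(TRUE, "") },
             error = function(e) c(FALSE, conditionMessage(e)),
             warning = function(w) c(TRUE, conditionMessage(w)))
  }
  p <- config$paths
  rows <- list()
  rows$schedules <- check(function() read_schedules(p$schedules))
  rows$fixes <- check(function() {
    sch <- suppressWarnings(read_schedules(p$schedules))
    suppressWarnings(read_fixes(p$fixes, sch, config$slot_tol_min))
  })
  rows$mask <- check(function() read_mask_geojson(p$mask))
  rows$wind <- check(function() read_wind_csv(p$wind))
  data.frame(file = names(rows),
             path = unlist(p[names(rows)]),
             ok = vapply(rows, function(r) r[1] == "TRUE", logical(1)),
             detail = vapply(rows, `[`, "", 2),
             row.names = NULL)
}

.write_stage_csv <- function(df, out_dir, name) {
  for (cn in names(df))
    if (inherits(df[[cn]], "POSIXct")) df[[cn]] <- .format_utc(df[[cn]])
  utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
}

#' Run the full analysis pipeline
#'
#' Reads fixes, schedules, mask and wind; trims to the migratory period;
#' builds and classifies 12-h segments with daylight; summarises per-bird
#' movement; identifies departures and their covariates; fits the
#' crossing model and the daylight regressions; and writes every stage as
#' CSV plus a JSON manifest. Re-running with the same config and seed
#' produces byte-identical outputs.
#'
#' @param config a [pipeline_config()] with all paths set
#' @return (invisibly) a list with the in-memory stage results
#' @export
run_pipeline <- function(config) {
  out_dir <- config$paths$out_dir
  if (is.null(out_dir)) .stopf("config must set out_dir")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  manifest <- list(seed = config$seed,
                   package_version = as.character(utils::packageVersion("nightcross")),
                   thresholds = config[c("surface_majority", "coastal_buffer_km",
                                         "min_block_km", "detour_angle_deg",
                                         "stationary_radius_km", "stationary_days",
                                         "step_km", "slot_tol_min")],
                   counts = list(), log = character())
  stage <- "init"
  note <- function(...) manifest$log <<- c(manifest$log, sprintf(...))
  res <- tryCatch({
    stage <- "read_inputs"
    schedules <- read_schedules(config$paths$schedules)
    fixes <- read_fixes(config$paths$fixes, schedules, config$slot_tol_min)
    mask <- read_mask_geojson(config$paths$mask)
    wind <- read_wind_csv(config$paths$wind)
    manifest$counts$fixes_in <- nrow(fixes)

    stage <- "trim_migration"
    trimmed <- do.call(rbind, lapply(unique(fixes$bird_id), function(id)
      trim_migration(fixes[fixes$bird_id == id, , drop = FALSE],
                     config$stationary_radius_km, config$stationary_days)))
    note("trim_migration: %d fixes in, %d retained, %d removed",
         nrow(fixes), nrow(trimmed), nrow(fixes) - nrow(trimmed))
    manifest$counts$fixes_retained <- nrow(trimmed)

    stage <- "segments"
    segments <- build_all_segments(trimmed, schedules)
    gaps <- attr(segments, "gaps")
    note("segments: %d built, %d schedule gaps", nrow(segments),
         if (is.null(gaps)) 0L else nrow(gaps))
    segments <- add_daylight(segments)
    stage <- "classify_surface"
    segments <- classify_surface(segments, mask, step_km = config$step_km,
                                 majority = config$surface_majority)
    manifest$counts$segments <- nrow(segments)
    manifest$counts$water_segments <- sum(segments$surface == "water")

    stage <- "summaries"
    tables <- summary_tables(segments)

    stage <- "departures"
    cfg <- config
    if (is.null(cfg$destinations))
      cfg$destinations <- lapply(schedules, `[[`, "destination")
    deps <- identify_departures(segments, mask, cfg)
    depcov <- departure_covariates(deps, trimmed, wind, mask)
    for (ex in attr(depcov, "exclusions")) note("exclusion: %s", ex)
    note("departures: %d found, %d with covariates, %d excluded",
         nrow(deps), nrow(depcov), nrow(deps) - nrow(depcov))
    manifest$counts$departures_found <- nrow(deps)
    manifest$counts$departures_modeled <- nrow(depcov)

    stage <- "crossing_model"
    fit <- fit_crossing_model(depcov, chains = config$chains,
                              iter = config$iter, seed = config$seed)
    r2 <- bayes_r2(fit)

    stage <- "daylight_regression"
    dl <- lapply(c("day", "night"), function(ph)
      tryCatch(fit_daylight_regression(segments, ph), error = function(e) NULL))
    names(dl) <- c("day", "night")

    stage <- "wind_summaries"
    uv <- t(vapply(seq_len(nrow(depcov)), function(i)
      interp_uv(wind, depcov$lat[i], depcov$lon[i], depcov$t[i]), numeric(2)))
    ws <- speed_dir(uv[, 1], uv[, 2])
    rose <- windrose_table(ws)
    bearings <- c()
    for (i in seq_len(nrow(depcov))) {
      nxt <- segments[segments$bird_id == depcov$bird_id[i] &
                        segments$t_start == depcov$t[i] &
                        segments$distance_km > 1, , drop = FALSE]
      if (nrow(nxt))
        bearings <- c(bearings, initial_bearing(nxt$lat_start[1], nxt$lon_start[1],
                                                nxt$lat_end[1], nxt$lon_end[1]))
    }
    bh <- bearing_histogram(bearings)

    stage <- "write_artifacts"
    .write_stage_csv(segments, out_dir, "segments.csv")
    .write_stage_csv(tables$flights, out_dir, "summary_flights.csv")
    .write_stage_csv(tables$distance, out_dir, "summary_distance.csv")
    .write_stage_csv(tables$speed, out_dir, "summary_speed.csv")
    .write_stage_csv(depcov, out_dir, "departures.csv")
    ms <- data.frame(Covariate = rownames(fit$summary), fit$summary,
                     check.names = FALSE, row.names = NULL)
    .write_stage_csv(ms, out_dir, "model_summary.csv")
    .write_stage_csv(data.frame(mean = r2[["mean"]], est_error = r2[["sd"]],
                                l95 = r2[["l95"]], u95 = r2[["u95"]]),
                     out_dir, "bayes_r2.csv")
    dlrows <- do.call(rbind, lapply(names(dl), function(ph) {
      f <- dl[[ph]]
      if (is.null(f)) return(NULL)
      data.frame(phase = ph, slope = f$slope, l95 = f$slope_ci[1],
                 u95 = f$slope_ci[2], intercept = f$intercept,
                 n_segments = f$n_segments)
    }))
    .write_stage_csv(dlrows %||%
                       data.frame(phase = character(), slope = numeric()),
                     out_dir, "daylight_regression.csv")
    rose_df <- data.frame(sector_deg = rep(rownames(rose), ncol(rose)),
                          speed_class = rep(colnames(rose), each = nrow(rose)),
                          count = as.vector(rose))
    .write_stage_csv(rose_df, out_dir, "windrose.csv")
    .write_stage_csv(data.frame(sector_deg = names(bh), count = as.integer(bh)),
                     out_dir, "bearings.csv")
    list(segments = segments, tables = tables, departures = depcov,
         fit = fit, bayes_r2 = r2, daylight = dl, windrose = rose,
         bearings = bh)
  }, error = function(e) e)
  if (inherits(res, "error")) {
    manifest$failed_stage <- stage
    manifest$error <- conditionMessage(res)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    .stopf("pipeline failed at stage '%s': %s", stage, conditionMessage(res))
  }
  cfg_json <- jsonlite::toJSON(config[setdiff(names(config), "paths")],
                               auto_unbox = TRUE, digits = NA)
  tf <- tempfile(); writeLines(cfg_json, tf)
  manifest$config_hash <- unname(tools::md5sum(tf)); unlink(tf)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(res)
}

#' Write a complete synthetic fixture set
#'
#' Materialises a synthetic world and simulated tracks in exactly the
#' file formats the pipeline consumes: `fixes.csv`, `schedules.json`,
#' `mask.geojson`, `wind.csv`, plus `truth_departures.csv`.
#'
#' @param out_dir output directory
#' @param seed integer seed (drives world and tracks)
#' @param n_birds number of birds
#' @param ... passed to [simulate_tracks()]
#' @return (invisibly) the simulation object
#' @export
write_fixture_set <- function(out_dir, seed = 42, n_birds = 11, ...) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  world <- make_world(seed)
  sim <- simulate_tracks(world, n_birds = n_birds, seed = seed + 1, ...)
  fx <- sim$fixes
  utils::write.csv(data.frame(bird_id = fx$bird_id,
                              timestamp = .format_utc(fx$t),
                              lat = fx$lat, lon = fx$lon),
                   file.path(out_dir, "fixes.csv"), row.names = FALSE)
  write_schedules(sim$schedules, file.path(out_dir, "schedules.json"))
  write_mask_geojson(world$mask, file.path(out_dir, "mask.geojson"))
  write_wind_csv(world$wind, file.path(out_dir, "wind.csv"))
  .write_stage_csv(sim$truth, out_dir, "truth_departures.csv")
  invisible(list(world = world, sim = sim))
}
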