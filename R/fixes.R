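# Reading and trimming GPS fixes.

#' Read GPS fixes from CSV
#'
#' Expects header columns `bird_id`, `timestamp` (ISO-8601 UTC), `lat`,
#' `lon`. Each fix is assigned the scheduled slot whose local time is
#' nearest the fix's local time; fixes more than `slot_tol_min` minutes
#' from any slot keep slot `"adhoc"` with a warning.
#'
#' @param path CSV path
#' @param schedules named list of [tag_schedule()] objects covering every
#'   bird id present
#' @param slot_tol_min slot-matching tolerance, minutes
#' @return data frame with columns `bird_id`, `t` (POSIXct UTC), `lat`,
#'   `lon`, `slot`, sorted by `(bird_id, t)`
#' @export
read_fixes <- function(path, schedules, slot_tol_min = 30) {
  if (!file.exists(path)) .stopf("fix file not found: %s", path)
  df <- utils::read.csv(path, colClasses = "character", strip.white = TRUE)
  need <- c("bird_id", "timestamp", "lat", "lon")
  if (!all(need %in% names(df)))
    .stopf("fix CSV must have columns %s", paste(need, collapse = ", "))
  if (nrow(df) == 0)
    return(data.frame(bird_id = character(), t = .parse_utc(character()),
                      lat = numeric(), lon = numeric(), slot = character()))
  lat <- suppressWarnings(as.numeric(df$lat))
  lon <- suppressWarnings(as.numeric(df$lon))
  t <- suppressWarnings(.parse_utc(df$timestamp))
  bad <- which(is.na(lat) | is.na(lon) | is.na(t) | df$bird_id == "" |
                 lat < -90 | lat > 90 | lon < -180 | lon > 180)
  if (length(bad))
    .stopf("malformed fix row at line %d of %s", bad[1] + 1L, path)
  unknown <- setdiff(unique(df$bird_id), names(schedules))
  if (length(unknown))
    .stopf("no schedule for bird id(s): %s", paste(unknown, collapse = ", "))
  out <- data.frame(bird_id = df$bird_id, t = t, lat = lat, lon = lon,
                    slot = "adhoc", stringsAsFactors = FALSE)
  out <- out[order(out$bird_id, out$t), , drop = FALSE]
  rownames(out) <- NULL
  n_adhoc <- 0L
  for (id in unique(out$bird_id)) {
    sch <- schedules[[id]]
    i <- which(out$bird_id == id)
    lm <- .local_minutes(out$t[i], sch$utc_offset)
    sm <- .slot_minutes(sch$daily_slots)
    d <- abs(outer(lm, sm, "-"))
    d <- pmin(d, 1440 - d)                      # circular distance
    j <- apply(d, 1, which.min)
    ok <- d[cbind(seq_along(i), j)] <= slot_tol_min
    out$slot[i[ok]] <- sch$daily_slots[j[ok]]
    n_adhoc <- n_adhoc + sum(!ok)
  }
  if (n_adhoc > 0)
    .warnf("%d fix(es) exceeded the %d-min slot tolerance; kept as 'adhoc'",
           n_adhoc, slot_tol_min)
  out
}

#' Trim a track to its migratory period
#'
#' Removes the leading and trailing maximal runs of fixes in which every
#' fix lies within `stationary_radius_km` of the run's first fix, provided
#' the run spans at least `stationary_days`. Such runs are the stationary
#' wintering/breeding residency periods bracketing migration; interior
#' fixes are never removed.
#'
#' @param fixes fixes for a single bird, sorted by time
#' @param stationary_radius_km residency radius, km
#' @param stationary_days minimum residency span, days
#' @return the trimmed fix table (possibly empty, with a warning, when the
#'   whole track is stationary)
#' @export
trim_migration <- function(fixes, stationary_radius_km = 30,
                           stationary_days = 3) {
  if (length(unique(fixes$bird_id)) > 1)
    .stopf("trim_migration expects fixes for a single bird")
  n <- nrow(fixes)
  if (n == 0) return(fixes)

  run_len <- function(idx) {   # maximal run anchored at idx[1]
    d <- geodesic_km(fixes$lat[idx[1]], fixes$lon[idx[1]],
                     fixes$lat[idx], fixes$lon[idx])
    out <- which(d > stationary_radius_km)
    if (length(out) == 0) length(idx) else out[1] - 1L
  }
  span_days <- function(idx)
    as.numeric(difftime(fixes$t[idx[length(idx)]], fixes$t[idx[1]],
                        units = "days"))

  keep <- rep(TRUE, n)
  k <- run_len(seq_len(n))
  if (k >= 2 && span_days(seq_len(k)) >= stationary_days)
    keep[seq_len(k)] <- FALSE
  # trailing run: smallest start i such that all of i..n sit within radius
  # of fix i
  i <- n
  while (i > 1) {
    d <- geodesic_km(fixes$lat[i - 1], fixes$lon[i - 1],
                     fixes$lat[(i - 1):n], fixes$lon[(i - 1):n])
    if (all(d <= stationary_radius_km)) i <- i - 1L else break
  }
  if (i < n && span_days(i:n) >= stationary_days)
    keep[i:n] <- FALSE
  out <- fixes[keep, , drop = FALSE]
  if (nrow(out) == 0)
    .warnf("all fixes for bird %s are stationary; track fully trimmed",
           fixes$bird_id[1])
  rownames(out) <- NULL
  out
}
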