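# Per-segment speeds and per-bird movement summaries.

#' Migration speed of a segment
#'
#' @param segment one-row segment (or any list with `distance_km` and
#'   `duration_h`); vectorised over rows when given the full table
#' @return speed in km/h
#' @export
segment_speed <- function(segment) {
  if (any(segment$duration_h <= 0)) .stopf("segment duration must be positive")
  segment$distance_km / segment$duration_h
}

#' Longest distance covered within any 24-h window
#'
#' Maximum, over windows of consecutive gap-free segments spanning at most
#' 24 h of elapsed time, of the summed segment distances.
#'
#' @param segments segments of one bird, sorted by time
#' @param tol_min tolerance for treating segments as consecutive, minutes
#' @return distance in km (0 for empty input)
#' @export
max_24h_distance <- function(segments, tol_min = 5) {
  n <- nrow(segments)
  if (n == 0) return(0)
  best <- 0
  for (i in seq_len(n)) {
    total <- 0
    for (j in i:n) {
      if (j > i) {
        gap <- abs(as.numeric(difftime(segments$t_start[j],
                                       segments$t_end[j - 1], units = "mins")))
        if (gap > tol_min) break
      }
      span <- as.numeric(difftime(segments$t_end[j], segments$t_start[i],
                                  units = "hours"))
      if (span > 24 + tol_min / 60) break
      total <- total + segments$distance_km[j]
      best <- max(best, total)
    }
  }
  best
}

#' Mean and standard error of a group of values
#'
#' The standard error uses the population (divisor-`n`) standard
#' deviation, `se = popSD / sqrt(n)`, so a single value reports
#' `x +/- 0.00`. Note this differs from the more common `n - 1` sample
#' convention.
#'
#' @param values numeric vector, `n >= 1`
#' @return named vector `c(mean, se)`
#' @export
group_mean_se <- function(values) {
  n <- length(values)
  if (n == 0) .stopf("group_mean_se needs at least one value")
  m <- mean(values)
  se <- sqrt(mean((values - m)^2)) / sqrt(n)
  c(mean = m, se = se)
}

#' Whole-number percentage
#'
#' `round(100 * count / total)` with ties rounded half away from zero.
#'
#' @param count,total non-negative integers, `count <= total`, `total > 0`
#' @return integer percent
#' @export
percent_of <- function(count, total) {
  if (total <= 0) .stopf("total must be positive")
  if (count < 0 || count > total) .stopf("count must be in [0, total]")
  as.integer(.round_half_away(100 * count / total))
}

.cell_key <- function(phase, surface) paste(surface, phase, sep = "/")

#' Per-bird movement summary
#'
#' Counts of day/night water flights, total track distance, per
#' phase-by-surface distance and speed statistics (mean +/- SE in the
#' [group_mean_se()] convention), per-cell speed maxima, and the longest
#' 24-h distance. Cells with no segments are reported as `NA` (printed as
#' a dash in the exported tables).
#'
#' @param segments classified segments (with `surface`) of one bird
#' @return a `bird_summary` list
#' @export
bird_summary <- function(segments) {
  if (!"surface" %in% names(segments))
    .stopf("segments must be surface-classified first")
  id <- if (nrow(segments)) segments$bird_id[1] else NA_character_
  cells <- expand.grid(surface = c("land", "water"),
                       phase = c("day", "night"),
                       stringsAsFactors = FALSE)
  dist_stats <- speed_stats <- list()
  for (k in seq_len(nrow(cells))) {
    sel <- segments$surface == cells$surface[k] &
           segments$phase == cells$phase[k]
    key <- .cell_key(cells$phase[k], cells$surface[k])
    if (!any(sel)) {
      dist_stats[[key]] <- c(mean = NA_real_, se = NA_real_, n = 0,
                             max = NA_real_)
      speed_stats[[key]] <- c(mean = NA_real_, se = NA_real_,
                              max = NA_real_)
    } else {
      d <- segments$distance_km[sel]
      v <- segment_speed(segments[sel, , drop = FALSE])
      dist_stats[[key]] <- c(group_mean_se(d), n = sum(sel), max = max(d))
      speed_stats[[key]] <- c(group_mean_se(v), max = max(v))
    }
  }
  structure(list(
    bird_id = id,
    n_day_water = sum(segments$surface == "water" & segments$phase == "day"),
    n_night_water = sum(segments$surface == "water" & segments$phase == "night"),
    total_km = sum(segments$distance_km),
    distance = dist_stats,
    speed = speed_stats,
    max_24h_km = max_24h_distance(segments)),
    class = "bird_summary")
}

#' @export
print.bird_summary <- function(x, ...) {
  cat(sprintf("Bird %s: total %.1f km, max 24-h %.1f km\n",
              x$bird_id, x$total_km, x$max_24h_km))
  cat(sprintf("  water flights: %d day, %d night\n",
              x$n_day_water, x$n_night_water))
  for (key in names(x$distance)) {
    d <- x$distance[[key]]
    if (d[["n"]] > 0)
      cat(sprintf("  %-11s %2.0f segs, %7.2f +/- %.2f km, top speed %.0f km/h\n",
                  key, d[["n"]], d[["mean"]], d[["se"]],
                  x$speed[[key]][["max"]]))
  }
  invisible(x)
}

# mean +/- SE string with absent cells as a dash
.fmt_cell <- function(stat, digits = 2) {
  if (is.na(stat[["mean"]])) return("-")
  sprintf(paste0("%.", digits, "f ± %.", digits, "f"),
          stat[["mean"]], stat[["se"]])
}

#' Group summary tables across birds
#'
#' Builds the flight-count, distance and speed tables (one row per bird)
#' from classified segments of all birds.
#'
#' @param segments classified segments, any number of birds
#' @return list of data frames `flights`, `distance`, `speed`
#' @export
summary_tables <- function(segments) {
  ids <- unique(segments$bird_id)
  sums <- lapply(ids, function(id)
    bird_summary(segments[segments$bird_id == id, , drop = FALSE]))
  flights <- data.frame(
    bird_id = ids,
    n_day_water = vapply(sums, `[[`, 0, "n_day_water"),
    n_night_water = vapply(sums, `[[`, 0, "n_night_water"))
  cell_cols <- function(part, digits) {
    out <- data.frame(bird_id = ids)
    for (key in c("land/day", "land/night", "water/day", "water/night"))
      out[[gsub("/", "_", key)]] <- vapply(
        sums, function(s) .fmt_cell(s[[part]][[key]], digits), "")
    out
  }
  distance <- cell_cols("distance", 2)
  distance$total_km <- vapply(sums, `[[`, 0, "total_km")
  distance <- distance[, c("bird_id", "total_km", "land_day", "land_night",
                           "water_day", "water_night")]
  speed <- cell_cols("speed", 0)
  for (key in c("land/day", "land/night", "water/day", "water/night"))
    speed[[paste0("max_", gsub("/", "_", key))]] <- vapply(
      sums, function(s) {
        m <- s$speed[[key]][["max"]]
        if (is.na(m)) NA_real_ else round(m)
      }, 0)
  list(flights = flights, distance = distance, speed = speed)
}
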