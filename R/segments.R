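# Schedule normalisation and 12-h segment construction.
#
# Three-slot tags record one fix inside a 12-h interval (0000 inside the
# 1800->0600 night, 1000 inside the 0400->1600 day). Those interior fixes
# are kept as auxiliary waypoints: they refine the along-path distance of
# the containing segment but never define a phase boundary, so every
# schedule yields at most two comparable 12-h segments per tracking day.

#' Normalise fixes of a 3-slot schedule into 12-h intervals
#'
#' Marks interior fixes (slot `"0000"` or `"1000"`) as waypoints; the
#' interval-boundary fixes remain the segment endpoints. For 2-slot
#' schedules this is the identity apart from adding the `waypoint` column.
#' Idempotent.
#'
#' @param fixes fixes for one bird (from [read_fixes()])
#' @param schedule the bird's [tag_schedule()]
#' @return `fixes` with a logical `waypoint` column
#' @export
normalize_schedule <- function(fixes, schedule) {
  if (!inherits(schedule, "tag_schedule")) .stopf("schedule must be a tag_schedule")
  interior <- setdiff(schedule$daily_slots, schedule$night_window)
  if (length(interior) && !interior %in% c("0000", "1000"))
    .stopf("slots {%s} do not bracket a 12-h night window",
           paste(schedule$daily_slots, collapse = ","))
  fixes$waypoint <- fixes$slot %in% interior
  fixes
}

#' Build 12-h day/night track segments
#'
#' Consecutive non-waypoint fixes 12 h apart (within `tol_h`) form one
#' segment; larger gaps break the chain and are recorded in the `gaps`
#' attribute. A segment is `night` when its start slot opens the schedule's
#' night window (1800 or 1600 local), otherwise `day`. Distance is the
#' great-circle distance between the endpoint fixes, summed through any
#' waypoint fix recorded inside the interval.
#'
#' @param fixes normalised fixes for one bird
#' @param schedule the bird's [tag_schedule()]
#' @param tol_h tolerance around the nominal 12-h spacing, hours
#' @return data frame of segments (one row per 12-h interval) with
#'   endpoint coordinates, `phase`, `duration_h` and `distance_km`;
#'   attribute `"gaps"` lists the broken chains
#' @export
build_segments <- function(fixes, schedule, tol_h = 1) {
  if (!"waypoint" %in% names(fixes)) fixes <- normalize_schedule(fixes, schedule)
  ep <- fixes[!fixes$waypoint, , drop = FALSE]
  segs <- list(); gaps <- list()
  if (nrow(ep) >= 2) {
    for (i in seq_len(nrow(ep) - 1)) {
      dt <- as.numeric(difftime(ep$t[i + 1], ep$t[i], units = "hours"))
      if (abs(dt - 12) > tol_h) {
        gaps[[length(gaps) + 1]] <- data.frame(
          bird_id = ep$bird_id[i], t_from = ep$t[i], t_to = ep$t[i + 1],
          gap_h = dt)
        next
      }
      wp <- fixes[fixes$waypoint & fixes$t > ep$t[i] & fixes$t < ep$t[i + 1], ,
                  drop = FALSE]
      path_lat <- c(ep$lat[i], wp$lat, ep$lat[i + 1])
      path_lon <- c(ep$lon[i], wp$lon, ep$lon[i + 1])
      m <- length(path_lat)
      dist <- sum(geodesic_km(path_lat[-m], path_lon[-m],
                              path_lat[-1], path_lon[-1]))
      phase <- if (ep$slot[i] == schedule$night_window[1]) "night" else "day"
      segs[[length(segs) + 1]] <- data.frame(
        bird_id = ep$bird_id[i],
        t_start = ep$t[i], t_end = ep$t[i + 1],
        lat_start = ep$lat[i], lon_start = ep$lon[i],
        lat_end = ep$lat[i + 1], lon_end = ep$lon[i + 1],
        slot_start = ep$slot[i], slot_end = ep$slot[i + 1],
        phase = phase, duration_h = dt, distance_km = dist,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(segs)) do.call(rbind, segs) else
    data.frame(bird_id = character(), t_start = .parse_utc(character()),
               t_end = .parse_utc(character()), lat_start = numeric(),
               lon_start = numeric(), lat_end = numeric(), lon_end = numeric(),
               slot_start = character(), slot_end = character(),
               phase = character(), duration_h = numeric(),
               distance_km = numeric(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "gaps") <- if (length(gaps)) do.call(rbind, gaps) else NULL
  out
}

#' Build segments for every bird in a fix table
#'
#' Convenience wrapper applying [normalize_schedule()] and
#' [build_segments()] per bird and row-binding the results.
#'
#' @param fixes fixes for any number of birds
#' @param schedules named list of [tag_schedule()] objects
#' @param tol_h tolerance around the nominal 12-h spacing, hours
#' @return combined segment table, sorted by `(bird_id, t_start)`
#' @export
build_all_segments <- function(fixes, schedules, tol_h = 1) {
  parts <- lapply(unique(fixes$bird_id), function(id) {
    f <- fixes[fixes$bird_id == id, , drop = FALSE]
    build_segments(normalize_schedule(f, schedules[[id]]), schedules[[id]],
                   tol_h = tol_h)
  })
  gaps <- do.call(rbind, Filter(Negate(is.null), lapply(parts, attr, "gaps")))
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  attr(out, "gaps") <- gaps
  out
}
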