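# Tag schedules. Tags record fixes at preset local times (daylight-time
# labels with fixed UTC offsets: CDT = UTC-5, EDT = UTC-4). Two-slot tags
# fix at the day/night boundaries; three-slot tags add an interior fix that
# is folded back into the containing 12-h interval.

KNOWN_SLOTS <- c("0000", "0400", "0600", "1000", "1600", "1800")

.slot_minutes <- function(slot) {
  as.integer(substr(slot, 1, 2)) * 60 + as.integer(substr(slot, 3, 4))
}

#' Define a tag schedule
#'
#' @param bird_id tag/bird identifier
#' @param utc_offset fixed local UTC offset in hours (CDT = -5, EDT = -4)
#' @param slots character vector of scheduled local fix times
#'   (subset of `"0000" "0400" "0600" "1000" "1600" "1800"`), 2 or 3 per day
#' @param destination optional breeding destination
#'   (`"texas"`, `"manitoba"`, `"florida"`, ...), used to pick the optimal
#'   crossing direction per waterbody
#' @return a `tag_schedule` list with the inferred 12-h `night_window`
#' @export
tag_schedule <- function(bird_id, utc_offset, slots, destination = NULL) {
  slots <- sort(unique(as.character(slots)))
  if (!all(slots %in% KNOWN_SLOTS))
    .stopf("unknown slot(s) %s for bird %s",
           paste(setdiff(slots, KNOWN_SLOTS), collapse = ","), bird_id)
  if (!length(slots) %in% 2:3)
    .stopf("schedule for bird %s must have 2 or 3 daily slots", bird_id)
  # night window is 1800->0600 or 1600->0400; both bounds must be scheduled
  if (all(c("0600", "1800") %in% slots)) {
    night <- c("1800", "0600")
  } else if (all(c("0400", "1600") %in% slots)) {
    night <- c("1600", "0400")
  } else {
    .stopf("slots {%s} for bird %s do not bracket a 12-h night window",
           paste(slots, collapse = ","), bird_id)
  }
  extra <- setdiff(slots, night)
  if (length(extra) > 1)
    .stopf("slots {%s} for bird %s do not bracket a 12-h night window",
           paste(slots, collapse = ","), bird_id)
  structure(list(bird_id = as.character(bird_id),
                 utc_offset = utc_offset,
                 daily_slots = slots,
                 night_window = night,
                 destination = destination),
            class = "tag_schedule")
}

#' Read tag schedules from a JSON or YAML config
#'
#' The file maps bird ids to entries with fields `utc_offset`, `slots`
#' and optionally `destination`.
#'
#' @param path path to a `.json`, `.yaml` or `.yml` file
#' @return named list of [tag_schedule()] objects
#' @export
read_schedules <- function(path) {
  if (!file.exists(path)) .stopf("schedule file not found: %s", path)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      .stopf("yaml package required to read %s", path)
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  }
  out <- lapply(names(raw), function(id) {
    e <- raw[[id]]
    tag_schedule(id, e$utc_offset, unlist(e$slots), e$destination)
  })
  names(out) <- names(raw)
  out
}

#' Write tag schedules to JSON
#' @param schedules named list of [tag_schedule()] objects
#' @param path output path
#' @export
write_schedules <- function(schedules, path) {
  obj <- lapply(schedules, function(s)
    list(utc_offset = s$utc_offset, slots = as.list(s$daily_slots),
         destination = s$destination))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(path)
}

# local minutes-of-day of a UTC time under a fixed offset
.local_minutes <- function(t, utc_offset) {
  (as.numeric(t) / 60 + utc_offset * 60) %% 1440
}
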