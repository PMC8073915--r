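# Published per-bird tracking summaries for the 11 GPS-tracked purple
# martins (spring migration, 2018-2020). These printed tables are inputs
# to the group-level arithmetic: water-flight counts per bird and total
# track distance per bird. A dash in the printed night-water column
# (bird 48051) is recorded as 0 flights.

#' Reference per-bird tracking summary
#'
#' Per-bird water-flight counts and total spring-migration distances for
#' the 11-bird purple martin GPS cohort, as printed in the source
#' tracking study. Used by the group summary arithmetic
#' ([group_mean_se()], [percent_of()]) and as a realism reference for the
#' synthetic generator.
#'
#' @return data frame with columns `bird_id`, `breeding_ground`,
#'   `n_day_water`, `n_night_water`, `total_km`
#' @export
martin_reference <- function() {
  data.frame(
    bird_id = c("1598", "1602", "2810", "48041", "48042", "48045", "48046",
                "48051", "48052", "48794", "2177"),
    breeding_ground = c("Florida", "Florida", "Texas", "Texas", "Texas",
                        "Texas", "Texas", "Texas", "Texas", "Texas",
                        "Manitoba"),
    n_day_water = c(1, 3, 1, 2, 1, 2, 3, 1, 3, 1, 3),
    n_night_water = c(2, 2, 2, 2, 1, 2, 3, 0, 2, 1, 2),
    total_km = c(4859.26, 6201.80, 3907.73, 7138.05, 3620.68, 8079.28,
                 6784.23, 8397.53, 7515.37, 4152.84, 7611.80),
    stringsAsFactors = FALSE)
}

#' Reference crossing-decision counts
#'
#' Study-level decision counts from the same cohort: water crossings and
#' detours entering the route-choice model, how many crossings were
#' initiated at night, and how many birds initiated a crossing in the
#' dark.
#'
#' @return named list of integer counts
#' @export
martin_decision_counts <- function() {
  list(n_birds = 11L,
       n_crossings = 22L, n_detours = 6L,
       n_crossings_at_night = 7L,
       n_birds_initiating_at_night = 6L)
}
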