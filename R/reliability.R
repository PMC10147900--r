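# Reliability screening: which county-years of feed data are trustworthy,
# and which counties enter which analysis tier.

#' Assess per-county-year feed reliability
#'
#' A county-year is reliable when the feed reported in at least 50% of the
#' expected 10-minute slots (`reporting_fraction >= 0.5`) *and* the feed's
#' tracked customers covered at least 50% of the county's registered
#' customers (`coverage_fraction >= 0.5`). Both thresholds are inclusive.
#'
#' `reporting_fraction` counts distinct reported 10-minute slots against the
#' leap-aware number of slots in the calendar year (days x 144).
#' `coverage_fraction` is the maximum simultaneous `customers_tracked`
#' divided by the registry's `customers_total` (households + businesses); a
#' stream without a `customers_tracked` column is assumed to track the full
#' county (coverage 1). Years are the county's local calendar years, using
#' the registry's fixed UTC offset.
#'
#' @param streams Stream tibble (`county_id`, `timestamp` UTC,
#'   `customers_out`, optionally `customers_tracked`).
#' @param registry County registry tibble.
#' @param years Optional integer vector restricting assessed years; default
#'   is every local year present in the stream.
#' @return Tibble: `county_id`, `year`, `reporting_fraction`,
#'   `coverage_fraction`, `reliable`.
#' @export
assess_reliability <- function(streams, registry, years = NULL) {
  check_columns(streams, c("county_id", "timestamp", "customers_out"), "streams")
  check_columns(registry, c("county_id", "customers_total", "utc_offset_hours"),
                "registry")
  if (any(registry$customers_total <= 0)) {
    abort("registry contains counties with customers_total <= 0.",
          class = "outagegrid_invalid_denominator")
  }
  has_tracked <- "customers_tracked" %in% names(streams)

  local <- streams %>%
    inner_join(registry %>% select("county_id", "customers_total",
                                   "utc_offset_hours"),
               by = "county_id") %>%
    mutate(
      local_time = .data$timestamp + .data$utc_offset_hours * 3600,
      year = utc_year(.data$local_time),
      slot = floor(as.numeric(.data$local_time) / SLOT_SECONDS)
    )
  if (!is.null(years)) local <- local %>% filter(.data$year %in% years)

  out <- local %>%
    group_by(.data$county_id, .data$year, .data$customers_total) %>%
    summarise(
      n_slots = dplyr::n_distinct(.data$slot),
      max_tracked = if (has_tracked) {
        max(.data$customers_tracked, na.rm = TRUE)
      } else {
        .data$customers_total[1]
      },
      .groups = "drop"
    ) %>%
    mutate(
      reporting_fraction = pmin(1, .data$n_slots /
                                  (days_in_year(.data$year) * SLOTS_PER_DAY)),
      coverage_fraction = pmin(1, .data$max_tracked / .data$customers_total),
      reliable = .data$reporting_fraction >= 0.5 & .data$coverage_fraction >= 0.5
    ) %>%
    select("county_id", "year", "reporting_fraction", "coverage_fraction",
           "reliable") %>%
    arrange(.data$county_id, .data$year)
  out
}

#' Assign counties to reliability tiers
#'
#' Counts the reliable years per county and derives the nested study tiers:
#' counties with at least one, at least two, and exactly `n_years_full`
#' (default 3, the span length) reliable years. Counties with zero reliable
#' years are excluded entirely.
#'
#' @param assessments Tibble from [assess_reliability()]; one row per
#'   county-year (duplicates are an error).
#' @param n_years_full Number of reliable years required for the full-span
#'   tier.
#' @return Tibble: `county_id`, `years_reliable`, logical `tier_1plus`,
#'   `tier_2plus`, `tier_full`.
#' @export
assign_tiers <- function(assessments, n_years_full = 3L) {
  check_columns(assessments, c("county_id", "year", "reliable"), "assessments")
  if (anyDuplicated(assessments[c("county_id", "year")])) {
    abort("duplicate county-year assessments.", class = "outagegrid_invalid_input")
  }
  assessments %>%
    group_by(.data$county_id) %>%
    summarise(years_reliable = sum(.data$reliable), .groups = "drop") %>%
    filter(.data$years_reliable >= 1L) %>%
    mutate(
      tier_1plus = .data$years_reliable >= 1L,
      tier_2plus = .data$years_reliable >= 2L,
      tier_full = .data$years_reliable >= n_years_full
    ) %>%
    arrange(.data$county_id)
}

#' Reliable county-years as a lookup table
#'
#' @param assessments Tibble from [assess_reliability()].
#' @return Tibble of the reliable `county_id`, `year` pairs.
#' @export
reliable_county_years <- function(assessments) {
  assessments %>%
    filter(.data$reliable) %>%
    select("county_id", "year")
}
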