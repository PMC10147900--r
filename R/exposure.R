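# Exposure metrics: hourly aggregation of the 10-minute feed, outage-event
# detection at a relative customer threshold, and SAIFI/SAIDI-like
# relative and absolute summaries.

#' Customer denominator for a county
#'
#' The exposure denominator is the estimated number of electricity customers:
#' census households plus business establishments.
#'
#' @param households,businesses Non-negative counts (vectorised).
#' @return `households + businesses`.
#' @examples
#' estimate_customer_denominator(80000, 20000)
#' @export
estimate_customer_denominator <- function(households, businesses) {
  if (any(households < 0) || any(businesses < 0)) {
    stop_bad_arg("households and businesses must be non-negative.")
  }
  households + businesses
}

#' Aggregate a 10-minute feed to county-hours
#'
#' Collapses the feed to one row per county and local clock hour. Two
#' statistics are kept: the within-hour maximum of customers out (used for
#' event *detection*, so an outage visible at any reading counts) and the
#' within-hour mean over reported readings (used for customer-hour
#' *integration*; readings are treated as covering equal 10-minute reporting
#' slots). Hours with no report appear with `reported = FALSE` and `NA`
#' values, on a complete hourly grid spanning each county's stream.
#'
#' @param streams Stream tibble (`county_id`, `timestamp` UTC,
#'   `customers_out`).
#' @param registry County registry (supplies `utc_offset_hours` for local
#'   clock conversion).
#' @return Tibble: `county_id`, `hour_start` (local clock, strictly
#'   increasing within county), `customers_out_max`, `customers_out_mean`,
#'   `reported`.
#' @export
aggregate_to_hourly <- function(streams, registry) {
  check_columns(streams, c("county_id", "timestamp", "customers_out"), "streams")
  check_columns(registry, c("county_id", "utc_offset_hours"), "registry")
  if (any(streams$customers_out < 0)) {
    abort("streams contain negative customers_out readings.",
          class = "outagegrid_invalid_input")
  }
  df <- streams %>%
    inner_join(registry %>% select("county_id", "utc_offset_hours"),
               by = "county_id")
  # Grouped max/mean over millions of rows: integer keys + rowsum / ordered
  # deduplication are much faster than a grouped summarise here.
  hour_num <- floor(as.numeric(df$timestamp) / 3600 + df$utc_offset_hours)
  cid <- match(df$county_id, unique(df$county_id))
  key <- cid * 2^31 + (hour_num - min(hour_num))
  sums <- rowsum(df$customers_out, key, reorder = TRUE)
  cnts <- rowsum(rep(1L, nrow(df)), key, reorder = TRUE)
  ord <- order(key, -df$customers_out)
  first <- !duplicated(key[ord])
  hourly <- tibble(
    county_id = df$county_id[ord][first],
    hour_start = as.POSIXct(hour_num[ord][first] * 3600,
                            origin = "1970-01-01", tz = "UTC"),
    customers_out_max = df$customers_out[ord][first],
    customers_out_mean = as.numeric(sums) / as.numeric(cnts)
  )
  # Complete the hourly grid per county so unreported hours are explicit.
  span <- hourly %>%
    group_by(.data$county_id) %>%
    summarise(first = min(.data$hour_start), last = max(.data$hour_start),
              .groups = "drop")
  grid <- purrr::map2_dfr(
    span$county_id, seq_len(nrow(span)),
    function(cid, i) {
      tibble(county_id = cid,
             hour_start = seq(span$first[i], span$last[i], by = 3600))
    }
  )
  grid %>%
    left_join(hourly, by = c("county_id", "hour_start")) %>%
    mutate(reported = !is.na(.data$customers_out_max)) %>%
    arrange(.data$county_id, .data$hour_start)
}

#' Data-driven outage threshold from pooled county-hours
#'
#' Computes a percentile (default the 90th) of the pooled distribution of
#' hourly fraction-of-customers-out across all counties. The pipeline's
#' default threshold is the fixed 0.1% (`0.001`) of county customers, which
#' corresponds to the 90th percentile of customers out per county-hour in
#' national feeds; this operation is the data-driven alternative. Quantiles
#' use linear interpolation between order statistics
#' (`stats::quantile(type = 7)`).
#'
#' @param hourly Hourly series from [aggregate_to_hourly()].
#' @param registry County registry (for `customers_total`).
#' @param percentile Percentile in (0, 100); default 90.
#' @return A single fraction.
#' @export
derive_threshold <- function(hourly, registry, percentile = 90) {
  check_columns(hourly, c("county_id", "customers_out_max", "reported"), "hourly")
  pooled <- hourly %>%
    filter(.data$reported) %>%
    inner_join(registry %>% select("county_id", "customers_total"),
               by = "county_id") %>%
    mutate(frac = .data$customers_out_max / .data$customers_total) %>%
    pull("frac")
  if (!length(pooled)) {
    abort("no reported county-hours to pool.", class = "outagegrid_invalid_input")
  }
  unname(quantile(pooled, probs = percentile / 100, type = 7))
}

#' Detect outage events as threshold-crossing runs of county-hours
#'
#' An outage event is a maximal run of consecutive reported hours in which
#' the hourly maximum fraction of customers without power reaches or exceeds
#' the threshold (`customers_out_max / customers_total >= threshold`,
#' inclusive). An unreported hour terminates a run (missing data is not
#' treated as an outage), so feed blackouts inside a long outage split it.
#' The event duration is the run length in hours; `event_customer_hours`
#' integrates the within-hour mean customers out over the event.
#'
#' @param hourly Hourly series from [aggregate_to_hourly()] (local clock).
#' @param registry County registry (for `customers_total`).
#' @param threshold Fraction of county customers, in (0, 1); default 0.001
#'   (0.1%).
#' @return Tibble: `county_id`, `start_hour` (local), `duration_hours`,
#'   `peak_customers_out`, `event_customer_hours`.
#' @export
detect_outage_events <- function(hourly, registry, threshold = 0.001) {
  check_fraction(threshold, "threshold", lo = 1e-12, hi = 1 - 1e-12)
  check_columns(hourly, c("county_id", "hour_start", "customers_out_max",
                          "customers_out_mean", "reported"), "hourly")
  df <- hourly %>%
    inner_join(registry %>% select("county_id", "customers_total"),
               by = "county_id") %>%
    arrange(.data$county_id, .data$hour_start) %>%
    mutate(above = .data$reported &
             .data$customers_out_max / .data$customers_total >= threshold)
  runs <- df %>%
    group_by(.data$county_id) %>%
    mutate(run = cumsum(.data$above & !lag(.data$above, default = FALSE))) %>%
    ungroup() %>%
    filter(.data$above)
  if (!nrow(runs)) {
    return(tibble(county_id = character(), start_hour = as_utc(character()),
                  duration_hours = integer(), peak_customers_out = numeric(),
                  event_customer_hours = numeric()))
  }
  runs %>%
    group_by(.data$county_id, .data$run) %>%
    summarise(
      start_hour = min(.data$hour_start),
      duration_hours = dplyr::n(),
      peak_customers_out = max(.data$customers_out_max),
      event_customer_hours = sum(.data$customers_out_mean),
      .groups = "drop"
    ) %>%
    select(-"run") %>%
    arrange(.data$county_id, .data$start_hour)
}

#' Summarise detected events per county-year
#'
#' Counts 1+ hour and 8+ hour events per county-year (an event belongs to
#' the local calendar year containing its start hour), restricted to
#' reliable county-years when an assessment is given.
#'
#' @param events Event tibble from [detect_outage_events()].
#' @param reliable Optional tibble of reliable `county_id`, `year` pairs
#'   (see [reliable_county_years()]); `NULL` keeps all county-years.
#' @param min_durations Integer vector of duration classes (hours).
#' @return Tibble: `county_id`, `year`, one `n_events_<d>h` column per
#'   duration class, `event_customer_hours`.
#' @export
summarize_events <- function(events, reliable = NULL, min_durations = c(1L, 8L)) {
  check_columns(events, c("county_id", "start_hour", "duration_hours"), "events")
  ev <- events %>% mutate(year = utc_year(.data$start_hour))
  if (!"event_customer_hours" %in% names(ev)) {
    ev$event_customer_hours <- NA_real_
  }
  if (!is.null(reliable)) {
    ev <- ev %>% semi_join(reliable, by = c("county_id", "year"))
  }
  out <- ev %>%
    group_by(.data$county_id, .data$year) %>%
    summarise(
      event_customer_hours = sum(.data$event_customer_hours),
      .groups = "drop"
    )
  for (d in sort(min_durations)) {
    counts <- ev %>%
      filter(.data$duration_hours >= d) %>%
      count(.data$county_id, .data$year, name = paste0("n_events_", d, "h"))
    out <- out %>% left_join(counts, by = c("county_id", "year"))
  }
  out %>%
    mutate(across(dplyr::starts_with("n_events_"),
                  ~ dplyr::coalesce(.x, 0L))) %>%
    arrange(.data$county_id, .data$year)
}

#' Annual average exposure per county
#'
#' Divides each county's total event counts and customer-hours (over its
#' reliable years) by the number of reliable years, the SAIFI-like annual
#' average used throughout the analysis.
#'
#' @param per_year County-year summary from [summarize_events()].
#' @param reliable Tibble of reliable `county_id`, `year` pairs; defines the
#'   denominator (counties present here with no events still appear, with
#'   zero averages).
#' @return Tibble: `county_id`, `n_years`, `avg_*` per metric column.
#' @export
annualize_exposure <- function(per_year, reliable) {
  check_columns(reliable, c("county_id", "year"), "reliable")
  denom <- reliable %>% count(.data$county_id, name = "n_years")
  metric_cols <- setdiff(names(per_year), c("county_id", "year"))
  denom %>%
    left_join(
      per_year %>%
        group_by(.data$county_id) %>%
        summarise(across(dplyr::all_of(metric_cols), ~ sum(.x, na.rm = TRUE)),
                  .groups = "drop"),
      by = "county_id"
    ) %>%
    mutate(across(dplyr::all_of(metric_cols), ~ dplyr::coalesce(.x, 0) / .data$n_years,
                  .names = "avg_{.col}")) %>%
    select("county_id", "n_years", dplyr::starts_with("avg_")) %>%
    arrange(.data$county_id)
}

#' Customer-hours without power per county-year
#'
#' Integrates the hourly mean customers-without-power over reported hours:
#' customer-hours = sum of `customers_out_mean` x 1 hour, per county and
#' local calendar year.
#'
#' @param hourly Hourly series from [aggregate_to_hourly()].
#' @return Tibble: `county_id`, `year`, `customer_hours_total`.
#' @export
compute_customer_hours <- function(hourly) {
  check_columns(hourly, c("county_id", "hour_start", "customers_out_mean",
                          "reported"), "hourly")
  hourly %>%
    filter(.data$reported) %>%
    mutate(year = utc_year(.data$hour_start)) %>%
    group_by(.data$county_id, .data$year) %>%
    summarise(customer_hours_total = sum(.data$customers_out_mean),
              .groups = "drop")
}

#' Hours without power per customer
#'
#' The SAIDI-like per-customer form: total customer-hours divided by the
#' county customer denominator.
#'
#' @param customer_hours Tibble from [compute_customer_hours()].
#' @param registry County registry (for `customers_total`).
#' @return Input with an added `hours_per_customer` column.
#' @export
hours_per_customer <- function(customer_hours, registry) {
  check_columns(customer_hours, c("county_id", "customer_hours_total"),
                "customer_hours")
  reg <- registry %>% select("county_id", "customers_total")
  if (any(reg$customers_total <= 0)) {
    abort("customers_total must be positive.",
          class = "outagegrid_invalid_denominator")
  }
  customer_hours %>%
    inner_join(reg, by = "county_id") %>%
    mutate(hours_per_customer = .data$customer_hours_total / .data$customers_total) %>%
    select(-"customers_total")
}

#' Tabulate 8+ hour event start times by month and local hour
#'
#' @param events Event tibble (local `start_hour`).
#' @param min_duration Minimum duration (hours) for inclusion; default 8.
#' @return Complete 12 x 24 tibble: `month`, `hour`, `n`.
#' @export
tabulate_start_times <- function(events, min_duration = 8L) {
  check_columns(events, c("start_hour", "duration_hours"), "events")
  counts <- events %>%
    filter(.data$duration_hours >= min_duration) %>%
    mutate(month = utc_month(.data$start_hour), hour = utc_hour(.data$start_hour)) %>%
    count(.data$month, .data$hour)
  tidyr::expand_grid(month = 1:12, hour = 0:23) %>%
    left_join(counts, by = c("month", "hour")) %>%
    mutate(n = dplyr::coalesce(.data$n, 0L))
}
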