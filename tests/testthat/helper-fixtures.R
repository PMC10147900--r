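# Shared fixtures built in code.

# A single-county registry with a round customer count.
one_county_registry <- function(customers = 10000L, offset = 0L) {
  tibble::tibble(
    county_id = "01001", state_id = "01",
    businesses = as.integer(customers * 0.2),
    households = as.integer(customers - customers * 0.2),
    customers_total = as.integer(customers),
    grid_row = 1L, grid_col = 1L, utc_offset_hours = as.integer(offset)
  )
}

# Hand-built planted_outages object for deterministic stream construction.
make_planted <- function(county_id, start_time, duration_hours,
                         peak_fraction_out = 0.01) {
  start_time <- as.POSIXct(start_time, tz = "UTC")
  structure(
    list(
      events = tibble::tibble(
        county_id = county_id,
        start_time = start_time,
        start_date = as.Date(start_time),
        duration_hours = as.integer(duration_hours),
        peak_fraction_out = peak_fraction_out,
        merged_from = 1L
      ),
      truth = list(event_rate_per_county_day = NA_real_,
                   weather_relative_risks = list(), n_merged = 0L,
                   span = NULL, seed = NA_integer_)
    ),
    class = "planted_outages"
  )
}

# Hourly series straight from a fraction-out vector (one county).
hourly_from_fractions <- function(fracs, customers = 100000L,
                                  start = "2019-06-01 00:00",
                                  reported = rep(TRUE, length(fracs))) {
  t0 <- as.POSIXct(start, tz = "UTC")
  tibble::tibble(
    county_id = "01001",
    hour_start = t0 + (seq_along(fracs) - 1) * 3600,
    customers_out_max = ifelse(reported, round(fracs * customers), NA_real_),
    customers_out_mean = ifelse(reported, round(fracs * customers), NA_real_),
    reported = reported
  )
}

# Independent brute-force maximal-run enumerator over a binary vector:
# returns start indices and lengths of maximal TRUE runs via explicit loop.
enumerate_runs <- function(above) {
  starts <- integer(); lens <- integer()
  i <- 1L; n <- length(above)
  while (i <= n) {
    if (isTRUE(above[i])) {
      j <- i
      while (j < n && isTRUE(above[j + 1L])) j <- j + 1L
      starts <- c(starts, i); lens <- c(lens, j - i + 1L)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  list(starts = starts, lengths = lens)
}

# A tiny classified county-day calendar with chosen flags.
toy_classes <- function(flags_df) {
  base <- tibble::tibble(
    county_id = flags_df$county_id, date = flags_df$date,
    precip = FALSE, snow = FALSE, heat = FALSE, cold = FALSE,
    wildfire = FALSE, lightning = FALSE, cyclone = FALSE
  )
  for (ty in intersect(names(flags_df), names(base)[-(1:2)])) {
    base[[ty]] <- flags_df[[ty]]
  }
  categorize_calendar(base)
}
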