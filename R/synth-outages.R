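# Synthetic outage feeds: a county-day event-planting layer (used directly by
# the co-occurrence and clustering simulations) and a 10-minute stream
# materialisation layer on top of it.

default_onset_sampler <- function(n) {
  # 8+ hour outages cluster around early evening (peak demand); emulate an
  # onset centred at 18:00 local with most mass in 15:00-20:00.
  pmin(23L, pmax(0L, as.integer(round(rnorm(n, mean = 18, sd = 1.5)))))
}

default_duration_sampler <- function(n) {
  # 1 + Geometric(0.30) hours: P(duration >= 8) = 0.7^7 ~= 0.082, so roughly
  # one in twelve 1+ hour events is an 8+ hour event.
  pmin(72L, 1L + rgeom(n, prob = 0.30))
}

default_peak_sampler <- function(n) runif(n, 0.002, 0.05)

#' Plant county-level outage events with recorded ground truth
#'
#' Draws at most one outage-event start per county-day (Bernoulli with the
#' configured daily rate), assigns each started event a local onset hour, an
#' integer duration in hours, and a peak fraction of customers out, then
#' merges any events that would overlap in time within a county. When a
#' weather calendar and per-event-type relative risks are supplied, the daily
#' start probability is multiplied by the product of the relative risks of
#' the event types active in that county-day, which couples outage starts to
#' severe weather.
#'
#' @param registry County registry tibble (see [generate_registry()]). An
#'   optional `outage_rate_multiplier` column scales each county's daily rate
#'   (used to plant high-outage regions).
#' @param span_start,span_end Inclusive local calendar dates (coercible with
#'   `as.Date()`) covered by the simulation.
#' @param daily_event_rate Baseline probability that an outage event starts
#'   in a county on a given day.
#' @param calendar Optional county-day weather calendar tibble with logical
#'   columns `heat, cold, precip, snow, lightning, cyclone, wildfire` (see
#'   [generate_weather_calendar()]).
#' @param coupling Optional named numeric vector of relative risks (>= 0) per
#'   event type; missing types default to 1.
#' @param onset_sampler,duration_sampler,peak_sampler Functions of `n`
#'   returning onset hours (0-23), durations in whole hours (> 0), and peak
#'   fractions of customers out.
#' @param seed Integer seed.
#' @return A list of class `"planted_outages"` with `events` (tibble:
#'   `county_id`, `start_time` local clock, `start_date`, `duration_hours`,
#'   `peak_fraction_out`, `merged_from`) and `truth` (list recording the
#'   generating parameters, relative risks, merge count, and seed).
#' @export
plant_outage_events <- function(registry, span_start, span_end,
                                daily_event_rate = 0.01,
                                calendar = NULL, coupling = NULL,
                                onset_sampler = default_onset_sampler,
                                duration_sampler = default_duration_sampler,
                                peak_sampler = default_peak_sampler,
                                seed = 1L) {
  check_columns(registry, "county_id", "registry")
  check_fraction(daily_event_rate, "daily_event_rate")
  span_start <- as.Date(span_start); span_end <- as.Date(span_end)
  if (span_end < span_start) stop_bad_arg("`span_end` must not precede `span_start`.")
  if (!is.null(coupling) && any(coupling < 0)) {
    stop_bad_arg("`coupling` relative risks must be >= 0.")
  }
  dates <- seq(span_start, span_end, by = "day")
  mult <- if ("outage_rate_multiplier" %in% names(registry)) {
    registry$outage_rate_multiplier
  } else {
    rep(1, nrow(registry))
  }

  grid <- tidyr::expand_grid(county_id = registry$county_id, date = dates) %>%
    left_join(tibble(county_id = registry$county_id, mult = mult), by = "county_id")
  grid$rr <- 1
  if (!is.null(calendar) && !is.null(coupling)) {
    types <- intersect(names(coupling), WEATHER_TYPES)
    cal <- calendar %>% select("county_id", "date", dplyr::all_of(types))
    grid <- grid %>% left_join(cal, by = c("county_id", "date"))
    for (ty in types) {
      flag <- grid[[ty]]
      flag[is.na(flag)] <- FALSE
      grid$rr <- grid$rr * ifelse(flag, coupling[[ty]], 1)
    }
  }
  p <- pmin(1, daily_event_rate * grid$mult * grid$rr)

  with_seed(child_seed(seed, 2L), {
    started <- runif(nrow(grid)) < p
    ev <- grid[started, c("county_id", "date")]
    n_ev <- nrow(ev)
    ev$onset_hour <- if (n_ev) onset_sampler(n_ev) else integer()
    ev$duration_hours <- if (n_ev) duration_sampler(n_ev) else integer()
    ev$peak_fraction_out <- if (n_ev) peak_sampler(n_ev) else numeric()
    if (n_ev && any(ev$duration_hours <= 0)) {
      stop_bad_arg("`duration_sampler` must return positive durations.")
    }
    ev$start_time <- as_utc(as.POSIXct(ev$date, tz = "UTC")) + ev$onset_hour * 3600

    merged <- merge_overlapping_events(ev)
    # Clip events at the end of the simulated span so the recorded duration
    # matches what a detector scanning the span can observe.
    span_close <- as_utc(as.POSIXct(span_end, tz = "UTC")) + 86400
    merged$events <- merged$events %>%
      mutate(duration_hours = pmin(
        .data$duration_hours,
        as.integer(floor(as.numeric(span_close - .data$start_time, units = "hours")))
      ))
    structure(
      list(
        events = merged$events,
        truth = list(
          event_rate_per_county_day = daily_event_rate,
          weather_relative_risks = as.list(coupling %||% setNames(numeric(), character())),
          n_merged = merged$n_merged,
          span = c(as.character(span_start), as.character(span_end)),
          seed = as.integer(seed)
        )
      ),
      class = "planted_outages"
    )
  })
}

# Merge events that overlap in time within one county; keeps the earliest
# start, the latest end, and the largest peak. `merged_from` counts how many
# raw draws each final event absorbs.
merge_overlapping_events <- function(ev) {
  if (!nrow(ev)) {
    return(list(
      events = tibble(county_id = character(), start_time = as_utc(character()),
                      start_date = as.Date(character()), duration_hours = integer(),
                      peak_fraction_out = numeric(), merged_from = integer()),
      n_merged = 0L
    ))
  }
  ev$start_num <- as.numeric(ev$start_time)
  ev <- ev[order(ev$county_id, ev$start_num), , drop = FALSE]
  ev$end_num <- ev$start_num + ev$duration_hours * 3600
  out <- ev %>%
    group_by(.data$county_id) %>%
    mutate(run = cumsum(.data$start_num > lag(cummax(.data$end_num),
                                              default = -Inf))) %>%
    group_by(.data$county_id, .data$run) %>%
    summarise(
      start_num = min(.data$start_num),
      end_num = max(.data$end_num),
      peak_fraction_out = max(.data$peak_fraction_out),
      merged_from = dplyr::n(),
      .groups = "drop"
    ) %>%
    mutate(
      start_time = as.POSIXct(.data$start_num, origin = "1970-01-01", tz = "UTC"),
      duration_hours = as.integer(round((.data$end_num - .data$start_num) / 3600)),
      start_date = as.Date(floor(.data$start_num / 86400), origin = "1970-01-01")
    ) %>%
    select("county_id", "start_time", "start_date", "duration_hours",
           "peak_fraction_out", "merged_from") %>%
    arrange(.data$county_id, .data$start_time)
  list(events = out, n_merged = sum(out$merged_from > 1L))
}

#' Generate synthetic 10-minute outage feeds with ground truth
#'
#' Materialises a 10-minute-resolution customers-without-power stream per
#' county over the span: a sub-threshold noise floor (uniform below
#' `noise_max_fraction` of customers, default 0.05%) everywhere, planted
#' events from [plant_outage_events()] raised to their peak fraction, and a
#' configurable fraction of reporting slots dropped to emulate intermittent
#' feeds. Timestamps in the returned stream are UTC; events are planted on
#' the county's local clock using the registry's fixed UTC offset.
#'
#' @inheritParams plant_outage_events
#' @param gap_fraction Proportion of 10-minute slots that carry no report.
#' @param gap_mode `"iid"` drops slots independently; `"block"` drops
#'   contiguous feed blackouts with mean length `block_mean_slots` slots.
#' @param block_mean_slots Mean length (slots) of block gaps.
#' @param tracked_fraction Fraction of county customers the feed tracks
#'   (scalar or per-county vector); written as `customers_tracked`.
#' @param noise_max_fraction Upper bound of the uniform sub-threshold noise
#'   floor, as a fraction of county customers.
#' @param planted Optional result of [plant_outage_events()]; when `NULL`
#'   events are planted internally with the arguments above.
#' @return A list of class `"outage_simulation"` with `streams` (tibble:
#'   `county_id`, `timestamp` UTC, `customers_out`, `customers_tracked`),
#'   `events` (planted-event tibble, local clock), and `truth` (generating
#'   parameters incl. per-county dropped-slot counts and the seed).
#' @examples
#' reg <- generate_registry(2, 2, customer_range = c(10000, 10000), seed = 7)
#' sim <- generate_outage_streams(reg, "2019-01-01", "2019-01-07",
#'                                daily_event_rate = 0.2, seed = 7)
#' head(sim$streams)
#' sim$events
#' @export
generate_outage_streams <- function(registry, span_start, span_end,
                                    daily_event_rate = 0.01,
                                    calendar = NULL, coupling = NULL,
                                    onset_sampler = default_onset_sampler,
                                    duration_sampler = default_duration_sampler,
                                    peak_sampler = default_peak_sampler,
                                    gap_fraction = 0,
                                    gap_mode = c("iid", "block"),
                                    block_mean_slots = 9,
                                    tracked_fraction = 1,
                                    noise_max_fraction = 5e-4,
                                    seed = 1L,
                                    planted = NULL) {
  gap_mode <- match.arg(gap_mode)
  check_columns(registry, c("county_id", "customers_total", "utc_offset_hours"),
                "registry")
  check_fraction(gap_fraction, "gap_fraction")
  span_start <- as.Date(span_start); span_end <- as.Date(span_end)
  if (is.null(planted)) {
    planted <- plant_outage_events(
      registry, span_start, span_end, daily_event_rate,
      calendar = calendar, coupling = coupling,
      onset_sampler = onset_sampler, duration_sampler = duration_sampler,
      peak_sampler = peak_sampler, seed = seed
    )
  }
  stopifnot(inherits(planted, "planted_outages"))
  events <- planted$events

  n_days <- as.integer(span_end - span_start) + 1L
  n_slots <- n_days * SLOTS_PER_DAY
  t0 <- as_utc(as.POSIXct(span_start, tz = "UTC"))
  tracked_fraction <- rep_len(tracked_fraction, nrow(registry))

  with_seed(child_seed(seed, 3L), {
    per_county <- purrr::map(seq_len(nrow(registry)), function(i) {
      cid <- registry$county_id[i]
      total <- registry$customers_total[i]
      frac <- runif(n_slots, 0, noise_max_fraction)
      out <- as.integer(floor(frac * total))
      ev <- events[events$county_id == cid, , drop = FALSE]
      if (nrow(ev)) {
        start_slot <- as.integer(round(as.numeric(ev$start_time - t0, units = "secs") /
                                         SLOT_SECONDS)) + 1L
        end_slot <- start_slot + ev$duration_hours * SLOTS_PER_HOUR - 1L
        lvl <- as.integer(ceiling(ev$peak_fraction_out * total))
        for (j in seq_len(nrow(ev))) {
          idx <- max(1L, start_slot[j]):min(n_slots, end_slot[j])
          out[idx] <- pmax(out[idx], lvl[j])
        }
      }
      keep <- draw_reporting_mask(n_slots, gap_fraction, gap_mode, block_mean_slots)
      local_time <- t0 + (seq_len(n_slots) - 1L) * SLOT_SECONDS
      tibble(
        county_id = cid,
        timestamp = (local_time - registry$utc_offset_hours[i] * 3600)[keep],
        customers_out = out[keep],
        customers_tracked = as.integer(round(tracked_fraction[i] * total))
      )
    })
    dropped <- n_slots - vapply(per_county, nrow, integer(1))
    streams <- bind_rows(per_county)
    structure(
      list(
        streams = streams,
        events = events,
        truth = c(planted$truth, list(
          reporting_gap_fraction = gap_fraction,
          gap_mode = gap_mode,
          noise_max_fraction = noise_max_fraction,
          n_slots_expected = n_slots,
          n_slots_dropped = setNames(dropped, registry$county_id)
        ))
      ),
      class = "outage_simulation"
    )
  })
}

draw_reporting_mask <- function(n_slots, gap_fraction, gap_mode, block_mean_slots) {
  if (gap_fraction == 0) return(rep(TRUE, n_slots))
  if (gap_mode == "iid") return(runif(n_slots) >= gap_fraction)
  # Block mode: geometric-length feed blackouts whose expected total length
  # matches gap_fraction of the span.
  n_blocks <- max(1L, as.integer(round(gap_fraction * n_slots / block_mean_slots)))
  starts <- sample.int(n_slots, n_blocks)
  lens <- 1L + rgeom(n_blocks, prob = 1 / block_mean_slots)
  keep <- rep(TRUE, n_slots)
  for (b in seq_len(n_blocks)) {
    keep[starts[b]:min(n_slots, starts[b] + lens[b] - 1L)] <- FALSE
  }
  keep
}
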