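# Synthetic county-day weather: daily flags for the seven severe
# weather/climate event types plus raw daily values and climatology
# baselines constructed to be consistent with the flags, so the rule-based
# classifier can be validated round-trip.

#' Generate a synthetic county-day weather calendar with baselines
#'
#' Draws daily flags for the seven severe weather/climate event types with
#' the requested marginal rates, then constructs daily weather values
#' (temperature, precipitation, snowfall, lightning, cyclone distance,
#' wildfire area) and climatology baselines (county-week temperature 85th
#' and 15th percentiles, county precipitation 85th percentile) such that
#' applying the classification rules in [classify_county_day()] reproduces
#' the drawn flags.
#'
#' Flag construction respects the classifier's structure: anomalous heat and
#' cold are mutually exclusive, and snowfall suppresses the heavy
#' precipitation flag (the precedence rule), with the underlying
#' precipitation draw rate inflated by `1/(1 - p_snow)` so the *final*
#' precipitation flag still attains its requested marginal rate.
#'
#' @inheritParams plant_outage_events
#' @param base_rates Named numeric vector of marginal daily rates in `[0,1]`
#'   for `precip`, `snow`, `heat`, `cold`, `wildfire`, `lightning`,
#'   `cyclone`. Defaults approximate the isolated-event marginals of a
#'   continental U.S. county-day panel.
#' @return A list of class `"weather_sim"` with tibbles `calendar`
#'   (`county_id`, `date`, seven logical flags), `weather` (daily values),
#'   `baseline_temp` (`county_id`, `week`, `temp_p85_c`, `temp_p15_c`), and
#'   `baseline_precip` (`county_id`, `precip_p85_mm`).
#' @examples
#' reg <- generate_registry(2, 2, seed = 3)
#' ws <- generate_weather_calendar(reg, "2019-06-01", "2019-06-30", seed = 3)
#' head(ws$calendar)
#' @export
generate_weather_calendar <- function(registry, span_start, span_end,
                                      base_rates = c(precip = 0.16, snow = 0.02,
                                                     heat = 0.08, cold = 0.035,
                                                     wildfire = 0.004,
                                                     lightning = 0.005,
                                                     cyclone = 0.001),
                                      seed = 1L) {
  check_columns(registry, "county_id", "registry")
  if (any(base_rates < 0 | base_rates > 1)) {
    stop_bad_arg("`base_rates` must lie in [0, 1].")
  }
  rates <- setNames(rep(0, length(WEATHER_TYPES)), WEATHER_TYPES)
  rates[names(base_rates)] <- base_rates
  if (rates["heat"] + rates["cold"] > 1) {
    stop_bad_arg("heat and cold rates must sum to at most 1.")
  }
  span_start <- as.Date(span_start); span_end <- as.Date(span_end)
  dates <- seq(span_start, span_end, by = "day")

  with_seed(child_seed(seed, 4L), {
    grid <- tidyr::expand_grid(county_id = registry$county_id, date = dates)
    n <- nrow(grid)

    # Disjoint heat/cold from one uniform draw; exact marginals.
    u_temp <- runif(n)
    heat <- u_temp < rates["heat"]
    cold <- u_temp > 1 - rates["cold"]
    snow <- runif(n) < rates["snow"]
    # Inflate the raw precipitation draw so the post-precedence marginal
    # equals the requested rate.
    p_precip_raw <- if (rates["snow"] < 1) {
      min(1, rates["precip"] / (1 - rates["snow"]))
    } else {
      0
    }
    precip <- runif(n) < p_precip_raw & !snow
    lightning <- runif(n) < rates["lightning"]
    cyclone <- runif(n) < rates["cyclone"]
    wildfire <- runif(n) < rates["wildfire"]

    calendar <- grid %>%
      mutate(precip = precip, snow = snow, heat = heat, cold = cold,
             wildfire = wildfire, lightning = lightning, cyclone = cyclone)

    # Climatology baselines: seasonal county-week temperature percentiles
    # (warm mid-year), flat county precipitation percentile.
    weeks <- 1:53
    baseline_temp <- tidyr::expand_grid(county_id = registry$county_id,
                                        week = weeks) %>%
      mutate(
        temp_p85_c = 12 + 16 * cos(2 * pi * (.data$week - 29) / 53) +
          runif(dplyr::n(), -1, 1),
        temp_p15_c = .data$temp_p85_c - 12
      )
    baseline_precip <- tibble(
      county_id = registry$county_id,
      precip_p85_mm = runif(nrow(registry), 8, 15)
    )

    weather <- calendar %>%
      mutate(week = week_of_year(.data$date)) %>%
      left_join(baseline_temp, by = c("county_id", "week")) %>%
      left_join(baseline_precip, by = "county_id")

    n_w <- nrow(weather)
    # Temperature consistent with the heat/cold flags and percentile rules.
    temp_non <- with(weather, {
      hi <- pmin(temp_p85_c, 24)
      lo <- pmin(temp_p15_c, hi)
      lo + runif(n_w) * (hi - lo)
    })
    weather$temp_c <- dplyr::case_when(
      weather$heat ~ pmax(24, weather$temp_p85_c) + runif(n_w, 0.5, 4),
      weather$cold ~ pmin(0, weather$temp_p15_c) - runif(n_w, 0.5, 4),
      TRUE ~ temp_non
    )
    raw_precip_day <- weather$precip | (weather$snow & runif(n_w) < 0.5)
    weather$precip_mm <- ifelse(raw_precip_day,
                                weather$precip_p85_mm + rexp(n_w, 1 / 5),
                                runif(n_w, 0, 0.8 * weather$precip_p85_mm))
    weather$snowfall_cm <- ifelse(weather$snow, 2.54 + rexp(n_w, 1 / 3),
                                  runif(n_w, 0, 2.0))
    weather$lightning_flash <- weather$lightning
    weather$cyclone_distance_km <- ifelse(weather$cyclone, runif(n_w, 0, 100), Inf)
    weather$wildfire_area_km2 <- ifelse(weather$wildfire, 1 + rexp(n_w, 1 / 10),
                                        runif(n_w, 0, 0.9))

    structure(
      list(
        calendar = calendar,
        weather = weather %>%
          select("county_id", "date", "temp_c", "precip_mm", "snowfall_cm",
                 "lightning_flash", "cyclone_distance_km", "wildfire_area_km2"),
        baseline_temp = baseline_temp,
        baseline_precip = baseline_precip
      ),
      class = "weather_sim"
    )
  })
}
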