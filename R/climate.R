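# Severe weather / climate event classification of county-days and the
# co-occurrence ratio statistic relating event days to 8+ hour outage
# start days.

# Canonical type order used for combination labels.
WEATHER_TYPES <- c("precip", "snow", "heat", "cold", "wildfire", "lightning",
                   "cyclone")

WEATHER_LABELS <- c(
  precip = "Heavy precipitation", snow = "Snowfall", heat = "Anomalous heat",
  cold = "Anomalous cold", wildfire = "Wildfire", lightning = "Lightning",
  cyclone = "Tropical cyclone"
)

# "Heavy precipitation-anomalous heat" style: first label capitalised,
# subsequent labels lowercased, joined by hyphens in canonical type order.
combo_label <- function(flag_matrix) {
  apply(flag_matrix, 1, function(fl) {
    labs <- WEATHER_LABELS[WEATHER_TYPES[fl]]
    if (!length(labs)) return("None")
    rest <- tolower(labs[-1])
    paste(c(labs[1], rest), collapse = "-")
  })
}

#' Classify county-days into severe weather / climate event types
#'
#' Applies the seven daily rules to county-day weather values against
#' climatology baselines:
#' * anomalous heat: temperature > 24 degC *and* above the county-week 85th
#'   percentile (strict);
#' * anomalous cold: temperature < 0 degC *and* below the county-week 15th
#'   percentile (strict);
#' * heavy precipitation: daily precipitation > the county 85th percentile
#'   (strict), suppressed on snowfall days (see Details);
#' * snowfall: accumulation >= 2.54 cm (1 inch, inclusive);
#' * lightning: a flash occurred in the county;
#' * tropical cyclone: county within 100 km of a track centre (inclusive);
#' * wildfire: county intersects a >= 1 km^2 fire (inclusive).
#'
#' Each county-day is then categorised as `none` (no flags), `isolated`
#' (exactly one), or `multiple` (two or more), with a canonical hyphenated
#' combination label (fixed type order: heavy precipitation, snowfall,
#' anomalous heat, anomalous cold, wildfire, lightning, tropical cyclone).
#'
#' @details Snowfall and heavy precipitation are separated: by default a
#' snowfall day suppresses the heavy-precipitation flag
#' (`snow_suppresses_precip = TRUE`), so melted snow is not double-counted
#' as heavy rain.
#'
#' @param weather Daily weather tibble: `county_id`, `date`, `temp_c`,
#'   `precip_mm`, `snowfall_cm`, `lightning_flash`, `cyclone_distance_km`,
#'   `wildfire_area_km2`.
#' @param baseline_temp County-week percentiles: `county_id`, `week`,
#'   `temp_p85_c`, `temp_p15_c`.
#' @param baseline_precip County percentiles: `county_id`, `precip_p85_mm`.
#' @param snow_suppresses_precip Precedence rule toggle.
#' @return Tibble: `county_id`, `date`, seven logical flags, `n_types`,
#'   `category` (`"none"`/`"isolated"`/`"multiple"`), `category_label`.
#'   County-days with no matching baseline are dropped with a warning.
#' @export
classify_county_day <- function(weather, baseline_temp, baseline_precip,
                                snow_suppresses_precip = TRUE) {
  check_columns(weather, c("county_id", "date", "temp_c", "precip_mm",
                           "snowfall_cm", "lightning_flash",
                           "cyclone_distance_km", "wildfire_area_km2"),
                "weather")
  check_columns(baseline_temp, c("county_id", "week", "temp_p85_c", "temp_p15_c"),
                "baseline_temp")
  check_columns(baseline_precip, c("county_id", "precip_p85_mm"), "baseline_precip")
  df <- weather %>%
    mutate(week = week_of_year(.data$date)) %>%
    left_join(baseline_temp, by = c("county_id", "week")) %>%
    left_join(baseline_precip, by = "county_id")
  missing <- is.na(df$temp_p85_c) | is.na(df$precip_p85_mm)
  if (any(missing)) {
    warn(sprintf("%d county-day(s) lack a climatology baseline and were excluded.",
                 sum(missing)))
    df <- df[!missing, , drop = FALSE]
  }
  df <- df %>%
    mutate(
      heat = .data$temp_c > 24 & .data$temp_c > .data$temp_p85_c,
      cold = .data$temp_c < 0 & .data$temp_c < .data$temp_p15_c,
      snow = .data$snowfall_cm >= 2.54,
      precip = .data$precip_mm > .data$precip_p85_mm &
        !(snow_suppresses_precip & .data$snowfall_cm >= 2.54),
      lightning = as.logical(.data$lightning_flash),
      cyclone = .data$cyclone_distance_km <= 100,
      wildfire = .data$wildfire_area_km2 >= 1
    )
  finish_classification(df %>% select("county_id", "date",
                                      dplyr::all_of(WEATHER_TYPES)))
}

#' Categorise a flag calendar into none / isolated / multiple county-days
#'
#' Adds `n_types`, `category`, and the canonical `category_label` to a
#' county-day calendar that already carries the seven event flags (for
#' example one produced by [generate_weather_calendar()]).
#'
#' @param calendar Tibble with `county_id`, `date` and logical columns
#'   `precip`, `snow`, `heat`, `cold`, `wildfire`, `lightning`, `cyclone`.
#' @return The calendar with classification columns appended.
#' @export
categorize_calendar <- function(calendar) {
  check_columns(calendar, c("county_id", "date", WEATHER_TYPES), "calendar")
  finish_classification(calendar)
}

finish_classification <- function(df) {
  fm <- as.matrix(df[WEATHER_TYPES])
  mode(fm) <- "logical"
  n_types <- rowSums(fm)
  df %>%
    mutate(
      n_types = as.integer(n_types),
      category = dplyr::case_when(
        n_types == 0 ~ "none",
        n_types == 1 ~ "isolated",
        TRUE ~ "multiple"
      ),
      category_label = combo_label(fm)
    )
}

#' Mark county-days on which an 8+ hour outage began
#'
#' Sets `outage_start = TRUE` on each classified county-day where at least
#' one event of `min_duration` hours or longer *began* (local start date);
#' several same-day starts count once. Events in counties absent from the
#' calendar are dropped with a warning.
#'
#' @param classes Classified county-day tibble (see [classify_county_day()]
#'   or [categorize_calendar()]).
#' @param events Detected or planted event tibble with `county_id`,
#'   `start_hour` or `start_time` (local), `duration_hours`.
#' @param min_duration Hours; default 8.
#' @return `classes` with an `outage_start` logical column.
#' @export
align_outage_days <- function(classes, events, min_duration = 8L) {
  check_columns(classes, c("county_id", "date"), "classes")
  start_col <- if ("start_hour" %in% names(events)) "start_hour" else "start_time"
  check_columns(events, c("county_id", start_col, "duration_hours"), "events")
  long <- events %>%
    filter(.data$duration_hours >= min_duration) %>%
    mutate(date = utc_date(.data[[start_col]])) %>%
    distinct(.data$county_id, .data$date)
  orphan <- long %>% anti_join(classes, by = c("county_id", "date"))
  if (nrow(orphan)) {
    warn(sprintf("%d outage start day(s) fall outside the classified calendar and were ignored.",
                 nrow(orphan)))
  }
  classes %>%
    left_join(long %>% mutate(outage_start = TRUE), by = c("county_id", "date")) %>%
    mutate(outage_start = dplyr::coalesce(.data$outage_start, FALSE))
}

#' Co-occurrence ratio of an event category with 8+ hour outages
#'
#' The proportion of county-days of event category *i* on which an 8+ hour
#' outage began, divided by the same proportion among county-days with no
#' severe weather or climate event:
#' `(n_outage_i / n_days_i) / (n_outage_none / n_days_none)`. A ratio above
#' 1 means outages are more likely on category-*i* days than on no-event
#' days. Zero denominators yield `NA` (undefined, distinct from 0) with a
#' warning.
#'
#' @param n_outage_i,n_days_i Outage-start county-days and total county-days
#'   in category *i* (vectorised).
#' @param n_outage_none,n_days_none The same counts for no-event days.
#' @return Numeric ratio(s).
#' @examples
#' co_occurrence_ratio(11310, 492489, 8637, 1265213)  # ~3.4
#' @export
co_occurrence_ratio <- function(n_outage_i, n_days_i, n_outage_none, n_days_none) {
  undefined <- n_days_i <= 0 | n_days_none <= 0 | n_outage_none <= 0
  if (any(undefined)) {
    warn("co-occurrence ratio undefined for zero denominators; returning NA.")
  }
  out <- (n_outage_i / n_days_i) / (n_outage_none / n_days_none)
  out[undefined] <- NA_real_
  out
}

#' Build the county-day co-occurrence table
#'
#' Tabulates county-days and outage-start county-days by event category:
#' a `Total` row, `None`, an `Isolated event` aggregate with one row per
#' isolated type, and a `Multiple event` aggregate with the top
#' `other_rank` combinations (by outage county-days) plus an `Other`
#' remainder. Co-occurrence ratios are computed against the `None` row.
#'
#' @param classes Classified, outage-aligned county-day tibble (needs
#'   `category`, `category_label`, `outage_start`).
#' @param other_rank Number of multiple-event combinations shown before
#'   grouping the rest into `Other`; default 7.
#' @return A tibble of class `"cooccurrence_table"`: `category`, `group`,
#'   `n_county_days`, `pct_county_days`, `n_outage_days`, `pct_outage_days`,
#'   `ratio`.
#' @export
build_cooccurrence_table <- function(classes, other_rank = 7L) {
  check_columns(classes, c("category", "category_label", "outage_start"),
                "classes")
  total_days <- nrow(classes)
  total_outage <- sum(classes$outage_start)
  none_days <- sum(classes$category == "none")
  none_outage <- sum(classes$outage_start[classes$category == "none"])

  iso <- classes %>%
    filter(.data$category == "isolated") %>%
    group_by(category = .data$category_label) %>%
    summarise(n_county_days = dplyr::n(), n_outage_days = sum(.data$outage_start),
              .groups = "drop") %>%
    arrange(dplyr::desc(.data$n_outage_days)) %>%
    mutate(group = "isolated")
  mult <- classes %>%
    filter(.data$category == "multiple") %>%
    group_by(category = .data$category_label) %>%
    summarise(n_county_days = dplyr::n(), n_outage_days = sum(.data$outage_start),
              .groups = "drop") %>%
    arrange(dplyr::desc(.data$n_outage_days))
  top <- head(mult, other_rank) %>% mutate(group = "multiple")
  other <- mult %>%
    dplyr::slice(-seq_len(min(other_rank, nrow(mult)))) %>%
    summarise(category = "Other", n_county_days = sum(.data$n_county_days),
              n_outage_days = sum(.data$n_outage_days)) %>%
    mutate(group = "multiple") %>%
    filter(.data$n_county_days > 0)

  rows <- bind_rows(
    tibble(category = "Total", group = "total", n_county_days = total_days,
           n_outage_days = total_outage),
    tibble(category = "None", group = "none", n_county_days = none_days,
           n_outage_days = none_outage),
    tibble(category = "Isolated event", group = "isolated_total",
           n_county_days = sum(iso$n_county_days),
           n_outage_days = sum(iso$n_outage_days)),
    iso,
    tibble(category = "Multiple event", group = "multiple_total",
           n_county_days = sum(mult$n_county_days),
           n_outage_days = sum(mult$n_outage_days)),
    top, other
  )
  rows <- rows %>%
    mutate(
      pct_county_days = 100 * .data$n_county_days / total_days,
      pct_outage_days = if (total_outage > 0) {
        100 * .data$n_outage_days / total_outage
      } else {
        NA_real_
      },
      # empty aggregate rows (e.g. no multiple-event days at all) have an
      # undefined ratio; leave NA without invoking the op's warning
      ratio = dplyr::if_else(
        .data$group %in% c("total", "none") | .data$n_county_days == 0 |
          none_days == 0 | none_outage == 0,
        NA_real_,
        suppressWarnings(
          co_occurrence_ratio(.data$n_outage_days, .data$n_county_days,
                              none_outage, none_days)
        )
      )
    ) %>%
    select("category", "group", "n_county_days", "pct_county_days",
           "n_outage_days", "pct_outage_days", "ratio")
  structure(rows, class = c("cooccurrence_table", class(tibble())))
}

#' Monthly composition of events on outage county-days
#'
#' For county-days on which an 8+ hour outage began, tabulates per-month
#' counts and within-month proportions of event categories, separately for
#' isolated-event and multiple-event days. Months with no outage county-days
#' in a panel are absent from that panel.
#'
#' @param classes Classified, outage-aligned county-day tibble.
#' @return Tibble: `panel` (`"isolated"`/`"multiple"`), `month`, `category`,
#'   `n`, `prop` (proportions sum to 1 within each panel-month).
#' @export
monthly_event_composition <- function(classes) {
  check_columns(classes, c("date", "category", "category_label", "outage_start"),
                "classes")
  classes %>%
    filter(.data$outage_start, .data$category %in% c("isolated", "multiple")) %>%
    mutate(month = as.integer(format(.data$date, "%m"))) %>%
    count(panel = .data$category, .data$month, category = .data$category_label) %>%
    group_by(.data$panel, .data$month) %>%
    mutate(prop = .data$n / sum(.data$n)) %>%
    ungroup() %>%
    arrange(.data$panel, .data$month, dplyr::desc(.data$n))
}

#' Reference county-day co-occurrence counts
#'
#' A published national 2018-2020 tabulation of continental U.S. county-days
#' (1653 counties with three reliable feed-years) by severe weather/climate
#' event category, with the number of those county-days on which an 8+ hour
#' outage began. Used in examples, validation tests, and the acceptance
#' script as a worked input for [co_occurrence_ratio()].
#'
#' @return Tibble: `category`, `group`, `n_county_days`, `n_outage_days`.
#' @export
reference_cooccurrence_counts <- function() {
  tibble::tribble(
    ~category,                                       ~group,           ~n_county_days, ~n_outage_days,
    "Total",                                         "total",          1799319L,       22793L,
    "None",                                          "none",           1265213L,       8637L,
    "Isolated event",                                "isolated_total", 492489L,        11310L,
    "Heavy precipitation",                           "isolated",       267823L,        8507L,
    "Snowfall",                                      "isolated",       25523L,         1172L,
    "Anomalous heat",                                "isolated",       131727L,        1090L,
    "Anomalous cold",                                "isolated",       57924L,         344L,
    "Wildfire",                                      "isolated",       5381L,          84L,
    "Lightning",                                     "isolated",       3578L,          63L,
    "Tropical cyclone",                              "isolated",       533L,           50L,
    "Multiple event",                                "multiple_total", 41617L,         2846L,
    "Heavy precipitation-anomalous heat",            "multiple",       17415L,         917L,
    "Heavy precipitation-tropical cyclone",          "multiple",       2650L,          679L,
    "Heavy precipitation-lightning",                 "multiple",       8142L,          644L,
    "Snowfall-anomalous cold",                       "multiple",       7151L,          250L,
    "Heavy precipitation-anomalous cold",            "multiple",       1779L,          134L,
    "Heavy precipitation-anomalous heat-tropical cyclone", "multiple", 244L,           86L,
    "Heavy precipitation-anomalous heat-lightning",  "multiple",       1197L,          78L,
    "Other",                                         "multiple",       3039L,          58L
  )
}

#' Attach co-occurrence ratios to a counts table
#'
#' Convenience wrapper: given a table of category counts (such as
#' [reference_cooccurrence_counts()]), computes each row's co-occurrence
#' ratio against the `none` row.
#'
#' @param counts Tibble with `category`, `group`, `n_county_days`,
#'   `n_outage_days`.
#' @return The input with a `ratio` column (`NA` for the total and none rows).
#' @export
add_cooccurrence_ratios <- function(counts) {
  check_columns(counts, c("group", "n_county_days", "n_outage_days"), "counts")
  none <- counts %>% filter(.data$group == "none")
  if (nrow(none) != 1) stop_bad_arg("`counts` must contain exactly one none row.")
  counts %>%
    mutate(ratio = dplyr::if_else(
      .data$group %in% c("total", "none"),
      NA_real_,
      co_occurrence_ratio(.data$n_outage_days, .data$n_county_days,
                          none$n_outage_days, none$n_county_days)
    ))
}
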