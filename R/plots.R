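# ggplot2 visual summaries for the main result types.

#' Contour-style plot of 8+ hour outage start times by month
#'
#' @param start_table Tibble from [tabulate_start_times()].
#' @return A ggplot object (month on x, local start hour on y, fill = count).
#' @export
plot_start_times <- function(start_table) {
  check_columns(start_table, c("month", "hour", "n"), "start_table")
  ggplot2::ggplot(start_table,
                  ggplot2::aes(x = factor(.data$month), y = .data$hour,
                               fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "events") +
    ggplot2::scale_y_continuous(breaks = seq(0, 23, 3)) +
    ggplot2::labs(x = "start month", y = "local start hour",
                  title = "8+ hour outage onsets by month and hour") +
    ggplot2::theme_minimal()
}

#' Monthly composition of weather events on outage county-days
#'
#' @param composition Tibble from [monthly_event_composition()].
#' @return A ggplot object: stacked within-month proportions, one facet per
#'   panel (isolated / multiple).
#' @export
plot_monthly_composition <- function(composition) {
  check_columns(composition, c("panel", "month", "category", "prop"),
                "composition")
  ggplot2::ggplot(composition,
                  ggplot2::aes(x = factor(.data$month), y = .data$prop,
                               fill = .data$category)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~panel, ncol = 1) +
    ggplot2::labs(x = "month", y = "share of outage county-days",
                  fill = "event type") +
    ggplot2::theme_minimal()
}

#' @describeIn build_cooccurrence_table Bar chart of co-occurrence ratios
#'   per category (aggregate and total rows omitted).
#' @param object,x A `cooccurrence_table`.
#' @param ... Unused.
#' @export
autoplot.cooccurrence_table <- function(object, ...) {
  df <- object %>%
    filter(!.data$group %in% c("total", "none"), !is.na(.data$ratio))
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$category, .data$ratio),
                                   y = .data$ratio, fill = .data$group)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "co-occurrence ratio (vs. no-event days)") +
    ggplot2::theme_minimal()
}

#' Lattice map of LISA cluster labels
#'
#' @param object A `lisa_result` (after [fdr_classify_clusters()]).
#' @param registry County registry supplying `grid_row`/`grid_col`.
#' @param ... Unused.
#' @return A ggplot tile map of cluster labels.
#' @export
autoplot.lisa_result <- function(object, registry, ...) {
  check_columns(registry, c("county_id", "grid_row", "grid_col"), "registry")
  lab_col <- if ("cluster_label" %in% names(object)) "cluster_label" else "quadrant"
  df <- as_tibble(object) %>%
    inner_join(registry %>% select("county_id", "grid_row", "grid_col"),
               by = "county_id")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$grid_col, y = .data$grid_row,
                                   fill = .data[[lab_col]])) +
    ggplot2::geom_tile(color = "grey80") +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_manual(values = c(
      "high-high" = "#d7191c", "low-low" = "#2c7bb6", "high-low" = "#fdae61",
      "low-high" = "#abd9e9", "not-significant" = "grey90"
    ), name = NULL) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
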