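# Synthetic social (SVI) and medical (DME) vulnerability surfaces with an
# optional planted high-vulnerability cluster co-located with elevated
# outage rates, so spatial clustering methods can be validated against
# known membership.

SVI_COMPONENTS <- c(
  "pct_below_poverty", "pct_unemployed", "pct_housing_cost_burden",
  "pct_no_hs_diploma", "pct_uninsured", "pct_age_65_plus",
  "pct_age_17_minus", "pct_disability", "pct_single_parent",
  "pct_limited_english", "pct_minority", "pct_multi_unit",
  "pct_mobile_homes", "pct_crowding", "pct_no_vehicle", "pct_group_quarters"
)

#' Generate a synthetic vulnerability surface with a planted cluster
#'
#' Produces a county table with an SVI-style overall percentile rank in
#' `[0, 1]`, sixteen named component percentages, and durable medical
#' equipment (DME) users per 1000 Medicare enrollees. Counties inside the
#' optional cluster region receive shifted SVI/DME values plus an
#' `outage_rate_multiplier` (consumed by [plant_outage_events()]), planting
#' a dual-burden region; membership is recorded in the returned truth.
#'
#' @inheritParams plant_outage_events
#' @param cluster_rows,cluster_cols Integer vectors of lattice rows/columns
#'   defining the planted cluster region; `NULL` plants no cluster.
#' @param svi_shift Additive shift to the SVI rank inside the cluster
#'   (clamped to `[0, 1]`); also shifts the poverty, minority, and
#'   mobile-home components upward.
#' @param dme_shift Additive shift (per 1000) to DME prevalence inside the
#'   cluster (clamped to `[0, 1000]`).
#' @param outage_rate_multiplier Multiplier on the daily outage-event rate
#'   inside the cluster.
#' @return A list of class `"vulnerability_sim"` with `vulnerability` (tibble:
#'   `county_id`, `svi`, 16 components, `dme_per_1000`,
#'   `outage_rate_multiplier`) and `truth` (cluster member ids and shifts).
#' @export
generate_vulnerability_surface <- function(registry,
                                           cluster_rows = NULL,
                                           cluster_cols = NULL,
                                           svi_shift = 0,
                                           dme_shift = 0,
                                           outage_rate_multiplier = 1,
                                           seed = 1L) {
  check_columns(registry, c("county_id", "grid_row", "grid_col"), "registry")
  has_cluster <- !is.null(cluster_rows) && !is.null(cluster_cols)
  if (has_cluster &&
      (any(!cluster_rows %in% registry$grid_row) ||
       any(!cluster_cols %in% registry$grid_col))) {
    stop_bad_arg("cluster region lies outside the registry lattice.")
  }
  n <- nrow(registry)
  with_seed(child_seed(seed, 5L), {
    in_cluster <- if (has_cluster) {
      registry$grid_row %in% cluster_rows & registry$grid_col %in% cluster_cols
    } else {
      rep(FALSE, n)
    }
    svi <- runif(n)
    svi[in_cluster] <- pmin(1, svi[in_cluster] + svi_shift)

    comp <- purrr::map(SVI_COMPONENTS, function(nm) {
      base <- 100 * stats::rbeta(n, 2, 8)   # typical component percentages
      if (nm %in% c("pct_below_poverty", "pct_minority", "pct_mobile_homes")) {
        base[in_cluster] <- pmin(100, base[in_cluster] + 100 * svi_shift * 0.4)
      }
      base
    })
    names(comp) <- SVI_COMPONENTS

    dme <- pmin(1000, pmax(0, rlnorm(n, meanlog = log(58), sdlog = 0.35)))
    dme[in_cluster] <- pmin(1000, dme[in_cluster] + dme_shift)

    vulnerability <- tibble(county_id = registry$county_id, svi = svi) %>%
      dplyr::bind_cols(as_tibble(comp)) %>%
      mutate(
        dme_per_1000 = dme,
        outage_rate_multiplier = ifelse(in_cluster, outage_rate_multiplier, 1)
      )
    structure(
      list(
        vulnerability = vulnerability,
        truth = list(
          vulnerability_cluster_counties = registry$county_id[in_cluster],
          svi_shift = svi_shift,
          dme_shift = dme_shift,
          outage_rate_multiplier = outage_rate_multiplier,
          seed = as.integer(seed)
        )
      ),
      class = "vulnerability_sim"
    )
  })
}
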