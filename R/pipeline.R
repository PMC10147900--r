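# End-to-end orchestration: simulate -> screen -> detect -> cooccur ->
# cluster, with per-stage structured logging and a reproducibility manifest.

#' Pipeline configuration
#'
#' Collects and validates every tunable of the end-to-end run. Defaults
#' mirror the published study design: a 0.1% customer threshold, 1+/8+ hour
#' duration classes, the full-span reliability tier for the weather
#' co-occurrence stage, the 2+ year tier for clustering, 99,999 LISA
#' permutations, and alpha = 0.05 with BH FDR control.
#'
#' @param out_dir Output directory for stage artifacts.
#' @param n_rows,n_cols Synthetic lattice dimensions.
#' @param span_start,span_end Simulated span (local dates).
#' @param daily_event_rate Baseline daily outage-event start probability.
#' @param gap_fraction Reporting gap fraction of 10-minute slots.
#' @param base_rates Daily marginal rates of the seven weather event types.
#' @param coupling Named relative risks coupling weather to outage starts.
#' @param threshold Outage threshold as a fraction of county customers.
#' @param min_durations Event duration classes in hours.
#' @param other_rank Multiple-event combinations kept before "Other".
#' @param cooccur_tier,cluster_tier Reliability tier used by each stage
#'   (`"1plus"`, `"2plus"`, or `"full"`).
#' @param permutations LISA conditional permutations.
#' @param alpha Cluster significance level.
#' @param seed Master seed; every stage derives its own substream from it.
#' @return A validated list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(out_dir,
                            n_rows = 10L, n_cols = 10L,
                            span_start = "2018-01-01", span_end = "2020-12-31",
                            daily_event_rate = 0.02,
                            gap_fraction = 0.05,
                            base_rates = NULL,
                            coupling = NULL,
                            threshold = 0.001,
                            min_durations = c(1L, 8L),
                            other_rank = 7L,
                            cooccur_tier = "full",
                            cluster_tier = "2plus",
                            permutations = 99999L,
                            alpha = 0.05,
                            seed = 1L) {
  check_fraction(threshold, "threshold", lo = 1e-12, hi = 1 - 1e-12)
  check_fraction(alpha, "alpha", lo = 1e-12, hi = 1)
  check_fraction(gap_fraction, "gap_fraction")
  stopifnot(cooccur_tier %in% c("1plus", "2plus", "full"),
            cluster_tier %in% c("1plus", "2plus", "full"))
  cfg <- list(
    out_dir = out_dir, n_rows = n_rows, n_cols = n_cols,
    span_start = as.Date(span_start), span_end = as.Date(span_end),
    daily_event_rate = daily_event_rate, gap_fraction = gap_fraction,
    base_rates = base_rates, coupling = coupling, threshold = threshold,
    min_durations = sort(as.integer(min_durations)), other_rank = other_rank,
    cooccur_tier = cooccur_tier, cluster_tier = cluster_tier,
    permutations = as.integer(permutations), alpha = alpha,
    seed = as.integer(seed)
  )
  structure(cfg, class = "pipeline_config")
}

tier_column <- function(tier) {
  c("1plus" = "tier_1plus", "2plus" = "tier_2plus", "full" = "tier_full")[[tier]]
}

stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the full synthetic outage-exposure pipeline
#'
#' Orchestrates simulate -> screen -> detect -> cooccur -> cluster on a
#' synthetic lattice world, writes every stage artifact as CSV plus a truth
#' JSON and a run manifest (config, seed, row counts per artifact), and
#' returns the in-memory bundle. Re-running with an identical config
#' reproduces identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress per-stage log lines.
#' @return Invisible list with all stage outputs (`registry`, `streams`,
#'   `assessments`, `tiers`, `hourly`, `events`, `per_year`, `annual`,
#'   `classes`, `cooccurrence`, `lisa_svi`, `lisa_dme`, `truth`,
#'   `manifest`).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  log_fn <- if (quiet) function(...) invisible() else stage_log
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed

  # --- simulate ------------------------------------------------------------
  registry <- generate_registry(config$n_rows, config$n_cols, seed = seed)
  weather <- generate_weather_calendar(
    registry, config$span_start, config$span_end,
    base_rates = config$base_rates %||% eval(formals(generate_weather_calendar)$base_rates),
    seed = seed
  )
  vuln <- generate_vulnerability_surface(registry, seed = seed)
  reg_sim <- registry %>%
    left_join(vuln$vulnerability %>%
                select("county_id", "outage_rate_multiplier"),
              by = "county_id")
  sim <- generate_outage_streams(
    reg_sim, config$span_start, config$span_end,
    daily_event_rate = config$daily_event_rate,
    calendar = weather$calendar, coupling = config$coupling,
    gap_fraction = config$gap_fraction, seed = seed
  )
  log_fn("simulate", "%d counties, %d stream rows, %d planted events",
         nrow(registry), nrow(sim$streams), nrow(sim$events))

  # --- screen --------------------------------------------------------------
  assessments <- assess_reliability(sim$streams, registry)
  tiers <- assign_tiers(assessments,
                        n_years_full = length(unique(assessments$year)))
  reliable <- reliable_county_years(assessments)
  log_fn("screen", "%d/%d county-years reliable; tiers 1+/2+/full = %d/%d/%d",
         nrow(reliable), nrow(assessments), sum(tiers$tier_1plus),
         sum(tiers$tier_2plus), sum(tiers$tier_full))

  # --- detect --------------------------------------------------------------
  hourly <- aggregate_to_hourly(sim$streams, registry)
  events <- detect_outage_events(hourly, registry, threshold = config$threshold)
  per_year <- summarize_events(events, reliable = reliable,
                               min_durations = config$min_durations)
  annual <- annualize_exposure(per_year, reliable)
  log_fn("detect", "%d events detected across %d counties",
         nrow(events), dplyr::n_distinct(events$county_id))

  # --- cooccur -------------------------------------------------------------
  tier_ids <- tiers$county_id[tiers[[tier_column(config$cooccur_tier)]]]
  classes <- categorize_calendar(weather$calendar) %>%
    filter(.data$county_id %in% tier_ids) %>%
    align_outage_days(events, min_duration = 8L)
  cooccurrence <- build_cooccurrence_table(classes, other_rank = config$other_rank)
  log_fn("cooccur", "%d county-days classified in tier '%s'; %d outage county-days",
         nrow(classes), config$cooccur_tier, sum(classes$outage_start))

  # --- cluster -------------------------------------------------------------
  cluster_ids <- tiers$county_id[tiers[[tier_column(config$cluster_tier)]]]
  adjacency <- lattice_adjacency(registry, scheme = "queen") %>%
    filter(.data$county_id %in% cluster_ids, .data$neighbor_id %in% cluster_ids)
  lisa_svi <- lisa_dme <- NULL
  if (nrow(adjacency)) {
    weights <- build_spatial_weights(adjacency, ids = cluster_ids)
    keep <- setdiff(weights$ids, weights$islands)
    cl_data <- annual %>%
      inner_join(vuln$vulnerability, by = "county_id") %>%
      filter(.data$county_id %in% keep)
    outage_col <- paste0("avg_n_events_", max(config$min_durations), "h")
    lisa_svi <- bivariate_local_moran(cl_data, "svi", outage_col, weights,
                                      n_permutations = config$permutations,
                                      seed = seed) %>%
      fdr_classify_clusters(alpha = config$alpha)
    lisa_dme <- bivariate_local_moran(cl_data, "dme_per_1000", outage_col,
                                      weights,
                                      n_permutations = config$permutations,
                                      seed = seed + 1L) %>%
      fdr_classify_clusters(alpha = config$alpha)
    log_fn("cluster", "SVI high-high: %d; DME high-high: %d",
           sum(lisa_svi$cluster_label == "high-high"),
           sum(lisa_dme$cluster_label == "high-high"))
  }

  # --- write artifacts -----------------------------------------------------
  files <- c(
    registry = "registry.csv", stream = "streams.csv", calendar = "calendar.csv",
    vulnerability = "vulnerability.csv", assessment = "assessments.csv",
    tiers = "tiers.csv", events = "events.csv",
    cooccurrence = "cooccurrence.csv", lisa_svi = "lisa_svi.csv",
    lisa_dme = "lisa_dme.csv", truth = "truth.json", manifest = "manifest.json"
  )
  paths <- setNames(file.path(config$out_dir, files), names(files))
  write_table(registry, "registry", paths[["registry"]])
  write_table(sim$streams, "stream", paths[["stream"]])
  write_table(weather$calendar, "calendar", paths[["calendar"]])
  write_table(vuln$vulnerability, "vulnerability", paths[["vulnerability"]])
  write_table(assessments, "assessment", paths[["assessment"]])
  write_table(tiers, "tiers", paths[["tiers"]])
  write_table(events, "events", paths[["events"]])
  readr::write_csv(cooccurrence, paths[["cooccurrence"]])
  if (!is.null(lisa_svi)) {
    write_table(as_tibble(lisa_svi), "lisa", paths[["lisa_svi"]])
    write_table(as_tibble(lisa_dme), "lisa", paths[["lisa_dme"]])
  }
  truth <- c(sim$truth,
             list(planted_events = sim$events, vulnerability = vuln$truth))
  write_truth_json(truth, paths[["truth"]])

  artifacts <- paths[file.exists(paths)]
  manifest <- list(
    seed = seed,
    config = config[setdiff(names(config), "out_dir")],
    config_hash = rlang::hash(config[setdiff(names(config), "out_dir")]),
    rows = list(
      registry = nrow(registry), streams = nrow(sim$streams),
      assessments = nrow(assessments), tiers = nrow(tiers),
      events = nrow(events), classes = nrow(classes),
      cooccurrence = nrow(cooccurrence),
      lisa = if (is.null(lisa_svi)) 0L else nrow(lisa_svi)
    )
  )
  write_truth_json(manifest, paths[["manifest"]])

  invisible(list(
    registry = registry, streams = sim$streams, truth = truth,
    events_planted = sim$events, weather = weather,
    vulnerability = vuln$vulnerability, assessments = assessments,
    tiers = tiers, hourly = hourly, events = events, per_year = per_year,
    annual = annual, classes = classes, cooccurrence = cooccurrence,
    lisa_svi = lisa_svi, lisa_dme = lisa_dme, manifest = manifest
  ))
}
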