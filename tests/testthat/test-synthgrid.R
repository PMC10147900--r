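# Synthetic world generators: lattice combinatorics, ground-truth recording,
# marginal calibration, and seed reproducibility.

test_that("degenerate 1x1 lattice has one county and no neighbors", {
  reg <- generate_registry(1, 1, customer_range = c(100, 100), seed = 5)
  expect_equal(nrow(reg), 1L)
  expect_equal(reg$customers_total, 100L)
  expect_equal(reg$customers_total, reg$households + reg$businesses)
  expect_equal(nrow(lattice_adjacency(reg, "queen")), 0L)
})

test_that("2x2 lattice: 2 rook and 3 queen neighbors each", {
  reg <- generate_registry(2, 2, customer_range = c(1000, 1000), seed = 5)
  rook <- lattice_adjacency(reg, "rook")
  queen <- lattice_adjacency(reg, "queen")
  expect_equal(unname(table(rook$county_id)), rep(2L, 4), ignore_attr = TRUE)
  expect_equal(unname(table(queen$county_id)), rep(3L, 4), ignore_attr = TRUE)
})

test_that("lattice adjacency matches brute-force enumeration", {
  reg <- generate_registry(3, 4, seed = 2)
  for (scheme in c("queen", "rook")) {
    adj <- lattice_adjacency(reg, scheme)
    # independent O(n^2) oracle over all county pairs
    expected <- list()
    for (i in seq_len(nrow(reg))) {
      for (j in seq_len(nrow(reg))) {
        if (i == j) next
        dr <- abs(reg$grid_row[i] - reg$grid_row[j])
        dc <- abs(reg$grid_col[i] - reg$grid_col[j])
        hit <- if (scheme == "rook") dr + dc == 1 else max(dr, dc) == 1
        if (hit) expected[[length(expected) + 1]] <-
            c(reg$county_id[i], reg$county_id[j])
      }
    }
    oracle <- do.call(rbind, expected)
    expect_setequal(paste(adj$county_id, adj$neighbor_id),
                    paste(oracle[, 1], oracle[, 2]))
  }
  # 3x3 center county has 8 queen neighbors
  reg3 <- generate_registry(3, 3, seed = 2)
  center <- reg3$county_id[reg3$grid_row == 2 & reg3$grid_col == 2]
  queen <- lattice_adjacency(reg3, "queen")
  expect_equal(sum(queen$county_id == center), 8L)
})

test_that("registry invariants hold and bad dimensions error", {
  reg <- generate_registry(4, 5, seed = 9)
  expect_equal(reg$customers_total, reg$households + reg$businesses)
  expect_false(anyDuplicated(reg$county_id) > 0)
  expect_false(anyDuplicated(reg[c("grid_row", "grid_col")]) > 0)
  expect_true(all(reg$households >= 0 & reg$businesses >= 0))
  expect_error(generate_registry(0, 3), class = "outagegrid_invalid_argument")
})

test_that("generators are bit-reproducible under a fixed seed", {
  reg1 <- generate_registry(3, 3, seed = 42)
  reg2 <- generate_registry(3, 3, seed = 42)
  expect_identical(reg1, reg2)
  s1 <- generate_outage_streams(reg1, "2019-01-01", "2019-01-31",
                                daily_event_rate = 0.1, gap_fraction = 0.2,
                                seed = 42)
  s2 <- generate_outage_streams(reg1, "2019-01-01", "2019-01-31",
                                daily_event_rate = 0.1, gap_fraction = 0.2,
                                seed = 42)
  expect_identical(s1$streams, s2$streams)
  expect_identical(s1$events, s2$events)
  s3 <- generate_outage_streams(reg1, "2019-01-01", "2019-01-31",
                                daily_event_rate = 0.1, seed = 43)
  expect_false(identical(s1$streams, s3$streams))
  w1 <- generate_weather_calendar(reg1, "2019-01-01", "2019-03-31", seed = 42)
  w2 <- generate_weather_calendar(reg1, "2019-01-01", "2019-03-31", seed = 42)
  expect_identical(w1$calendar, w2$calendar)
  expect_identical(w1$weather, w2$weather)
})

test_that("a single planted event materialises as exactly its above-threshold run", {
  reg <- one_county_registry(100000L)
  planted <- make_planted("01001", "2019-03-10 06:00", 9L, peak_fraction_out = 0.01)
  sim <- generate_outage_streams(reg, "2019-03-01", "2019-03-20",
                                 gap_fraction = 0, seed = 1, planted = planted)
  frac <- sim$streams$customers_out / reg$customers_total
  above <- frac >= 0.001
  runs <- enumerate_runs(above)
  expect_equal(length(runs$starts), 1L)
  expect_equal(runs$lengths, 9L * 6L)  # 9 hours of 10-minute slots
  expect_equal(sim$streams$timestamp[runs$starts],
               as.POSIXct("2019-03-10 06:00", tz = "UTC"))
})

test_that("zero event rate keeps every reading below the outage threshold", {
  reg <- one_county_registry(50000L)
  sim <- generate_outage_streams(reg, "2019-01-01", "2019-01-31",
                                 daily_event_rate = 0, seed = 3)
  expect_true(all(sim$streams$customers_out / reg$customers_total < 0.001))
  expect_equal(nrow(sim$events), 0L)
})

test_that("planted event count is within 4 SD of the Poisson expectation", {
  reg <- generate_registry(5, 10, seed = 7)
  rate <- 0.02
  n_days <- as.integer(as.Date("2019-06-29") - as.Date("2019-01-01")) + 1L
  pl <- plant_outage_events(reg, "2019-01-01", "2019-06-29",
                            daily_event_rate = rate, seed = 7)
  n_raw <- sum(pl$events$merged_from)   # raw Bernoulli successes pre-merge
  mu <- nrow(reg) * n_days * rate
  sd <- sqrt(mu * (1 - rate))
  expect_lt(abs(n_raw - mu), 4 * sd)
})

test_that("overlapping planted events are merged and recorded", {
  reg <- one_county_registry()
  ev <- tibble::tibble(
    county_id = "01001", date = as.Date("2019-01-01") + c(0, 0),
    onset_hour = c(6L, 10L), duration_hours = c(8L, 4L),
    peak_fraction_out = c(0.01, 0.02),
    start_time = as.POSIXct("2019-01-01", tz = "UTC") + c(6, 10) * 3600
  )
  merged <- outagegrid:::merge_overlapping_events(ev)
  expect_equal(nrow(merged$events), 1L)
  expect_equal(merged$events$duration_hours, 8L)  # 06:00-14:00
  expect_equal(merged$events$peak_fraction_out, 0.02)
  expect_equal(merged$events$merged_from, 2L)
  expect_equal(merged$n_merged, 1L)
})

test_that("reporting gaps drop the recorded number of slots", {
  reg <- one_county_registry()
  sim <- generate_outage_streams(reg, "2019-01-01", "2019-01-10",
                                 daily_event_rate = 0, gap_fraction = 0.4,
                                 seed = 11)
  n_expected <- sim$truth$n_slots_expected
  expect_equal(nrow(sim$streams),
               n_expected - unname(sim$truth$n_slots_dropped["01001"]))
  # iid drop rate within 4 SD of binomial expectation
  p <- 0.4
  expect_lt(abs(sim$truth$n_slots_dropped["01001"] - p * n_expected),
            4 * sqrt(n_expected * p * (1 - p)))
  # block mode also respects the budget roughly (overlaps allowed)
  simb <- generate_outage_streams(reg, "2019-01-01", "2019-01-10",
                                  daily_event_rate = 0, gap_fraction = 0.2,
                                  gap_mode = "block", seed = 11)
  expect_gt(unname(simb$truth$n_slots_dropped["01001"]), 0)
})

test_that("weather calendar: zero rates give all-none days; marginals calibrate", {
  reg <- generate_registry(3, 3, seed = 4)
  ws0 <- generate_weather_calendar(reg, "2019-01-01", "2019-01-31",
                                   base_rates = c(precip = 0), seed = 4)
  cls0 <- categorize_calendar(ws0$calendar)
  expect_true(all(cls0$category == "none"))

  rates <- c(precip = 0.2, snow = 0.05, heat = 0.1, cold = 0.05,
             wildfire = 0.01, lightning = 0.02, cyclone = 0.01)
  reg2 <- generate_registry(6, 6, seed = 4)
  ws <- generate_weather_calendar(reg2, "2018-01-01", "2019-12-31",
                                  base_rates = rates, seed = 4)
  n <- nrow(ws$calendar)
  for (ty in names(rates)) {
    k <- sum(ws$calendar[[ty]])
    expect_lt(abs(k - n * rates[[ty]]),
              4 * sqrt(n * rates[[ty]] * (1 - rates[[ty]])),
              label = sprintf("marginal calibration for %s", ty))
  }
})

test_that("classifier reproduces the generator's flags round-trip", {
  reg <- generate_registry(4, 4, seed = 8)
  ws <- generate_weather_calendar(reg, "2019-01-01", "2019-12-31", seed = 8)
  cls <- classify_county_day(ws$weather, ws$baseline_temp, ws$baseline_precip)
  merged <- dplyr::inner_join(
    ws$calendar, cls,
    by = c("county_id", "date"), suffix = c("_gen", "_cls")
  )
  expect_equal(nrow(merged), nrow(ws$calendar))
  for (ty in c("precip", "snow", "heat", "cold", "wildfire", "lightning",
               "cyclone")) {
    expect_equal(merged[[paste0(ty, "_cls")]], merged[[paste0(ty, "_gen")]],
                 label = sprintf("round-trip flag %s", ty))
  }
})

test_that("with neutral coupling, outage starts are independent of weather flags", {
  # chi-square on a large simulated panel should not reject at alpha = 0.01
  reg <- generate_registry(10, 10, seed = 21)
  ws <- generate_weather_calendar(reg, "2018-01-01", "2019-12-31",
                                  base_rates = c(precip = 0.2), seed = 21)
  pl <- plant_outage_events(reg, "2018-01-01", "2019-12-31",
                            daily_event_rate = 0.05,
                            calendar = ws$calendar,
                            coupling = c(precip = 1), seed = 21)
  starts <- unique(pl$events[c("county_id", "start_date")])
  names(starts)[2] <- "date"
  starts$started <- TRUE
  days <- dplyr::left_join(ws$calendar, starts, by = c("county_id", "date"))
  days$started <- !is.na(days$started)
  tab <- table(days$precip, days$started)
  p <- suppressWarnings(stats::chisq.test(tab)$p.value)
  expect_gt(p, 0.01)
})

test_that("vulnerability surface plants and records cluster membership", {
  reg <- generate_registry(6, 6, seed = 13)
  vs0 <- generate_vulnerability_surface(reg, seed = 13)
  expect_equal(length(vs0$truth$vulnerability_cluster_counties), 0L)
  expect_true(all(vs0$vulnerability$svi >= 0 & vs0$vulnerability$svi <= 1))
  expect_true(all(vs0$vulnerability$dme_per_1000 >= 0 &
                    vs0$vulnerability$dme_per_1000 <= 1000))

  vs <- generate_vulnerability_surface(reg, cluster_rows = 2:4,
                                       cluster_cols = 2:4, svi_shift = 0.4,
                                       dme_shift = 50,
                                       outage_rate_multiplier = 3, seed = 13)
  expect_equal(length(vs$truth$vulnerability_cluster_counties), 9L)
  inside <- vs$vulnerability$county_id %in% vs$truth$vulnerability_cluster_counties
  expect_true(all(vs$vulnerability$outage_rate_multiplier[inside] == 3))
  expect_true(all(vs$vulnerability$outage_rate_multiplier[!inside] == 1))
  expect_error(
    generate_vulnerability_surface(reg, cluster_rows = 10:12, cluster_cols = 1:2,
                                   svi_shift = 0.1),
    class = "outagegrid_invalid_argument"
  )
})
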