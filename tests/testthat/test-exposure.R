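# Exposure: hourly aggregation, threshold derivation, run detection against
# a brute-force oracle, and customer-hour metrics.

test_that("customer denominator is the sum of households and businesses", {
  expect_equal(estimate_customer_denominator(80000, 20000), 100000)
  expect_equal(estimate_customer_denominator(0, 0), 0)
  expect_equal(estimate_customer_denominator(12345, 0), 12345)
  expect_error(estimate_customer_denominator(-1, 5),
               class = "outagegrid_invalid_argument")
})

test_that("hourly aggregation computes within-hour max and mean", {
  reg <- one_county_registry(offset = 0L)
  t0 <- as.POSIXct("2019-06-01 05:00", tz = "UTC")
  s <- tibble::tibble(county_id = "01001", timestamp = t0 + (0:5) * 600,
                      customers_out = c(120, 120, 120, 120, 120, 120))
  h <- aggregate_to_hourly(s, reg)
  expect_equal(h$customers_out_max, 120)
  expect_equal(h$customers_out_mean, 120)

  s2 <- tibble::tibble(county_id = "01001", timestamp = t0 + (0:5) * 600,
                       customers_out = c(0, 0, 0, 600, 0, 0))
  h2 <- aggregate_to_hourly(s2, reg)
  expect_equal(h2$customers_out_max, 600)
  expect_equal(h2$customers_out_mean, 100)   # equal 10-minute weights

  # an hour with no readings appears as reported = FALSE on the grid
  s3 <- tibble::tibble(county_id = "01001",
                       timestamp = c(t0, t0 + 2 * 3600),
                       customers_out = c(10, 20))
  h3 <- aggregate_to_hourly(s3, reg)
  expect_equal(nrow(h3), 3L)
  expect_equal(h3$reported, c(TRUE, FALSE, TRUE))
  expect_error(
    aggregate_to_hourly(dplyr::mutate(s3, customers_out = c(-1, 5)), reg),
    class = "outagegrid_invalid_input"
  )
  # local clock shift follows the registry's UTC offset
  rego <- one_county_registry(offset = -6L)
  ho <- aggregate_to_hourly(s, rego)
  expect_equal(ho$hour_start, t0 - 6 * 3600)
})

test_that("threshold derivation follows the declared quantile convention", {
  reg <- one_county_registry(customers = 100000L)
  h <- hourly_from_fractions(rep(0.0005, 20))
  expect_equal(derive_threshold(h, reg), 0.0005)

  fr <- c(rep(0.0001, 9), 0.01)
  h2 <- hourly_from_fractions(fr)
  # sorted-list oracle for type-7 linear interpolation at p = 0.9
  srt <- sort(round(fr * 100000) / 100000)
  idx <- (length(srt) - 1) * 0.9 + 1
  oracle <- srt[floor(idx)] + (idx - floor(idx)) * (srt[ceiling(idx)] - srt[floor(idx)])
  expect_equal(derive_threshold(h2, reg, percentile = 90), oracle)
  expect_error(derive_threshold(h2[0, ], reg), class = "outagegrid_invalid_input")
})

test_that("detection respects the relative 0.1% threshold worked examples", {
  # 100,000 customers: 100 out qualifies
  regA <- one_county_registry(customers = 100000L)
  hA <- hourly_from_fractions(c(0, 100 / 100000, 0))
  evA <- detect_outage_events(hA, regA)
  expect_equal(nrow(evA), 1L)
  expect_equal(evA$duration_hours, 1L)
  # 1,000,000 customers: 999 out does not qualify
  regB <- one_county_registry(customers = 1000000L)
  hB <- hourly_from_fractions(c(0, 999 / 1e6, 0), customers = 1000000L)
  expect_equal(nrow(detect_outage_events(hB, regB)), 0L)
  hB2 <- hourly_from_fractions(c(0, 1000 / 1e6, 0), customers = 1000000L)
  expect_equal(nrow(detect_outage_events(hB2, regB)), 1L)
})

test_that("detected events equal brute-force maximal-run enumeration", {
  reg <- one_county_registry(customers = 1000L)
  set.seed(99)
  for (rep in 1:200) {
    above <- runif(30) < 0.4
    h <- hourly_from_fractions(ifelse(above, 0.01, 0), customers = 1000L)
    ev <- detect_outage_events(h, reg)
    oracle <- enumerate_runs(above)
    expect_equal(nrow(ev), length(oracle$starts))
    expect_equal(ev$duration_hours, oracle$lengths)
    expect_equal(as.numeric(ev$start_hour),
                 as.numeric(h$hour_start[oracle$starts]))
  }
})

test_that("an unreported hour terminates a run", {
  reg <- one_county_registry(customers = 1000L)
  h <- hourly_from_fractions(rep(0.01, 5), customers = 1000L,
                             reported = c(TRUE, TRUE, FALSE, TRUE, TRUE))
  ev <- detect_outage_events(h, reg)
  expect_equal(nrow(ev), 2L)
  expect_equal(ev$duration_hours, c(2L, 2L))
})

test_that("raising the threshold shrinks exposure monotonically", {
  # Note: a higher threshold can SPLIT one long run into several shorter
  # events, so the event COUNT is not monotone; what is monotone is the set
  # of above-threshold hours (nested), hence the total above-threshold
  # duration, and every high-threshold event is contained in exactly one
  # low-threshold event of at least its duration.
  reg <- one_county_registry(customers = 10000L)
  set.seed(5)
  fr <- runif(200, 0, 0.003)
  h <- hourly_from_fractions(fr, customers = 10000L)
  ev_lo <- detect_outage_events(h, reg, threshold = 0.001)
  ev_hi <- detect_outage_events(h, reg, threshold = 0.002)
  expect_lte(sum(ev_hi$duration_hours), sum(ev_lo$duration_hours))
  lo_start <- as.numeric(ev_lo$start_hour)
  lo_end <- lo_start + ev_lo$duration_hours * 3600
  for (i in seq_len(nrow(ev_hi))) {
    s <- as.numeric(ev_hi$start_hour[i])
    e <- s + ev_hi$duration_hours[i] * 3600
    container <- which(lo_start <= s & lo_end >= e)
    expect_length(container, 1)
    expect_lte(ev_hi$duration_hours[i], ev_lo$duration_hours[container])
  }
  # a threshold above every reading detects nothing
  expect_equal(nrow(detect_outage_events(h, reg, threshold = 0.004)), 0L)
})

test_that("event summaries count duration classes and annualize", {
  t0 <- as.POSIXct("2019-06-01 00:00", tz = "UTC")
  ev <- tibble::tibble(
    county_id = "01001",
    start_hour = t0 + c(0, 100, 200) * 3600,
    duration_hours = c(1L, 9L, 3L),
    peak_customers_out = 1L, event_customer_hours = c(10, 90, 30)
  )
  s <- summarize_events(ev)
  expect_equal(s$n_events_1h, 3L)
  expect_equal(s$n_events_8h, 1L)
  # annual average over two reliable years with totals (4, 2) -> 3
  rel <- tibble::tibble(county_id = "01001", year = c(2019L, 2020L))
  ev2 <- tibble::tibble(
    county_id = "01001",
    start_hour = c(t0 + (1:4) * 3600 * 24, t0 + 366 * 86400 + (1:2) * 86400),
    duration_hours = rep(2L, 6),
    peak_customers_out = 1L, event_customer_hours = 2
  )
  ann <- annualize_exposure(summarize_events(ev2, reliable = rel), rel)
  expect_equal(ann$avg_n_events_1h, 3)
  # events in unreliable years are excluded
  rel1 <- tibble::tibble(county_id = "01001", year = 2019L)
  s1 <- summarize_events(ev2, reliable = rel1)
  expect_equal(sum(s1$n_events_1h), 4L)
})

test_that("customer-hours integrate the hourly mean and divide by customers", {
  h <- hourly_from_fractions(c(100, 200, 0) / 1e5)
  ch <- compute_customer_hours(h)
  expect_equal(ch$customer_hours_total, 300)
  reg <- one_county_registry(customers = 10000L)
  ch2 <- tibble::tibble(county_id = "01001", year = 2019L,
                        customer_hours_total = 1e6)
  expect_equal(hours_per_customer(ch2, reg)$hours_per_customer, 100)

  # constant c for H hours equals c*H, cross-checked by 10-minute integration
  regc <- one_county_registry(customers = 100000L)
  t0 <- as.POSIXct("2019-02-01 00:00", tz = "UTC")
  H <- 7L; cc <- 250L
  s <- tibble::tibble(county_id = "01001",
                      timestamp = t0 + (seq_len(H * 6) - 1) * 600,
                      customers_out = cc)
  hh <- aggregate_to_hourly(s, regc)
  expect_equal(compute_customer_hours(hh)$customer_hours_total,
               sum(rep(cc, H * 6)) / 6)   # rectangle integration oracle
  expect_equal(compute_customer_hours(hh)$customer_hours_total, cc * H)
})

test_that("event customer-hours never exceed the total customer-hours", {
  reg <- generate_registry(3, 3, seed = 17)
  sim <- generate_outage_streams(reg, "2019-01-01", "2019-03-31",
                                 daily_event_rate = 0.1, seed = 17)
  h <- aggregate_to_hourly(sim$streams, reg)
  ev <- detect_outage_events(h, reg)
  tot <- compute_customer_hours(h)
  per <- summarize_events(ev)
  j <- dplyr::inner_join(per, tot, by = c("county_id", "year"))
  expect_true(all(j$event_customer_hours <= j$customer_hours_total + 1e-9))
})

test_that("start-time tabulation fills a 12x24 grid with correct marginals", {
  t0 <- as.POSIXct("2019-06-15 18:00", tz = "UTC")
  ev <- tibble::tibble(county_id = "01001", start_hour = t0,
                       duration_hours = 10L, peak_customers_out = 1L,
                       event_customer_hours = 1)
  tab <- tabulate_start_times(ev)
  expect_equal(dim(tab), c(288L, 3L))
  expect_equal(sum(tab$n), 1L)
  expect_equal(tab$n[tab$month == 6 & tab$hour == 18], 1L)
  empty <- tabulate_start_times(ev[0, ])
  expect_equal(sum(empty$n), 0L)
  # synthetic onsets centred at 18:00 put the mode at hour 18
  reg <- generate_registry(5, 5, seed = 23)
  pl <- plant_outage_events(reg, "2019-01-01", "2019-12-31",
                            daily_event_rate = 0.3, seed = 23)
  ev8 <- dplyr::rename(pl$events, start_hour = start_time)
  tab8 <- tabulate_start_times(ev8, min_duration = 8L)
  by_hour <- tapply(tab8$n, tab8$hour, sum)
  expect_equal(as.integer(names(which.max(by_hour))), 18L)
  expect_equal(sum(tab8$n), sum(pl$events$duration_hours >= 8))
})
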