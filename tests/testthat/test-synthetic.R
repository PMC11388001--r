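test_that("station generator is deterministic and respects its base climate", {
  s1 <- gen_station_series(3, seed = 42)
  s2 <- gen_station_series(3, seed = 42)
  expect_identical(s1, s2)
  expect_false(identical(s1, gen_station_series(3, seed = 43)))
  expect_true(all(diff(as.integer(s1$date)) == 1))
  expect_true(all(is.finite(s1$tmax_c)))
  # flat base climate: threshold tracks the stated mean
  flat <- gen_station_series(2, base_climate = list(annual_mean_tmax = 25.6,
                                                    seasonal_amplitude = 0,
                                                    noise_sd = 0.3),
                             seed = 1)
  expect_lt(abs(climatological_threshold(flat) - 25.6), 0.15)
})

test_that("embedded exceedance runs are planted exactly and detected", {
  s <- gen_station_series(
    1, base_climate = list(annual_mean_tmax = 30, seasonal_amplitude = 0,
                           noise_sd = 0.2),
    embedded_events = list(list(start = "1990-07-01", duration_days = 6,
                                peak_tmax = 34)),
    seed = 8)
  planted <- s$tmax_c[s$date >= as.Date("1990-07-01") &
                        s$date <= as.Date("1990-07-06")]
  expect_equal(planted, rep(34, 6))
  ev <- detect_events(s$date, s$tmax_c, threshold = 32.1)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$duration, 6)
  expect_equal(ev$start_date, as.Date("1990-07-01"))
})

test_that("overlapping embedded events are rejected", {
  expect_error(gen_station_series(
    1, embedded_events = list(
      list(start = "1990-07-01", duration_days = 6, peak_tmax = 34),
      list(start = "1990-07-04", duration_days = 6, peak_tmax = 35)),
    seed = 1), "overlap")
})

test_that("urban grid satisfies its structural invariants", {
  g <- gen_urban_grid(500, seed = 3)
  expect_equal(g$street_fraction + g$roof_fraction, rep(1, 500))
  frac_cols <- c("svi", "street_fraction", "roof_fraction", "tree_cover",
                 "tc_added_target")
  for (cl in frac_cols) expect_true(all(g[[cl]] >= 0 & g[[cl]] <= 1))
  g1 <- gen_urban_grid(1, seed = 1)
  expect_equal(nrow(g1), 1)
  expect_equal(g1$street_fraction + g1$roof_fraction, 1)
  expect_identical(gen_urban_grid(50, seed = 9), gen_urban_grid(50, seed = 9))
})

test_that("street fraction rises and control tree cover falls with SVI", {
  g <- gen_urban_grid(10000, seed = 4)
  expect_gt(cor(g$svi, g$street_fraction, method = "spearman"), 0.3)
  expect_lt(cor(g$svi, g$tree_cover, method = "spearman"), -0.3)
  expect_gt(cor(g$svi, g$tc_added_target, method = "spearman"), 0.3)
  # Houston-like contrast between extreme SVI classes
  expect_lt(mean(g$street_fraction[g$svi < 0.1]), 0.30)
  expect_equal(mean(g$street_fraction[g$svi > 0.9]), 0.40, tolerance = 0.02)
})

test_that("zero slope decouples street fraction from SVI", {
  g <- gen_urban_grid(10000, svi_street_slope = 0, seed = 6)
  expect_lt(abs(cor(g$svi, g$street_fraction)), 0.1)
})

test_that("met forcing is seeded, bounded, and dark at night", {
  g <- gen_urban_grid(20, seed = 1)
  m1 <- gen_met_forcing(g, 2, seed = 7)
  expect_identical(m1, gen_met_forcing(g, 2, seed = 7))
  expect_true(all(m1$rh2 >= 0 & m1$rh2 <= 100))
  expect_true(all(m1$ws10 >= 0))
  expect_true(all(m1$sw_down >= 0))
  night <- m1$hour < 6 | m1$hour > 18
  expect_true(all(m1$sw_down[night] == 0))
  expect_equal(nrow(m1), 20 * 2 * 24)
})

test_that("zero-amplitude, zero-noise forcing is constant", {
  g <- gen_urban_grid(5, seed = 1)
  p <- default_diurnal_params(t2_amp = 0, rh_amp = 0, ws_amp = 0,
                              mrt_day_excess = 0, mrt_night_deficit = 0,
                              noise_sd = 0, cell_sd = 0)
  m <- gen_met_forcing(g, 1, p, seed = 2)
  expect_equal(length(unique(m$t2)), 1)
  expect_equal(length(unique(m$rh2)), 1)
  expect_equal(length(unique(m$ws10)), 1)
  expect_equal(length(unique(m$mrt)), 1)
})

test_that("heatwave preset pushes every cell's daily maximum past 35.1 degC", {
  g <- gen_urban_grid(50, seed = 2)
  m <- gen_met_forcing(g, 2, default_diurnal_params("heatwave"), seed = 3)
  daily_max <- tapply(m$t2, interaction(m$cell_id, m$day), max)
  expect_true(all(daily_max > 35.1))
  # and afternoon midrange UTCI clears the heat-stress onset
  aft <- m[m$hour %in% 13:16, ]
  u <- utci_percentiles(aft$t2, aft$rh2, aft$ws10, aft$mrt)$utci_p50
  expect_true(all(u > 26))
})
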