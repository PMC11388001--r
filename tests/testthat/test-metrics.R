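test_that("hourly heat stress is the positive UTCI exceedance", {
  expect_equal(heat_stress(26), 0)
  expect_equal(heat_stress(40), 14)
  expect_equal(heat_stress(20), 0)
  expect_equal(heat_stress(c(25, 26, 27, 40)), c(0, 0, 1, 14))
  expect_equal(heat_stress(40, threshold = 32), 8)
})

test_that("daily cumulative heat stress sums 24 hourly exceedances", {
  expect_equal(daily_cumulative(heat_stress(rep(40, 24))), 336)
  expect_equal(daily_cumulative(heat_stress(rep(20, 24))), 0)
  expect_equal(daily_cumulative(heat_stress(c(27, rep(26, 23)))), 1)
  expect_error(daily_cumulative(rep(1, 23)), "24")
  expect_error(daily_cumulative(rep(1, 25)), "24")
})

test_that("DCH equals a naive per-hour loop on random UTCI series", {
  set.seed(21)
  for (rep in 1:25) {
    u <- runif(24, 15, 45)
    expect_equal(daily_cumulative(heat_stress(u)), naive_dch(u))
    expect_equal(daily_cumulative(heat_stress(u, 32)), naive_dch(u, 32))
  }
})

test_that("ADCH averages the complete day-by-event table", {
  expect_equal(adch(100), 100)
  expect_equal(adch(matrix(c(100, 200, 300, 400), 2)), 250)
  expect_equal(adch(rep(7.5, 12)), 7.5)
  expect_error(adch(c(1, NA, 3)), "missing")
  expect_error(adch(numeric(0)), "empty")
})

test_that("VDCH weights the percent ADCH change by vulnerability", {
  # svi = 1: a 1% ADCH reduction is a VDCH of -1%
  expect_equal(vdch(99, 100, svi = 1), -1)
  expect_equal(vdch(50, 100, svi = 0), 0)
  # svi = 0.1: a 10% ADCH reduction is needed for the same -1%
  expect_equal(vdch(90, 100, svi = 0.1), -1)
  expect_equal(vdch(110, 100, svi = 0.5), 5)  # deterioration is positive
  expect_warning(v0 <- vdch(5, 0, svi = 0.8), "zero control")
  expect_equal(v0, 0)
  expect_equal(vdch(98, 100, svi = 0.5, w = 2), -2)
})

test_that("VDCH vanishes iff SVI is zero or ADCH is unchanged", {
  set.seed(2)
  svi <- runif(50); a_ctl <- runif(50, 50, 150)
  a_i <- a_ctl * (1 + rnorm(50, sd = 0.05))
  v <- vdch(a_i, a_ctl, svi)
  expect_identical(v == 0, svi == 0 | a_i == a_ctl)
})

test_that("required ADCH change inverts the VDCH definition", {
  expect_equal(required_adch_change(-1, svi = 0.1), -10)
  expect_equal(required_adch_change(-1, svi = 1), -1)
  expect_error(required_adch_change(-1, svi = 0), "unreachable")
  set.seed(13)
  for (rep in 1:50) {
    x <- rnorm(1, 0, 5); svi <- runif(1, 0.05, 1); w <- runif(1, 0.2, 3)
    need <- required_adch_change(x, svi, w)
    expect_equal(vdch(100 * (1 + need / 100), 100, svi, w), x)
  }
})

test_that("duration and cooling equivalents translate percent DCH reductions", {
  expect_equal(duration_equivalent(336, 2, 40), 28.8)
  expect_equal(duration_equivalent(336, 0, 40), 0)
  expect_equal(duration_equivalent(336, 4, 40),
               2 * duration_equivalent(336, 2, 40))
  expect_error(duration_equivalent(336, 2, 25), "exceed")
  expect_equal(cooling_equivalent_pct(336, 0.3, 24), 2.142857, tolerance = 1e-6)
  expect_equal(round(cooling_equivalent_pct(336, 0.3, 24)), 2)
  expect_equal(cooling_equivalent_pct(336, 0, 24), 0)
  expect_equal(cooling_equivalent_pct(336, 0.6, 24),
               2 * cooling_equivalent_pct(336, 0.3, 24))
  expect_error(cooling_equivalent_pct(0, 0.3, 24), "non-zero")
})

test_that("SVI-binned curves report per-bin median and IQR", {
  svi <- seq(0.05, 0.95, by = 0.1)
  flat <- adch_change_by_svi_bins(rep(-2, 10), svi)
  expect_equal(flat$median, rep(-2, 10))
  expect_equal(flat$q75 - flat$q25, rep(0, 10))
  # single cell per bin: median equals that cell
  one <- adch_change_by_svi_bins(-svi, svi)
  expect_equal(one$median, -svi)
  expect_equal(one$n, rep(1L, 10))
})

test_that("binned medians recover a change that decreases with SVI", {
  set.seed(31)
  svi <- runif(2000)
  chg <- -svi
  cv <- adch_change_by_svi_bins(chg, svi)
  expect_true(all(diff(cv$median) < 0))
  # brute-force oracle for one interior bin
  sel <- svi > 0.3 & svi <= 0.4
  expect_equal(cv$median[4], median(chg[sel]))
  expect_equal(cv$q25[4], unname(quantile(chg[sel], 0.25)))
})

test_that("empty bins are missing, not zero", {
  cv <- adch_change_by_svi_bins(c(-1, -2), c(0.05, 0.06))
  expect_true(all(is.na(cv$median[-1])))
  expect_equal(cv$n[1], 2L)
})

test_that("urban averaging ignores non-urban cells", {
  v <- c(-1, -1, -1, 99)
  urban <- c(TRUE, TRUE, TRUE, FALSE)
  expect_equal(urban_average_vdch(v, urban), -1)
  v[4] <- -99  # editing non-urban cells leaves the result unchanged
  expect_equal(urban_average_vdch(v, urban), -1)
  expect_equal(urban_average_vdch(rep(2.5, 5), rep(TRUE, 5)), 2.5)
  expect_error(urban_average_vdch(v, rep(FALSE, 4)), "no urban")
})

test_that("whole-day VDCH lies between the period values on a 2-cell fixture", {
  # equal hour counts: 12 daytime + 12 nighttime hours, both stressed
  svi <- c(0.4, 0.8)
  day_ctl <- c(120, 100); night_ctl <- c(40, 30)
  day_i <- day_ctl * 0.97; night_i <- night_ctl * 0.99
  v_day <- vdch(day_i, day_ctl, svi)
  v_night <- vdch(night_i, night_ctl, svi)
  v_whole <- vdch(day_i + night_i, day_ctl + night_ctl, svi)
  for (k in 1:2) {
    expect_gte(v_whole[k], min(v_day[k], v_night[k]))
    expect_lte(v_whole[k], max(v_day[k], v_night[k]))
  }
})
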