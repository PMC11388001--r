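test_that("climatological threshold is the seasonal mean of the station average", {
  days <- seq(as.Date("2000-01-01"), as.Date("2000-12-31"), by = "day")
  a <- make_station("A", days, 30)
  expect_equal(climatological_threshold(a), 30)
  b <- make_station("B", days, 34)
  expect_equal(climatological_threshold(list(a, b)), 32)
})

test_that("threshold on a synthetic 30-year record equals the brute-force JJA mean", {
  s <- gen_station_series(30, seed = 5)
  thr <- climatological_threshold(s)
  jja <- s$tmax_c[as.integer(format(s$date, "%m")) %in% 6:8]
  expect_equal(thr, mean(jja))
  # Houston-like default climate: JJA mean near 32 degC
  expect_lt(abs(thr - 32.1), 0.6)
})

test_that("missing season days fail fast beyond tolerance", {
  days <- seq(as.Date("2000-06-01"), as.Date("2000-08-31"), by = "day")
  s <- make_station("A", days, 30)
  s <- s[-c(10, 11, 12), ]
  expect_error(climatological_threshold(s), "missing")
  expect_equal(climatological_threshold(s, max_missing_frac = 0.1), 30)
})

test_that("event detection finds maximal exceedance runs of sufficient length", {
  days <- seq(as.Date("2018-06-01"), by = "day", length.out = 40)
  tmax <- rep(30, 40)
  expect_equal(nrow(detect_events(days, tmax, threshold = 32.1)), 0)
  tmax[10:15] <- 34  # one 6-day run flanked by cool days
  ev <- detect_events(days, tmax, threshold = 32.1)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$duration, 6)
  expect_equal(ev$start_date, days[10])
  expect_equal(ev$peak_tmax, 34)
  tmax[17:22] <- 33.5  # second run, separated by one cool day: never merged
  ev2 <- detect_events(days, tmax, threshold = 32.1)
  expect_equal(nrow(ev2), 2)
  expect_equal(ev2$duration, c(6, 6))
})

test_that("detector agrees with a day-by-day brute-force scan", {
  set.seed(3)
  for (rep in 1:20) {
    n <- 120
    tmax <- 30 + cumsum(rnorm(n, sd = 1.2))
    thr <- 30 + rnorm(1)
    days <- seq(as.Date("2017-06-01"), by = "day", length.out = n)
    ev <- detect_events(days, tmax, thr)
    bf <- brute_force_events(tmax, thr)
    expect_equal(nrow(ev), length(bf))
    for (k in seq_along(bf)) {
      expect_equal(as.integer(ev$start_date[k] - days[1]) + 1L,
                   unname(bf[[k]]["start"]))
      expect_equal(ev$duration[k],
                   unname(bf[[k]]["end"] - bf[[k]]["start"] + 1L))
    }
    # hot-day mask reconstruction: event days + short runs = all hot days
    hot <- tmax > thr
    in_event <- rep(FALSE, n)
    for (k in seq_len(nrow(ev))) {
      i0 <- as.integer(ev$start_date[k] - days[1]) + 1L
      in_event[i0:(i0 + ev$duration[k] - 1L)] <- TRUE
    }
    expect_true(all(hot[in_event]))
    r <- rle(hot[!in_event & hot] | TRUE)  # leftover hot days exist only in short runs
    runs <- rle(hot)
    short_hot_days <- sum(runs$lengths[runs$values & runs$lengths < 6])
    expect_equal(sum(hot) - sum(in_event), short_hot_days)
  }
})

test_that("raising the threshold never increases total event-days", {
  set.seed(9)
  tmax <- 30 + cumsum(rnorm(200, sd = 1))
  days <- seq(as.Date("2018-01-01"), by = "day", length.out = 200)
  totals <- vapply(seq(25, 40, by = 0.5), function(th)
    sum(detect_events(days, tmax, th)$duration), numeric(1))
  expect_true(all(diff(totals) <= 0))
})

test_that("severe-event filter applies strict peak and duration cuts", {
  ev <- data.frame(peak_tmax = 36, duration = 15)
  expect_equal(nrow(select_severe(ev)), 1)
  expect_equal(nrow(select_severe(data.frame(peak_tmax = 36, duration = 10))), 0)
  # 12 detected cases of which exactly 5 satisfy both cuts
  fixture <- data.frame(
    peak_tmax = c(36.0, 35.5, 36.2, 37.1, 35.2, 35.0, 34.8, 36.5, 35.1, 33.9, 36.8, 35.3),
    duration  = c(15,   16,   20,   18,   15,   16,   17,   12,   15,   19,   10,   14))
  expect_equal(nrow(fixture), 12)
  kept <- select_severe(fixture)
  expect_equal(nrow(kept), 5)
  expect_true(all(kept$peak_tmax > 35.1 & kept$duration > 14))
})

test_that("WMO heatwave check requires more than 5 consecutive exceedance days", {
  # Houston numbers: 25.6 average daily max, 5 K margin -> 30.6 exceedance level
  expect_true(wmo_check(rep(31, 6), avg_daily_max = 25.6))
  expect_false(wmo_check(rep(31, 5), avg_daily_max = 25.6))
  expect_false(wmo_check(rep(30.6, 10), avg_daily_max = 25.6))  # strict >
  expect_true(wmo_check(c(25, 31, 31, 31, 31, 31, 31, 25), 25.6))
})

test_that("simulation window spans 48 h either side of the 21Z peak", {
  w <- simulation_window(as.Date("2019-08-10"))
  expect_equal(w$window_start,
               as.POSIXct("2019-08-08 21:00:00", tz = "UTC"))
  expect_equal(w$window_end,
               as.POSIXct("2019-08-12 21:00:00", tz = "UTC"))
  expect_equal(as.numeric(difftime(w$window_end, w$window_start,
                                   units = "hours")), 96)
})

test_that("events export as JSON lines with their windows", {
  days <- seq(as.Date("2018-06-01"), by = "day", length.out = 40)
  tmax <- rep(30, 40); tmax[10:16] <- 36
  ev <- detect_events(days, tmax, 32.1)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_events_jsonl(ev, path)
  rec <- jsonlite::fromJSON(readLines(path)[1])
  expect_equal(rec$duration, 7)
  expect_equal(rec$peak_tmax, 36)
  expect_match(rec$window_start, "T21:00Z")
})
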