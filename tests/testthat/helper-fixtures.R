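# Shared oracles and fixtures.  Oracles are deliberately naive, independent
# re-derivations of the quantities the package computes.

# Day-by-day scan for maximal runs of days strictly above a threshold.
brute_force_events <- function(tmax, threshold, min_run = 6L) {
  runs <- list()
  i <- 1L
  n <- length(tmax)
  while (i <= n) {
    if (tmax[i] > threshold) {
      j <- i
      while (j < n && tmax[j + 1L] > threshold) j <- j + 1L
      if (j - i + 1L >= min_run)
        runs[[length(runs) + 1L]] <- c(start = i, end = j)
      i <- j + 1L
    } else i <- i + 1L
  }
  runs
}

# Naive per-hour loop for daily cumulative heat stress.
naive_dch <- function(utci_hourly, threshold = 26) {
  total <- 0
  for (u in utci_hourly) if (u >= threshold) total <- total + (u - threshold)
  total
}

# Scalar term-by-term evaluation of the UTCI polynomial from the vendored
# coefficient/exponent table -- an evaluation route independent of the
# package's vectorised power-table implementation.
reference_utci <- function(ta, rh, va, tmrt) {
  coefs <- heatequity:::.utci_poly_coef
  ex <- heatequity:::.utci_poly_exponents
  pa <- saturation_vapor_pressure(ta) * rh / 100 / 10
  d <- tmrt - ta
  ta + sum(coefs * ta^ex[, "ta"] * va^ex[, "va"] * d^ex[, "dtmrt"] *
             pa^ex[, "pa"])
}

# Hand-built urban grid with controlled fractions.
make_grid <- function(svi, street_fraction, tree_cover = 0.17,
                      tc_added_target = 0.14, is_urban = TRUE) {
  n <- max(length(svi), length(street_fraction))
  structure(
    data.frame(cell_id = seq_len(n), svi = rep_len(svi, n),
               street_fraction = rep_len(street_fraction, n),
               roof_fraction = 1 - rep_len(street_fraction, n),
               tree_cover = rep_len(tree_cover, n),
               tc_added_target = rep_len(tc_added_target, n),
               is_urban = rep_len(is_urban, n)),
    class = c("urban_grid", "data.frame"))
}

# Constant-temperature station series over given dates.
make_station <- function(id, dates, tmax) {
  structure(data.frame(station_id = id, date = dates,
                       tmax_c = rep_len(tmax, length(dates))),
            class = c("station_series", "data.frame"))
}
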