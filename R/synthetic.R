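#' Generate a synthetic station daily-maximum temperature series
#'
#' Produces a seeded daily-maximum series with a sinusoidal annual cycle plus
#' Gaussian noise, into which exceedance runs ("embedded events") can be
#' planted exactly.  The default base climate mimics a Houston-like station:
#' a 25.6 degC annual-average daily maximum whose summer (JJA) mean sits near
#' 32.1 degC.
#'
#' @param n_years number of calendar years, >= 1.
#' @param base_climate list with `annual_mean_tmax` (degC),
#'   `seasonal_amplitude` (K), `peak_doy` (day of year of the warm peak) and
#'   `noise_sd` (K).
#' @param embedded_events list of events, each
#'   `list(start = "YYYY-MM-DD", duration_days, peak_tmax)`; on event days
#'   the daily maximum is set to `peak_tmax` exactly.  Overlapping events are
#'   an error.
#' @param seed integer RNG seed.
#' @param station_id station label.
#' @param start_year first calendar year.
#' @return data.frame of class `station_series` with columns `station_id`,
#'   `date`, `tmax_c`.
#' @export
gen_station_series <- function(n_years,
                               base_climate = list(annual_mean_tmax = 25.6,
                                                   seasonal_amplitude = 7.2,
                                                   peak_doy = 200,
                                                   noise_sd = 1.5),
                               embedded_events = list(),
                               seed = 1L,
                               station_id = "SYN1",
                               start_year = 1990L) {
  stopifnot(n_years >= 1)
  bc <- modifyList(list(annual_mean_tmax = 25.6, seasonal_amplitude = 7.2,
                        peak_doy = 200, noise_sd = 1.5), base_climate)
  set.seed(seed)
  dates <- seq(as.Date(sprintf("%d-01-01", start_year)),
               as.Date(sprintf("%d-12-31", start_year + n_years - 1L)),
               by = "day")
  doy <- as.integer(format(dates, "%j"))
  tmax <- bc$annual_mean_tmax +
    bc$seasonal_amplitude * cos(2 * pi * (doy - bc$peak_doy) / 365.25) +
    stats::rnorm(length(dates), sd = bc$noise_sd)
  used <- rep(FALSE, length(dates))
  for (ev in embedded_events) {
    stopifnot(!is.null(ev$start), ev$duration_days >= 1,
              is.numeric(ev$peak_tmax))
    i0 <- match(as.Date(ev$start), dates)
    if (is.na(i0) || i0 + ev$duration_days - 1L > length(dates))
      stop("embedded event falls outside the series")
    idx <- i0:(i0 + ev$duration_days - 1L)
    if (any(used[idx])) stop("embedded events overlap")
    used[idx] <- TRUE
    tmax[idx] <- ev$peak_tmax
  }
  structure(data.frame(station_id = station_id, date = dates, tmax_c = tmax),
            class = c("station_series", "data.frame"))
}

#' Generate a synthetic urban grid
#'
#' Draws an abstract city of grid cells carrying a Social Vulnerability
#' Index, complementary street and roof fractions, the control tree cover,
#' and the tree-equity-targeted tree-cover addition.  SVI is uniform on
#' \[0, 1\] (it is a rank-based index).  Street fraction rises with SVI --
#' with Houston-like defaults from just under 30% in resilient cells
#' (SVI < 0.1) to about 40% in vulnerable cells (SVI > 0.9) -- so roof
#' fraction falls with SVI.  Control tree cover decreases with SVI (current
#' canopy is thinner where vulnerability is higher), while the targeted
#' addition increases with SVI.
#'
#' @param n_cells number of cells, >= 1.
#' @param svi_street_slope increase of street fraction per unit SVI; 0 makes
#'   street fraction independent of SVI.
#' @param seed integer RNG seed.
#' @param street_intercept street fraction at SVI = 0.
#' @param street_noise_sd Gaussian scatter of street fraction.
#' @param tc_intercept,tc_svi_slope,tc_noise_sd control tree-cover model
#'   (fraction of street area), slope negative by default.
#' @param tc_add_intercept,tc_add_slope targeted tree-cover addition model,
#'   slope positive by default.
#' @param frac_nonurban fraction of cells flagged non-urban.
#' @return data.frame of class `urban_grid` with columns `cell_id`, `svi`,
#'   `street_fraction`, `roof_fraction`, `tree_cover`, `tc_added_target`,
#'   `is_urban`.
#' @export
gen_urban_grid <- function(n_cells, svi_street_slope = 0.115, seed = 1L,
                           street_intercept = 0.29, street_noise_sd = 0.03,
                           tc_intercept = 0.24, tc_svi_slope = -0.14,
                           tc_noise_sd = 0.04,
                           tc_add_intercept = 0.08, tc_add_slope = 0.12,
                           frac_nonurban = 0) {
  stopifnot(n_cells >= 1, frac_nonurban >= 0, frac_nonurban < 1)
  set.seed(seed)
  svi <- stats::runif(n_cells)
  clip01 <- function(x, lo = 0, hi = 1) pmin(pmax(x, lo), hi)
  street <- clip01(street_intercept + svi_street_slope * svi +
                     stats::rnorm(n_cells, sd = street_noise_sd), 0.05, 0.95)
  tc <- clip01(tc_intercept + tc_svi_slope * svi +
                 stats::rnorm(n_cells, sd = tc_noise_sd), 0.01, 0.8)
  tc_add <- clip01(tc_add_intercept + tc_add_slope * svi +
                     stats::rnorm(n_cells, sd = tc_noise_sd / 2), 0, 0.5)
  is_urban <- stats::runif(n_cells) >= frac_nonurban
  structure(
    data.frame(cell_id = seq_len(n_cells), svi = svi,
               street_fraction = street, roof_fraction = 1 - street,
               tree_cover = tc, tc_added_target = tc_add,
               is_urban = is_urban),
    class = c("urban_grid", "data.frame"))
}

#' Diurnal forcing parameters
#'
#' Parameter set for the synthetic hourly meteorological forcing.  The
#' `"heatwave"` preset (the default) produces daily maximum 2-m temperatures
#' near 37.5 degC -- comfortably above the 35.1 degC severe-heatwave peak
#' criterion -- with afternoon mean radiant temperatures high enough that
#' midrange UTCI exceeds the 26 degC heat-stress onset for much of the day.
#' The `"mild"` preset stays below heatwave levels.
#'
#' @param preset `"heatwave"` or `"mild"`.
#' @param ... overrides for individual parameters: `t2_mean`, `t2_amp`
#'   (degC), `rh_mean`, `rh_amp` (percent), `ws_mean`, `ws_amp` (m/s),
#'   `mrt_day_excess`, `mrt_night_deficit` (K), `sw_max` (W/m2),
#'   `noise_sd` (Gaussian noise on the diurnal harmonics), `cell_sd`
#'   (between-cell temperature offsets, K).
#' @return named list of parameters.
#' @export
default_diurnal_params <- function(preset = c("heatwave", "mild"), ...) {
  preset <- match.arg(preset)
  p <- list(t2_mean = 32, t2_amp = 5.5, rh_mean = 55, rh_amp = 18,
            ws_mean = 3, ws_amp = 1, mrt_day_excess = 18,
            mrt_night_deficit = 2, sw_max = 950, noise_sd = 0.4,
            cell_sd = 0.3)
  if (preset == "mild") {
    p$t2_mean <- 27
    p$t2_amp <- 4.5
  }
  modifyList(p, list(...))
}

#' Solar zenith angle of the idealised diurnal cycle
#'
#' The synthetic forcing uses an idealised sun: elevation follows
#' `sin(pi * (hour - 6) / 12)` between 06 and 18 local time and the sun is
#' below the horizon otherwise (zenith pi/2).
#'
#' @param hour local hour of day in \[0, 24), vectorised.
#' @return zenith angle in radians.
#' @export
solar_zenith <- function(hour) {
  cosz <- .solar_cos_zenith(hour)
  acos(pmin(cosz, 1))
}

# clipped solar elevation; sub-numerical residuals at sunrise/sunset are
# treated as dark so that sw_down is exactly zero there
.solar_cos_zenith <- function(hour) {
  cosz <- sin(pi * (hour - 6) / 12)
  cosz[cosz < 1e-9] <- 0
  cosz
}

#' Generate synthetic hourly meteorological forcing
#'
#' Hourly 2-m temperature, 2-m relative humidity, 10-m wind speed, mean
#' radiant temperature, and downwelling shortwave for every grid cell over
#' `n_days` local days.  Each variable follows a sinusoidal diurnal cycle
#' (temperature peaking at 15:00 local, humidity in antiphase) with Gaussian
#' noise on the harmonics; shortwave follows the clipped idealised
#' solar-elevation curve of [solar_zenith()] and is exactly zero when the
#' sun is below the horizon.  MRT exceeds the air temperature in proportion
#' to solar elevation during the day and sits slightly below it at night.
#'
#' @param grid an `urban_grid` from [gen_urban_grid()].
#' @param n_days number of simulated days, >= 1.
#' @param diurnal_params parameter list from [default_diurnal_params()].
#' @param seed integer RNG seed.
#' @return long data.frame of class `met_field` with columns `cell_id`,
#'   `day`, `hour`, `t2`, `rh2`, `ws10`, `mrt`, `sw_down`.
#' @export
gen_met_forcing <- function(grid, n_days,
                            diurnal_params = default_diurnal_params(),
                            seed = 1L) {
  stopifnot(inherits(grid, "urban_grid"), n_days >= 1)
  p <- diurnal_params
  set.seed(seed)
  n_cells <- nrow(grid)
  cell_offset <- stats::rnorm(n_cells, sd = p$cell_sd)
  base <- expand.grid(hour = 0:23, day = seq_len(n_days),
                      cell_id = grid$cell_id)
  base <- base[, c("cell_id", "day", "hour")]
  n <- nrow(base)
  off <- cell_offset[match(base$cell_id, grid$cell_id)]
  harm <- cos(2 * pi * (base$hour - 15) / 24)
  noise <- function(sd) stats::rnorm(n, sd = sd)
  cosz <- .solar_cos_zenith(base$hour)
  t2 <- p$t2_mean + off + p$t2_amp * harm + noise(p$noise_sd)
  rh2 <- pmin(pmax(p$rh_mean - p$rh_amp * harm + noise(2.5 * p$noise_sd),
                   5), 100)
  ws10 <- pmax(p$ws_mean + p$ws_amp * cos(2 * pi * (base$hour - 16) / 24) +
                 noise(p$noise_sd), 0.3)
  mrt <- t2 + p$mrt_day_excess * cosz - p$mrt_night_deficit * (cosz == 0) +
    noise(p$noise_sd)
  sw_down <- p$sw_max * cosz
  out <- cbind(base, data.frame(t2 = t2, rh2 = rh2, ws10 = ws10, mrt = mrt,
                                sw_down = sw_down))
  attr(out, "diurnal_params") <- p
  class(out) <- c("met_field", "data.frame")
  out
}
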