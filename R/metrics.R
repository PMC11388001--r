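#' Hourly heat-stress exceedance (HS)
#'
#' Magnitude of UTCI above the heat-stress onset threshold, zero below it:
#' `HS = max(UTCI - threshold, 0)`.  The recommended onset of heat stress is
#' a UTCI of 26 degC; a 32 degC threshold is also supported for sensitivity
#' work.
#'
#' @param utci UTCI in degC, vectorised.
#' @param threshold heat-stress onset, degC (default 26).
#' @return exceedance in K, same length as `utci`.
#' @export
heat_stress <- function(utci, threshold = 26) {
  pmax(utci - threshold, 0)
}

#' Daily cumulative heat stress (DCH)
#'
#' Sum of the hourly heat-stress exceedances over one local day.  A day is
#' 24 hourly samples (t = 0..23); any other count is an error.
#'
#' @param hs_hourly 24 hourly HS values in K.
#' @return DCH in K h.
#' @examples
#' daily_cumulative(rep(14, 24))  # 336 K h: a full day at UTCI 40, threshold 26
#' @export
daily_cumulative <- function(hs_hourly) {
  if (length(hs_hourly) != 24L)
    stop("'hs_hourly' must hold exactly 24 hourly values, got ",
         length(hs_hourly))
  if (anyNA(hs_hourly)) stop("'hs_hourly' contains missing values")
  sum(hs_hourly)
}

#' Averaged daily cumulative heat stress (ADCH)
#'
#' Arithmetic mean of DCH over all simulated days of all heatwave events for
#' one experiment.  The day-by-event table must be complete.
#'
#' @param dch_by_day_event numeric matrix or data.frame of DCH values with
#'   one cell per (day, event) combination, or a plain vector of DCH values.
#' @return ADCH in K h.
#' @export
adch <- function(dch_by_day_event) {
  x <- unlist(dch_by_day_event, use.names = FALSE)
  if (length(x) == 0L) stop("empty DCH table")
  if (anyNA(x)) stop("DCH table has missing cells; the day-by-event table must be complete")
  mean(x)
}

#' Vulnerability-weighted daily cumulative heat-stress change (VDCH)
#'
#' Percent change of ADCH relative to the control experiment, weighted by the
#' cell's Social Vulnerability Index:
#' `VDCH = w * SVI * (ADCH_i - ADCH_ctl) / ADCH_ctl * 100`.
#' Negative values mean improved community heat-stress resilience; the SVI
#' weighting discounts cooling delivered to resilient neighborhoods.  Cells
#' with no control heat stress (`adch_ctl = 0`) have nothing to mitigate and
#' return 0 with a warning.
#'
#' @param adch_i experiment ADCH, K h (vectorised over cells).
#' @param adch_ctl control ADCH, K h.
#' @param svi Social Vulnerability Index in \[0, 1\].
#' @param w vulnerability weighting (default 1: SVI and ADCH change count
#'   equally).
#' @return VDCH in percent.
#' @export
vdch <- function(adch_i, adch_ctl, svi, w = 1) {
  n <- max(length(adch_i), length(adch_ctl), length(svi))
  adch_i <- rep_len(adch_i, n); adch_ctl <- rep_len(adch_ctl, n)
  svi <- rep_len(svi, n)
  if (any(svi < 0 | svi > 1)) stop("'svi' must lie in [0, 1]")
  out <- numeric(n)
  ok <- adch_ctl != 0
  if (any(!ok))
    warning(sum(!ok), " cell(s) with zero control ADCH; VDCH set to 0 there")
  out[ok] <- w * svi[ok] * (adch_i[ok] - adch_ctl[ok]) / adch_ctl[ok] * 100
  out
}

#' ADCH change required for a target VDCH
#'
#' Inverts the VDCH definition: the percent ADCH change that yields
#' `target_vdch` in a neighborhood of vulnerability `svi` is
#' `target_vdch / (w * svi)`.  A VDCH of -1% needs only a 1% ADCH reduction
#' where SVI = 1, but a 10% reduction where SVI = 0.1.
#'
#' @param target_vdch target VDCH in percent.
#' @param svi Social Vulnerability Index, must be > 0.
#' @param w vulnerability weighting, must be > 0.
#' @return required ADCH change in percent.
#' @export
required_adch_change <- function(target_vdch, svi, w = 1) {
  if (any(svi <= 0)) stop("target unreachable where svi = 0")
  if (any(w <= 0)) stop("'w' must be positive")
  target_vdch / (w * svi)
}

#' Duration equivalent of a percent DCH reduction
#'
#' Expresses a percent reduction of DCH as the number of minutes of exposure
#' removed while UTCI is held at `utci_level`:
#' `minutes = pct/100 * dch / (utci_level - threshold) * 60`.  A 2% cut of a
#' 336 K h day at UTCI 40 degC is 28.8 min less exposure.
#'
#' @param dch daily cumulative heat stress, K h.
#' @param pct_reduction percent DCH reduction.
#' @param utci_level sustained UTCI level, degC; must exceed `threshold`.
#' @param threshold heat-stress onset, degC (default 26).
#' @return minutes of exposure removed.
#' @export
duration_equivalent <- function(dch, pct_reduction, utci_level,
                                threshold = 26) {
  if (any(utci_level <= threshold))
    stop("'utci_level' must exceed the heat-stress threshold")
  pct_reduction / 100 * dch / (utci_level - threshold) * 60
}

#' Percent DCH reduction equivalent to sustained cooling
#'
#' Percent of DCH removed by cooling the UTCI by `delta_utci` K for `hours`
#' hours: `100 * delta_utci * hours / dch`.  Cooling a 336 K h day from 40.0
#' to 39.7 degC for all 24 h removes about 2%.
#'
#' @param dch daily cumulative heat stress, K h; must be positive.
#' @param delta_utci sustained UTCI cooling, K.
#' @param hours hours over which the cooling is sustained (UTCI above
#'   threshold throughout).
#' @return percent DCH reduction.
#' @export
cooling_equivalent_pct <- function(dch, delta_utci, hours) {
  if (any(dch == 0)) stop("'dch' must be non-zero")
  100 * delta_utci * hours / dch
}

#' SVI-binned ADCH-change curve with interquartile spread
#'
#' Bins cells by Social Vulnerability Index (deciles by default; the extreme
#' bins are SVI < 0.1 and SVI > 0.9) and summarises the per-cell percent
#' ADCH change in each bin by its median and interquartile range.  Empty
#' bins are reported as missing, not zero.
#'
#' @param adch_change_pct per-cell percent ADCH change.
#' @param svi per-cell Social Vulnerability Index in \[0, 1\].
#' @param breaks bin edges partitioning \[0, 1\] (default deciles).
#' @return data.frame with columns `bin_lo`, `bin_hi`, `bin_mid`, `n`,
#'   `median`, `q25`, `q75`.
#' @export
adch_change_by_svi_bins <- function(adch_change_pct, svi,
                                    breaks = seq(0, 1, by = 0.1)) {
  stopifnot(length(adch_change_pct) == length(svi),
            !is.unsorted(breaks), breaks[1] <= 0, breaks[length(breaks)] >= 1)
  if (any(svi < 0 | svi > 1)) stop("'svi' must lie in [0, 1]")
  idx <- cut(svi, breaks = breaks, include.lowest = TRUE, labels = FALSE)
  nb <- length(breaks) - 1L
  out <- data.frame(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1])
  out$bin_mid <- (out$bin_lo + out$bin_hi) / 2
  out$n <- tabulate(idx, nbins = nb)
  qs <- function(b, p) if (out$n[b] == 0L) NA_real_ else
    unname(stats::quantile(adch_change_pct[idx == b], p))
  out$median <- vapply(seq_len(nb), qs, numeric(1), p = 0.5)
  out$q25 <- vapply(seq_len(nb), qs, numeric(1), p = 0.25)
  out$q75 <- vapply(seq_len(nb), qs, numeric(1), p = 0.75)
  out
}

#' Urban-averaged VDCH
#'
#' Mean VDCH over urban cells for one experiment and period (whole day,
#' daytime, or nighttime -- the period enters upstream, through which hours
#' the DCH was accumulated over).
#'
#' @param vdch_per_cell per-cell VDCH in percent.
#' @param urban_mask logical urban flags, same length.
#' @return mean VDCH in percent.
#' @export
urban_average_vdch <- function(vdch_per_cell, urban_mask) {
  stopifnot(length(vdch_per_cell) == length(urban_mask),
            is.logical(urban_mask))
  if (!any(urban_mask)) stop("no urban cells in mask")
  mean(vdch_per_cell[urban_mask])
}
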