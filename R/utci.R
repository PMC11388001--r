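#' Saturation vapour pressure over water
#'
#' ITS-90 formulation of the saturation vapour pressure over liquid water,
#' the formulation bundled with the operational UTCI procedure for converting
#' relative humidity to vapour pressure.
#'
#' @param ta air temperature in degrees Celsius.
#' @return saturation vapour pressure in hPa, same length as `ta`.
#' @examples
#' saturation_vapor_pressure(0)   # ~6.11 hPa
#' saturation_vapor_pressure(30)  # ~42.4 hPa
#' @export
saturation_vapor_pressure <- function(ta) {
  if (!is.numeric(ta) || anyNA(ta) || any(!is.finite(ta)))
    stop("'ta' must be finite numeric")
  tk <- ta + 273.15
  g <- c(-2.8365744e3, -6.028076559e3, 1.954263612e1, -2.737830188e-2,
         1.6261698e-5, 7.0229056e-10, -1.8680009e-13)
  es <- 2.7150305 * log(tk)
  for (i in seq_along(g)) es <- es + g[i] * tk^(i - 3L)
  exp(es) * 0.01  # Pa -> hPa
}

#' Universal Thermal Climate Index (operational polynomial approximation)
#'
#' Evaluates the published sixth-order polynomial approximation of UTCI in
#' air temperature, vapour pressure, wind speed, and the excess of mean
#' radiant temperature over air temperature.  Inputs outside the polynomial's
#' validity domain are clamped to it (with a warning) before evaluation:
#' `ta` to \[-50, 50\] degC, `va10` to \[0.5, 17\] m/s, `tmrt - ta` to
#' \[-30, 70\] K, and vapour pressure to at most 50 hPa.
#'
#' @param ta 2-m air temperature, degC.
#' @param rh 2-m relative humidity, percent in \[0, 100\].
#' @param va10 10-m wind speed, m/s.
#' @param tmrt mean radiant temperature, degC.
#' @param clamp clamp out-of-domain inputs (default) instead of failing.
#' @param quiet suppress the out-of-domain warning.
#' @return UTCI in degC, vectorised over the inputs.
#' @examples
#' utci(ta = 29, rh = 60, va10 = 1, tmrt = 30)
#' @export
utci <- function(ta, rh, va10, tmrt, clamp = TRUE, quiet = FALSE) {
  n <- max(length(ta), length(rh), length(va10), length(tmrt))
  ta <- rep_len(as.numeric(ta), n); rh <- rep_len(as.numeric(rh), n)
  va10 <- rep_len(as.numeric(va10), n); tmrt <- rep_len(as.numeric(tmrt), n)
  if (anyNA(ta) || anyNA(rh) || anyNA(va10) || anyNA(tmrt) ||
      any(!is.finite(c(ta, rh, va10, tmrt))))
    stop("UTCI inputs must be finite")
  if (any(rh < 0 | rh > 100)) stop("'rh' must lie in [0, 100]")
  if (any(va10 < 0)) stop("'va10' must be non-negative")

  pa <- saturation_vapor_pressure(ta) * rh / 100 / 10  # kPa
  dtmrt <- tmrt - ta
  out_of_domain <- ta < -50 | ta > 50 | va10 < 0.5 | va10 > 17 |
    dtmrt < -30 | dtmrt > 70 | pa > 5
  if (any(out_of_domain)) {
    if (!clamp) stop("inputs outside the UTCI polynomial validity domain")
    if (!quiet)
      warning(sum(out_of_domain),
              " input(s) outside the UTCI validity domain were clamped")
    ta <- pmin(pmax(ta, -50), 50)
    va10 <- pmin(pmax(va10, 0.5), 17)
    dtmrt <- pmin(pmax(dtmrt, -30), 70)
    pa <- pmin(pa, 5)
  }
  ta + .utci_offset(ta, va10, dtmrt, pa)
}

# Polynomial offset (UTCI - Ta).  Evaluated with precomputed power tables and
# a single accumulation pass over the 210 terms; cheap and vectorised.
.utci_offset <- function(ta, va, dtmrt, pa) {
  powers <- function(x) {
    m <- matrix(1, nrow = length(x), ncol = 7L)
    for (p in 1:6) m[, p + 1L] <- m[, p] * x
    m
  }
  tp <- powers(ta); vp <- powers(va); dp <- powers(dtmrt); pp <- powers(pa)
  ex <- .utci_poly_exponents
  acc <- numeric(length(ta))
  for (t in seq_len(nrow(ex))) {
    acc <- acc + .utci_poly_coef[t] *
      tp[, ex[t, 1L] + 1L] * vp[, ex[t, 2L] + 1L] *
      dp[, ex[t, 3L] + 1L] * pp[, ex[t, 4L] + 1L]
  }
  acc
}

#' Subgrid-wind UTCI percentiles (cool spot, midrange, hot spot)
#'
#' The forcing provides one grid-cell wind speed, but pedestrians experience
#' a distribution of wind speeds within the cell.  A subgrid wind
#' distribution is placed around the cell value, UTCI is evaluated at its
#' quantiles, and the cell's cool-spot (10th percentile), midrange (50th) and
#' hot-spot (90th) UTCI are reported.  Because UTCI is monotone decreasing in
#' wind under hot conditions, the hot spot corresponds to the low-wind tail;
#' values are sorted so that p10 <= p50 <= p90 always holds.  The default
#' subgrid distribution is lognormal with median equal to the cell wind and a
#' configurable log-scale spread; `sdlog = 0` degenerates to the point value.
#'
#' @param ta,rh,tmrt UTCI drivers (degC, percent, degC), vectorised.
#' @param ws10 cell-median 10-m wind speed, m/s.
#' @param wind_dist list describing the subgrid wind distribution; currently
#'   `list(family = "lognormal", sdlog = <spread>)`.
#' @param quantiles probabilities of the reported spots.
#' @return data.frame with columns `utci_p10`, `utci_p50`, `utci_p90`.
#' @export
utci_percentiles <- function(ta, rh, ws10, tmrt,
                             wind_dist = list(family = "lognormal", sdlog = 0.3),
                             quantiles = c(0.1, 0.5, 0.9)) {
  stopifnot(is.list(wind_dist), length(quantiles) == 3L,
            !is.unsorted(quantiles))
  family <- wind_dist$family %||% "lognormal"
  sdlog <- wind_dist$sdlog %||% 0.3
  if (!identical(family, "lognormal"))
    stop("unsupported subgrid wind distribution family: ", family)
  if (sdlog < 0) stop("'sdlog' must be non-negative")
  n <- max(length(ta), length(rh), length(ws10), length(tmrt))
  ta <- rep_len(ta, n); rh <- rep_len(rh, n)
  ws10 <- rep_len(ws10, n); tmrt <- rep_len(tmrt, n)
  # wind at each subgrid quantile; median of the lognormal is the cell value
  u <- vapply(quantiles, function(q) {
    if (sdlog == 0) ws10 else ws10 * exp(sdlog * stats::qnorm(q))
  }, numeric(n))
  if (n == 1L) u <- matrix(u, nrow = 1L)
  vals <- vapply(seq_len(3L), function(k)
    utci(ta, rh, u[, k], tmrt, quiet = TRUE), numeric(n))
  if (n == 1L) vals <- matrix(vals, nrow = 1L)
  sorted <- t(apply(vals, 1L, sort))
  data.frame(utci_p10 = sorted[, 1L], utci_p50 = sorted[, 2L],
             utci_p90 = sorted[, 3L])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
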