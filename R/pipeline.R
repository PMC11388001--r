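#' Experiment-suite run configuration
#'
#' Assembles and validates the configuration of an end-to-end run: the seed,
#' the synthetic-city size, the heatwave events to simulate, the scenario
#' list, and all physical constants (heat-stress threshold, vulnerability
#' weighting, canopy parameters, surrogate sensitivities).  Unknown keys are
#' rejected.
#'
#' @param seed integer seed driving every random draw of the run.
#' @param n_cells number of grid cells.
#' @param n_events number of heatwave events simulated.
#' @param n_days days simulated per event.
#' @param scenarios list of [scenario_spec()] objects; `"all"` expands to
#'   the seven-experiment design (control + 3 strategies x 2 intensities),
#'   `"high"` to control + the three high scenarios.
#' @param threshold UTCI heat-stress onset, degC (default 26; 32 supported).
#' @param w vulnerability weighting in the VDCH (default 1).
#' @param wind_sdlog subgrid wind lognormal spread (see
#'   [utci_percentiles()]).
#' @param svi_bins SVI bin edges for the ADCH-change curves.
#' @param canopy a [canopy_params()] object.
#' @param effect_model a [default_effect_model()] list.
#' @param diurnal_params forcing parameters, see [default_diurnal_params()].
#' @param grid_params named list of overrides passed to [gen_urban_grid()].
#' @return validated list of class `run_config`.
#' @export
run_config <- function(seed = 1L, n_cells = 300L, n_events = 2L,
                       n_days = 2L, scenarios = "all", threshold = 26,
                       w = 1, wind_sdlog = 0.3,
                       svi_bins = seq(0, 1, by = 0.1),
                       canopy = canopy_params(),
                       effect_model = default_effect_model(),
                       diurnal_params = default_diurnal_params(),
                       grid_params = list()) {
  if (identical(scenarios, "all")) {
    scenarios <- c(list(scenario_spec("control")),
                   lapply(c("cool_roof", "green_roof", "urban_trees"),
                          scenario_spec, intensity = "low"),
                   lapply(c("cool_roof", "green_roof", "urban_trees"),
                          scenario_spec, intensity = "high"))
  } else if (identical(scenarios, "high")) {
    scenarios <- c(list(scenario_spec("control")),
                   lapply(c("cool_roof", "green_roof", "urban_trees"),
                          scenario_spec, intensity = "high"))
  }
  stopifnot(is.list(scenarios),
            all(vapply(scenarios, inherits, logical(1), "scenario_spec")))
  if (!any(vapply(scenarios, function(s) s$strategy == "control",
                  logical(1))))
    stop("the scenario list must include the control experiment")
  stopifnot(length(seed) == 1L, is.finite(seed),
            n_cells >= 1, n_events >= 1, n_days >= 1,
            threshold > 0, w > 0, wind_sdlog >= 0,
            inherits(canopy, "canopy_params"),
            inherits(effect_model, "effect_model"),
            is.list(diurnal_params), is.list(grid_params))
  known_grid <- setdiff(names(formals(gen_urban_grid)), c("n_cells", "seed"))
  bad <- setdiff(names(grid_params), known_grid)
  if (length(bad)) stop("unknown grid_params key(s): ",
                        paste(bad, collapse = ", "))
  structure(list(seed = as.integer(seed), n_cells = as.integer(n_cells),
                 n_events = as.integer(n_events), n_days = as.integer(n_days),
                 scenarios = scenarios, threshold = threshold, w = w,
                 wind_sdlog = wind_sdlog, svi_bins = svi_bins,
                 canopy = canopy, effect_model = effect_model,
                 diurnal_params = diurnal_params, grid_params = grid_params),
            class = "run_config")
}

.scenario_label <- function(s) {
  if (s$strategy == "control") "control"
  else paste(s$strategy, s$intensity, sep = "_")
}

#' Run the full heat-equity experiment suite
#'
#' Orchestrates the end-to-end analysis on synthetic inputs: generates the
#' urban grid and per-event hourly forcing, applies every scenario,
#' evaluates midrange (subgrid-wind median) UTCI, accumulates hourly
#' heat-stress exceedances into per-cell daily cumulative heat stress (DCH)
#' over the whole day and separately over daytime (shortwave > 0) and
#' nighttime hours, averages over days and events into ADCH, and derives
#' per-cell VDCH against the control together with SVI-binned ADCH-change
#' curves and urban-averaged VDCH summaries per period.  Deterministic under
#' a fixed seed.
#'
#' @param config a [run_config()] object.
#' @return an object of class `heat_equity` with components `grid`,
#'   `adch` (cell x experiment x period array), `vdch` (same shape, percent),
#'   `summary` (experiment x period urban means), `curves` (per-experiment
#'   SVI-bin ADCH-change data.frames), `ranking` (experiments ordered by
#'   daytime urban VDCH), and `config`.
#' @seealso [heat_equity()] for the one-call interface,
#'   [write_report()] to export the result bundle.
#' @export
run_experiment_suite <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  grid <- do.call(gen_urban_grid,
                  c(list(n_cells = config$n_cells, seed = config$seed),
                    config$grid_params))
  mets <- lapply(seq_len(config$n_events), function(e)
    gen_met_forcing(grid, config$n_days, config$diurnal_params,
                    seed = config$seed + e))

  labels <- vapply(config$scenarios, .scenario_label, character(1))
  periods <- c("whole", "daytime", "nighttime")
  adch_arr <- array(NA_real_,
                    dim = c(nrow(grid), length(labels), length(periods)),
                    dimnames = list(NULL, labels, periods))

  for (s in seq_along(config$scenarios)) {
    # DCH per cell for every (event, day, period), then averaged into ADCH
    acc <- vector("list", length(periods))
    names(acc) <- periods
    for (e in seq_len(config$n_events)) {
      met <- apply_scenario_surrogate(mets[[e]], grid, config$scenarios[[s]],
                                      config$effect_model, config$canopy)
      u <- utci_percentiles(
        met$t2, met$rh2, met$ws10, met$mrt,
        wind_dist = list(family = "lognormal", sdlog = config$wind_sdlog))
      hs <- heat_stress(u$utci_p50, config$threshold)
      day <- met$sw_down > 0
      key <- interaction(met$cell_id, met$day, drop = FALSE)
      for (p in periods) {
        sel <- switch(p, whole = rep(TRUE, length(hs)),
                      daytime = day, nighttime = !day)
        dch_cd <- tapply(ifelse(sel, hs, 0), key, sum)
        acc[[p]] <- cbind(acc[[p]], matrix(dch_cd, nrow = nrow(grid)))
      }
    }
    for (p in periods) adch_arr[, s, p] <- rowMeans(acc[[p]])
  }

  ctl <- which(labels == "control")
  vdch_arr <- adch_arr
  vdch_arr[] <- NA_real_
  for (s in seq_along(labels)) for (p in periods) {
    vdch_arr[, s, p] <- suppressWarnings(
      vdch(adch_arr[, s, p], adch_arr[, ctl, p], grid$svi, config$w))
  }

  summary_df <- expand.grid(experiment = labels, period = periods,
                            stringsAsFactors = FALSE)
  summary_df$urban_vdch_pct <- mapply(function(lb, p)
    urban_average_vdch(vdch_arr[, lb, p], grid$is_urban),
    summary_df$experiment, summary_df$period)
  summary_df$urban_adch <- mapply(function(lb, p)
    mean(adch_arr[grid$is_urban, lb, p]),
    summary_df$experiment, summary_df$period)

  curves <- lapply(setdiff(labels, "control"), function(lb) {
    chg <- 100 * (adch_arr[, lb, "whole"] - adch_arr[, ctl, "whole"]) /
      adch_arr[, ctl, "whole"]
    adch_change_by_svi_bins(chg[grid$is_urban], grid$svi[grid$is_urban],
                            config$svi_bins)
  })
  names(curves) <- setdiff(labels, "control")

  day_rank <- summary_df[summary_df$period == "daytime" &
                           summary_df$experiment != "control", ]
  ranking <- day_rank$experiment[order(day_rank$urban_vdch_pct)]

  structure(list(grid = grid, adch = adch_arr, vdch = vdch_arr,
                 summary = summary_df, curves = curves, ranking = ranking,
                 config = config),
            class = "heat_equity")
}

#' One-call heat-equity analysis
#'
#' Convenience wrapper: builds a [run_config()] from its arguments and runs
#' [run_experiment_suite()].
#'
#' @param ... arguments passed to [run_config()].
#' @return a `heat_equity` object.
#' @examples
#' \donttest{
#' fit <- heat_equity(seed = 1, n_cells = 100, n_events = 1, n_days = 1,
#'                    scenarios = "high")
#' summary(fit)
#' }
#' @export
heat_equity <- function(...) run_experiment_suite(run_config(...))

#' @export
print.heat_equity <- function(x, ...) {
  cfg <- x$config
  cat("Heat-equity experiment suite\n")
  cat(sprintf("  %d cells, %d event(s) x %d day(s), threshold %g degC, w = %g, seed %d\n",
              cfg$n_cells, cfg$n_events, cfg$n_days, cfg$threshold, cfg$w,
              cfg$seed))
  cat("  experiments:", paste(dimnames(x$adch)[[2]], collapse = ", "), "\n")
  cat("  equity ranking (daytime urban VDCH, best first):\n")
  d <- x$summary[x$summary$period == "daytime", ]
  d <- d[match(x$ranking, d$experiment), ]
  for (i in seq_len(nrow(d)))
    cat(sprintf("    %d. %-18s %+.2f%%\n", i, d$experiment[i],
                d$urban_vdch_pct[i]))
  invisible(x)
}

#' @export
summary.heat_equity <- function(object, ...) {
  tab <- stats::reshape(object$summary[, c("experiment", "period",
                                           "urban_vdch_pct")],
                        idvar = "experiment", timevar = "period",
                        direction = "wide")
  names(tab) <- sub("urban_vdch_pct.", "", names(tab), fixed = TRUE)
  tab <- tab[tab$experiment != "control", ]
  rownames(tab) <- NULL
  structure(list(vdch_table = tab, ranking = object$ranking,
                 threshold = object$config$threshold),
            class = "summary.heat_equity")
}

#' @export
print.summary.heat_equity <- function(x, ...) {
  cat(sprintf("Urban-averaged VDCH (%%), UTCI threshold %g degC:\n",
              x$threshold))
  tab <- x$vdch_table
  tab[, -1] <- round(tab[, -1], 2)
  print.data.frame(tab, row.names = FALSE)
  cat("Equity ranking (daytime, best first):",
      paste(x$ranking, collapse = " > "), "\n")
  invisible(x)
}

#' Plot SVI-binned ADCH-change curves
#'
#' One panel per non-control experiment: median percent ADCH change per SVI
#' bin with interquartile-range error bars, the curve used to judge whether
#' a strategy's benefit grows or shrinks with neighborhood vulnerability.
#'
#' @param x a `heat_equity` object.
#' @param experiments experiments to draw (default: all non-control).
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.heat_equity <- function(x, experiments = names(x$curves), ...) {
  old <- graphics::par(mfrow = c(1, length(experiments)),
                       mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (lb in experiments) {
    cv <- x$curves[[lb]]
    ok <- !is.na(cv$median)
    ylim <- range(cv$q25[ok], cv$q75[ok], 0)
    graphics::plot(cv$bin_mid[ok], cv$median[ok], type = "b", pch = 19,
                   ylim = ylim, xlab = "SVI", ylab = "ADCH change (%)",
                   main = lb, ...)
    graphics::arrows(cv$bin_mid[ok], cv$q25[ok], cv$bin_mid[ok], cv$q75[ok],
                     angle = 90, code = 3, length = 0.03)
    graphics::abline(h = 0, lty = 3)
  }
  invisible(x)
}
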