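#' Read and write the package's plain-text interchange formats
#'
#' Station series, urban grids and meteorological fields travel as flat CSV
#' files; the met field uses a long format (one row per cell-hour) so that
#' arbitrary gridded hourly variables fit one schema.
#'
#' @param x object to write.
#' @param path file path.
#' @return the writers return `path` invisibly; the readers return the
#'   corresponding classed data.frame.
#' @name heatequity-io
NULL

#' @rdname heatequity-io
#' @export
write_station_series <- function(x, path) {
  stopifnot(inherits(x, "station_series"))
  utils::write.csv(data.frame(station_id = x$station_id,
                              date = format(x$date), tmax_c = x$tmax_c),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname heatequity-io
#' @export
read_station_series <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("station_id", "date", "tmax_c") %in% names(df)))
  df$date <- as.Date(df$date)
  if (anyNA(df$date)) stop("unparseable dates in ", path)
  structure(df, class = c("station_series", "data.frame"))
}

#' @rdname heatequity-io
#' @export
write_urban_grid <- function(x, path) {
  stopifnot(inherits(x, "urban_grid"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname heatequity-io
#' @export
read_urban_grid <- function(path) {
  df <- utils::read.csv(path)
  need <- c("cell_id", "svi", "street_fraction", "roof_fraction",
            "tree_cover", "tc_added_target", "is_urban")
  stopifnot(all(need %in% names(df)))
  df$is_urban <- as.logical(df$is_urban)
  structure(df, class = c("urban_grid", "data.frame"))
}

#' @rdname heatequity-io
#' @export
write_met_field <- function(x, path) {
  stopifnot(inherits(x, "met_field"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname heatequity-io
#' @export
read_met_field <- function(path) {
  df <- utils::read.csv(path)
  need <- c("cell_id", "day", "hour", "t2", "rh2", "ws10", "mrt", "sw_down")
  stopifnot(all(need %in% names(df)))
  structure(df, class = c("met_field", "data.frame"))
}

#' Export a heat-equity result bundle
#'
#' Writes the per-cell metrics, the SVI-bin curves, and the urban-averaged
#' summary of a [run_experiment_suite()] result to a directory as CSV and
#' JSON, so a run is inspectable and resumable stage by stage.
#'
#' @param x a `heat_equity` object.
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_report <- function(x, dir) {
  stopifnot(inherits(x, "heat_equity"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_urban_grid(x$grid, file.path(dir, "urban_grid.csv"))

  labels <- dimnames(x$adch)[[2]]
  per_cell <- do.call(rbind, lapply(labels, function(lb) {
    do.call(rbind, lapply(dimnames(x$adch)[[3]], function(p)
      data.frame(cell_id = x$grid$cell_id, experiment = lb, period = p,
                 svi = x$grid$svi, adch = x$adch[, lb, p],
                 vdch_pct = x$vdch[, lb, p])))
  }))
  utils::write.csv(per_cell, file.path(dir, "metrics_per_cell.csv"),
                   row.names = FALSE)

  curves <- do.call(rbind, lapply(names(x$curves), function(lb)
    cbind(experiment = lb, x$curves[[lb]])))
  utils::write.csv(curves, file.path(dir, "svi_bin_curves.csv"),
                   row.names = FALSE)

  utils::write.csv(x$summary, file.path(dir, "summary.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(seed = x$config$seed, threshold = x$config$threshold,
         w = x$config$w, ranking = x$ranking,
         urban_vdch = split(x$summary$urban_vdch_pct,
                            list(x$summary$experiment, x$summary$period))),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
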