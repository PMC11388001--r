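#' Mitigation scenario specification
#'
#' Defines one of the seven experiments: a control and three mitigation
#' strategies (cool roofs, green roofs, urban street trees), each at low and
#' high intensity.  Parameter values follow the simulation-case design:
#' control roof albedo 0.19 with no green roofs and observed tree cover;
#' cool roofs raise roof albedo to 0.55 (low) or 0.70 (high); green roofs
#' cover 30% (low) or 80% (high) of the roof area; urban trees add 50% (low)
#' or 100% (high) of the tree-equity-targeted tree-cover increment.
#'
#' @param strategy one of `"control"`, `"cool_roof"`, `"green_roof"`,
#'   `"urban_trees"`.
#' @param intensity `"low"` or `"high"` (ignored for control).
#' @return an object of class `scenario_spec` with fields `strategy`,
#'   `intensity`, `roof_albedo`, `green_roof_coverage`,
#'   `tc_target_multiplier`.
#' @examples
#' scenario_spec("cool_roof", "high")
#' @export
scenario_spec <- function(strategy = c("control", "cool_roof", "green_roof",
                                       "urban_trees"),
                          intensity = c("high", "low")) {
  strategy <- match.arg(strategy)
  intensity <- match.arg(intensity)
  spec <- list(strategy = strategy,
               intensity = if (strategy == "control") "none" else intensity,
               roof_albedo = 0.19, green_roof_coverage = 0,
               tc_target_multiplier = 0)
  if (strategy == "cool_roof")
    spec$roof_albedo <- if (intensity == "low") 0.55 else 0.70
  if (strategy == "green_roof")
    spec$green_roof_coverage <- if (intensity == "low") 0.30 else 0.80
  if (strategy == "urban_trees")
    spec$tc_target_multiplier <- if (intensity == "low") 0.5 else 1.0
  structure(spec, class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("Scenario: %s (%s)\n", x$strategy, x$intensity))
  cat(sprintf("  roof albedo %.2f | green roof coverage %.0f%% | tc multiplier %.1f\n",
              x$roof_albedo, 100 * x$green_roof_coverage,
              x$tc_target_multiplier))
  invisible(x)
}

#' Surrogate effect-model parameters for the roof strategies
#'
#' The link from a roof-albedo or green-roof-coverage change to the 2-m
#' fields is emergent from the full urban-canopy physics and has no closed
#' form; the rooftop strategies are therefore represented by linear
#' surrogates whose sensitivities are free parameters.  The defaults are
#' calibrated so that, under the default synthetic forcing, the
#' urban-average daytime UTCI reductions of the high scenarios fall in the
#' 0.2--0.3 K range with cool roofs strongest, then trees, then green roofs.
#'
#' @param cool_t2_per_alb daytime 2-m cooling at full sun per unit
#'   (roof fraction x roof-albedo increase), K.
#' @param green_t2_per_cov daytime 2-m cooling at full sun per unit
#'   (roof fraction x green-roof coverage), K.
#' @param green_night_warming nighttime 2-m warming per unit (roof fraction
#'   x coverage), K; active only when shortwave is zero (stored daytime heat
#'   released after dark).
#' @param rh_per_t2 relative-humidity response to a 2-m temperature change,
#'   percent per K of cooling (cooler air at fixed vapour content is more
#'   humid).
#' @param sw_ref shortwave flux treated as full sun, W/m2.
#' @return named list of class `effect_model`.
#' @export
default_effect_model <- function(cool_t2_per_alb = 1.6,
                                 green_t2_per_cov = 0.75,
                                 green_night_warming = 0.10,
                                 rh_per_t2 = 2.5,
                                 sw_ref = 950) {
  structure(list(cool_t2_per_alb = cool_t2_per_alb,
                 green_t2_per_cov = green_t2_per_cov,
                 green_night_warming = green_night_warming,
                 rh_per_t2 = rh_per_t2, sw_ref = sw_ref),
            class = "effect_model")
}

#' Apply a mitigation scenario to the meteorological forcing
#'
#' Perturbs the control forcing according to the scenario.  The rooftop
#' strategies act through the linear surrogate of [default_effect_model()]:
#' cool and green roofs cool the daytime 2-m temperature in proportion to
#' the cell's roof fraction, the strategy magnitude (albedo increase or
#' coverage), and instantaneous solar forcing, with a matching
#' relative-humidity increase; green roofs additionally warm the nighttime
#' 2-m temperature (heat stored by the soil layer by day, released after
#' dark).  The urban-trees strategy leaves the 2-m fields untouched and acts
#' on the mean radiant temperature: the added street-tree cover intercepts
#' shortwave per Beer's law ([sw_ground()]), and the cell-mean reduction in
#' ground-level shortwave (scaled by street fraction, since trees occupy
#' streets) is converted to an MRT change by [mrt_adjustment()].  The
#' control scenario returns the forcing unchanged.
#'
#' @param met a `met_field` from [gen_met_forcing()].
#' @param grid the matching `urban_grid`.
#' @param scenario a [scenario_spec()].
#' @param effect_model a [default_effect_model()] list.
#' @param canopy a [canopy_params()] object (tree pathway and its MRT
#'   sensitivity).
#' @param albedo_ctl control roof albedo against which cool-roof changes are
#'   measured.
#' @return the perturbed `met_field`.
#' @export
apply_scenario_surrogate <- function(met, grid, scenario,
                                     effect_model = default_effect_model(),
                                     canopy = canopy_params(),
                                     albedo_ctl = 0.19) {
  stopifnot(inherits(met, "met_field"), inherits(grid, "urban_grid"),
            inherits(scenario, "scenario_spec"))
  if (!all(met$cell_id %in% grid$cell_id))
    stop("met field refers to cells absent from the grid")
  if (scenario$strategy == "control") return(met)
  i <- match(met$cell_id, grid$cell_id)
  roof <- grid$roof_fraction[i]
  em <- effect_model
  relsw <- met$sw_down / em$sw_ref

  if (scenario$strategy == "cool_roof") {
    dalb <- scenario$roof_albedo - albedo_ctl
    dt2 <- -em$cool_t2_per_alb * roof * dalb * relsw
  } else if (scenario$strategy == "green_roof") {
    cov <- scenario$green_roof_coverage
    dt2 <- -em$green_t2_per_cov * roof * cov * relsw +
      em$green_night_warming * roof * cov * (met$sw_down == 0)
  } else if (scenario$strategy == "urban_trees") {
    tc_ctl <- grid$tree_cover[i]
    tc_new <- pmin(tc_ctl + scenario$tc_target_multiplier *
                     grid$tc_added_target[i], 1)
    zen <- solar_zenith(met$hour)
    trans <- canopy_transmission(canopy, zen)
    # ground shortwave reduction per unit street area, Beer's-law interception
    dsw_street <- met$sw_down * (tc_new - tc_ctl) * (1 - trans)
    dsw_cell <- grid$street_fraction[i] * dsw_street
    met$mrt <- met$mrt + mrt_adjustment(dsw_cell, canopy$mrt_sensitivity)
    attr(met, "scenario") <- scenario
    return(met)
  } else stop("unknown strategy: ", scenario$strategy)

  met$t2 <- met$t2 + dt2
  met$rh2 <- pmin(pmax(met$rh2 - em$rh_per_t2 * dt2, 0), 100)
  attr(met, "scenario") <- scenario
  met
}
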