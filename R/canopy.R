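#' Street-tree canopy radiation parameters
#'
#' Bundles the constants of the Beer's-law shortwave interception scheme for
#' street trees and its Bowen-ratio energy partition.  Defaults follow the
#' values used for Houston-like evergreen broadleaf street trees: clumping
#' coefficient `omega = 0.5`, leaf-orientation factor `g = 0.5`, leaf area
#' index `lai = 3`, and Bowen ratio `bowen_beta = 2` (sensible:latent = 2:1).
#' `mrt_sensitivity` converts a reduction in shortwave reaching the ground to
#' a mean-radiant-temperature change (K per W/m2); see [mrt_adjustment()].
#'
#' @param omega empirical clumping coefficient, in (0, 1].
#' @param g leaf orientation angle distribution factor, in (0, 1].
#' @param lai leaf area index of the street-tree canopy, >= 0.
#' @param bowen_beta Bowen ratio of the foliage, > -1.
#' @param mrt_sensitivity MRT response to ground shortwave reduction,
#'   K per W/m2, >= 0.
#' @return an object of class `canopy_params`.
#' @export
canopy_params <- function(omega = 0.5, g = 0.5, lai = 3, bowen_beta = 2,
                          mrt_sensitivity = 0.066) {
  stopifnot(is.numeric(omega), omega > 0, omega <= 1,
            is.numeric(g), g > 0, g <= 1,
            is.numeric(lai), lai >= 0,
            is.numeric(bowen_beta), bowen_beta > -1,
            is.numeric(mrt_sensitivity), mrt_sensitivity >= 0)
  structure(list(omega = omega, g = g, lai = lai, bowen_beta = bowen_beta,
                 mrt_sensitivity = mrt_sensitivity),
            class = "canopy_params")
}

#' @export
print.canopy_params <- function(x, ...) {
  cat("Street-tree canopy parameters\n")
  cat(sprintf("  clumping omega: %.3g   leaf orientation G: %.3g\n",
              x$omega, x$g))
  cat(sprintf("  LAI: %.3g   Bowen ratio: %.3g   MRT sensitivity: %.3g K/(W/m2)\n",
              x$lai, x$bowen_beta, x$mrt_sensitivity))
  invisible(x)
}

#' Beer's-law canopy shortwave transmission
#'
#' Fraction of direct shortwave transmitted through the tree canopy,
#' `exp(-omega * G * LAI / cos(zenith))`.  When the sun is at or below the
#' horizon (`zenith >= pi/2`) the transmitted fraction is 0 by convention:
#' there is no direct beam to transmit and the path-length term diverges.
#'
#' @param params a [canopy_params()] object.
#' @param zenith solar zenith angle in radians, vectorised; must be >= 0.
#' @return transmitted fraction in \[0, 1\].
#' @examples
#' canopy_transmission(canopy_params(), zenith = 0)  # exp(-0.75)
#' @export
canopy_transmission <- function(params, zenith) {
  stopifnot(inherits(params, "canopy_params"), is.numeric(zenith),
            all(is.finite(zenith)), all(zenith >= 0))
  tr <- numeric(length(zenith))
  up <- zenith < pi / 2
  tr[up] <- exp(-params$omega * params$g * params$lai / cos(zenith[up]))
  tr
}

#' Shortwave reaching the ground under partial tree cover
#'
#' Mixes the tree-free ground shortwave with the under-canopy shortwave by
#' tree-cover fraction: `SWground = (1 - tc) * SWgroundsun + tc *
#' SWgroundtree`, where `SWgroundtree` is the Beer's-law transmitted flux.
#' The energy intercepted by the foliage is `enloss = SWgroundsun - SWground`.
#'
#' @param sw_ground_sun tree-free shortwave flux at the ground, W/m2, >= 0.
#' @param tc tree-cover fraction in \[0, 1\].
#' @param params a [canopy_params()] object.
#' @param zenith solar zenith angle in radians.
#' @return a data.frame of class `radiation_state` with columns
#'   `sw_ground_sun`, `zenith`, `tc`, `sw_ground_tree`, `sw_ground`,
#'   `enloss`.
#' @export
sw_ground <- function(sw_ground_sun, tc, params = canopy_params(),
                      zenith = 0) {
  if (!is.numeric(tc) || any(tc < 0 | tc > 1))
    stop("'tc' must lie in [0, 1]")
  if (!is.numeric(sw_ground_sun) || any(sw_ground_sun < 0))
    stop("'sw_ground_sun' must be non-negative")
  n <- max(length(sw_ground_sun), length(tc), length(zenith))
  sw_ground_sun <- rep_len(sw_ground_sun, n)
  tc <- rep_len(tc, n); zenith <- rep_len(zenith, n)
  trans <- canopy_transmission(params, zenith)
  sw_tree <- sw_ground_sun * trans
  sw <- (1 - tc) * sw_ground_sun + tc * sw_tree
  structure(
    data.frame(sw_ground_sun = sw_ground_sun, zenith = zenith, tc = tc,
               sw_ground_tree = sw_tree, sw_ground = sw,
               enloss = sw_ground_sun - sw),
    class = c("radiation_state", "data.frame"))
}

#' Bowen-ratio partition of canopy-intercepted energy
#'
#' Splits the shortwave energy intercepted by the foliage into latent heat
#' (transpiration) and sensible heat using a fixed Bowen ratio:
#' `LH = enloss / (beta + 1)` and `SH = beta * enloss / (beta + 1)`, so
#' `LH + SH = enloss` exactly and `SH / LH = beta`.  Net longwave exchange of
#' the foliage is taken as zero, so interception and turbulent release
#' balance.
#'
#' @param state a `radiation_state` from [sw_ground()] (or any data.frame
#'   with an `enloss` column).
#' @param beta Bowen ratio, > -1; defaults to the value carried by `params`.
#' @param params a [canopy_params()] object supplying the default `beta`.
#' @return `state` with columns `lh_tree` and `sh_tree` added.
#' @export
tree_energy_partition <- function(state, beta = params$bowen_beta,
                                  params = canopy_params()) {
  stopifnot(is.data.frame(state), "enloss" %in% names(state))
  if (!is.numeric(beta) || beta <= -1) stop("'beta' must exceed -1")
  state$lh_tree <- state$enloss / (beta + 1)
  state$sh_tree <- beta * state$enloss / (beta + 1)
  state
}

#' Linear mean-radiant-temperature response to canopy shading
#'
#' The in-canyon radiative geometry that maps shortwave at the ground to the
#' mean radiant temperature a pedestrian experiences is not modelled here;
#' the tree scenario instead applies a linear response: a reduction of the
#' shortwave reaching the ground by `delta_sw_ground` W/m2 cools the MRT by
#' `sensitivity * delta_sw_ground` K.  With the default sensitivity a
#' 200 W/m2 shading reduction gives several K of MRT cooling, the order of
#' magnitude observed for midday road surfaces under added canopy.
#'
#' @param delta_sw_ground reduction in shortwave reaching the ground, W/m2
#'   (positive = less shortwave at the ground).
#' @param sensitivity MRT change per unit shortwave reduction, K per W/m2,
#'   >= 0.
#' @return MRT change in K (negative when shortwave is reduced).
#' @examples
#' mrt_adjustment(200, sensitivity = 0.025)  # -5 K
#' @export
mrt_adjustment <- function(delta_sw_ground,
                           sensitivity = canopy_params()$mrt_sensitivity) {
  stopifnot(is.numeric(sensitivity), sensitivity >= 0)
  -sensitivity * delta_sw_ground
}
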