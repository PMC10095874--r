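#' Convert timber volume to tons of carbon
#'
#' Standard stock conversion: volume times wood density times a biomass
#' expansion factor times the carbon fraction of dry matter. The carbon
#' fraction defaults to the conventional 0.5; density and expansion factors
#' are species/region specific and must be supplied.
#'
#' @param timber_volume_m3 Standing volume (m3).
#' @param wood_density Basic wood density (t dry matter / m3).
#' @param expansion_factor Biomass expansion factor (dimensionless > 0).
#' @param carbon_fraction Carbon fraction of dry matter, default 0.5.
#' @return Carbon stock, tC.
#' @export
biomass_to_carbon <- function(timber_volume_m3, wood_density = 0.5,
                              expansion_factor = 1.3,
                              carbon_fraction = 0.5) {
  if (any(c(wood_density, expansion_factor, carbon_fraction) <= 0))
    stop_encar("conversion factors must be positive")
  timber_volume_m3 * wood_density * expansion_factor * carbon_fraction
}

#' Net ecosystem production
#'
#' NEP = NPP - heterotrophic respiration. May be negative (source zones);
#' when used as the accessible bio-carbon resource it is floored at zero by
#' [nep_accessible()], while the raw value is kept for diagnostics.
#'
#' @param npp Net primary production, tC/yr (>= 0).
#' @param rh Heterotrophic respiration, tC/yr (>= 0).
#' @return NEP, tC/yr.
#' @export
nep <- function(npp, rh) {
  if (any(npp < 0) || any(rh < 0))
    stop_encar("NPP and heterotrophic respiration must be non-negative")
  npp - rh
}

#' @rdname nep
#' @param x Raw NEP value(s).
#' @return `nep_accessible()`: `max(0, x)`.
#' @export
nep_accessible <- function(x) pmax(x, 0)

#' Bio-carbon use record
#'
#' Total use is the sum of harvested crops, wood removals and withdrawals of
#' animals, all expressed in tC/yr.
#'
#' @param crops_harvest,wood_removals,animal_withdrawals Non-negative
#'   components, tC/yr.
#' @return Object of class `carbon_use` with `total`.
#' @export
carbon_use <- function(crops_harvest = 0, wood_removals = 0,
                       animal_withdrawals = 0) {
  if (any(c(crops_harvest, wood_removals, animal_withdrawals) < 0))
    stop_encar("carbon use components must be non-negative")
  structure(list(crops_harvest = crops_harvest,
                 wood_removals = wood_removals,
                 animal_withdrawals = animal_withdrawals,
                 total = crops_harvest + wood_removals + animal_withdrawals),
            class = "carbon_use")
}

#' Carbon intensity-of-use index (raw)
#'
#' Accessible NEP divided by total use. Values below 1 mean use exceeds
#' ecosystem production (degradation); zero use returns `Inf` as the
#' no-depletion sentinel, capped to 1 by the capability layer.
#'
#' @param nep_accessible Accessible NEP, tC/yr (>= 0).
#' @param use A `carbon_use` object or a bare non-negative total, tC/yr.
#' @return Raw index (ratio, possibly `Inf`).
#' @export
carbon_intensity_index <- function(nep_accessible, use) {
  tot <- if (inherits(use, "carbon_use")) use$total else use
  if (any(nep_accessible < 0)) stop_encar("accessible NEP must be >= 0")
  if (any(tot < 0)) stop_encar("use must be non-negative")
  ifelse(tot == 0, Inf, nep_accessible / tot)
}

#' Bio-carbon use as a fraction of the accessible resource
#'
#' The reciprocal of the intensity index, reported as a percentage of
#' accessible NEP.
#'
#' @param use A `carbon_use` or bare total, tC/yr.
#' @param nep_accessible Accessible NEP, tC/yr (> 0).
#' @return Percentage of the accessible resource used.
#' @export
use_fraction <- function(use, nep_accessible) {
  tot <- if (inherits(use, "carbon_use")) use$total else use
  if (any(nep_accessible <= 0))
    stop_encar("use_fraction requires a positive accessible NEP")
  100 * tot / nep_accessible
}

#' Livestock counts to carbon withdrawals
#'
#' @param head Livestock head count.
#' @param tc_per_head_yr Withdrawal coefficient, tC/head/yr (default a
#'   cattle-scale 0.15).
#' @return tC/yr.
#' @export
animal_withdrawal <- function(head, tc_per_head_yr = 0.15) {
  if (any(head < 0) || any(tc_per_head_yr < 0))
    stop_encar("head counts and coefficients must be non-negative")
  head * tc_per_head_yr
}
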