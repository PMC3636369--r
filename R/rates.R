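# First-order rate-coefficient primitives for the six flux classes of the
# compartment model: geosphere release, water fluxes, gas fluxes, particle
# fluxes, wetland growth, and biological uptake/decomposition. All rates act
# on total compartment inventories (Bq) assuming instantaneous equilibrium
# between pore water and solids quantified by Kd.

# distribution capacity of a compartment in m3 water-equivalents:
# dissolved + sorbed storage per unit pore-water concentration
capacity <- function(water_volume, kd, solid_mass) water_volume + kd * solid_mass

# flux/capacity with a 0/0 guard: zero flux never moves anything, and a
# positive flux out of a zero-capacity compartment is a configuration error
rate_or_zero <- function(flux, cap, what = "flux") {
  if (flux < 0) stop(sprintf("negative %s", what), call. = FALSE)
  if (flux == 0) return(0)
  if (cap <= 0) stop(sprintf("positive %s out of a zero-capacity compartment", what), call. = FALSE)
  flux / cap
}

#' Dissolved fraction under Kd equilibrium
#'
#' Fraction of a compartment's inventory residing in pore water when the
#' water/solid partitioning is at equilibrium with distribution
#' coefficient Kd. The sorbed fraction is its complement.
#'
#' @param kd distribution coefficient, m3/kg dw, >= 0.
#' @param solid_mass solid mass of the compartment, kg dw.
#' @param water_volume pore (or free) water volume, m3.
#' @return fraction in `[0, 1]`.
#' @export
dissolved_fraction <- function(kd, solid_mass, water_volume) {
  check_scalar(kd, "kd", min = 0); check_scalar(solid_mass, "solid_mass", min = 0)
  check_scalar(water_volume, "water_volume", min = 0)
  cap <- capacity(water_volume, kd, solid_mass)
  if (cap <= 0) stop("compartment has zero water and zero sorption capacity", call. = FALSE)
  water_volume / cap
}

#' Advective transfer rate
#'
#' First-order rate moving the dissolved share of a compartment's
#' inventory with a water flux; sorption retards transport by inflating
#' the denominator (retardation).
#'
#' @param flux water flux out of the source compartment, m3/a, >= 0.
#' @param water_volume source pore-water volume, m3.
#' @param kd source Kd, m3/kg dw.
#' @param solid_mass source solid mass, kg dw.
#' @return rate in /a: `flux / (water_volume + kd * solid_mass)`.
#' @export
advective_rate <- function(flux, water_volume, kd = 0, solid_mass = 0) {
  check_scalar(flux, "flux", min = 0)
  rate_or_zero(flux, capacity(water_volume, kd, solid_mass), "water flux")
}

#' Diffusive exchange rates between adjacent compartments
#'
#' Symmetric exchange driven by the pore-water concentration difference:
#' conductance G = diffusivity * area / length (m3/a) acts on pore-water
#' concentrations, so the per-inventory rates are G over each side's
#' distribution capacity. At equal pore-water concentrations net flux is
#' zero.
#'
#' @param diffusivity effective diffusivity, m2/a.
#' @param area contact area, m2.
#' @param length diffusion path length, m, > 0.
#' @param cap_i,cap_j distribution capacities (m3-equivalents) of the two
#'   compartments, > 0 where the conductance is non-zero.
#' @return numeric c(k_i_to_j, k_j_to_i) in /a.
#' @export
diffusive_rates <- function(diffusivity, area, length, cap_i, cap_j) {
  check_scalar(diffusivity, "diffusivity", min = 0)
  check_scalar(area, "area", min = 0)
  check_scalar(length, "length", min = 0, strict = TRUE)
  G <- diffusivity * area / length
  c(rate_or_zero(G, cap_i, "diffusive conductance"),
    rate_or_zero(G, cap_j, "diffusive conductance"))
}

#' Sedimentation and resuspension rates
#'
#' Sedimentation moves the particle-sorbed share of the water-column
#' inventory to the upper sediment; resuspension returns the sorbed share
#' of the upper-sediment inventory to the water column.
#'
#' @param sedimentation_flux gross sedimentation, kg dw/m2/a.
#' @param resuspension_flux resuspension, kg dw/m2/a.
#' @param area aquatic area, m2.
#' @param water_volume water-column volume, m3.
#' @param suspended_mass suspended solids in the water column, kg dw.
#' @param kd_water Kd of suspended particles, m3/kg.
#' @param sediment_mass solid mass of the upper sediment, kg dw.
#' @param sediment_water pore-water volume of the upper sediment, m3.
#' @param kd_sed Kd of the sediment, m3/kg.
#' @return numeric c(k_sed, k_res) in /a.
#' @export
particle_rates <- function(sedimentation_flux, resuspension_flux, area,
                           water_volume, suspended_mass, kd_water,
                           sediment_mass, sediment_water, kd_sed) {
  check_scalar(sedimentation_flux, "sedimentation_flux", min = 0)
  check_scalar(resuspension_flux, "resuspension_flux", min = 0)
  k_sed <- rate_or_zero(sedimentation_flux * area * kd_water,
                        capacity(water_volume, kd_water, suspended_mass),
                        "sedimentation flux")
  if (resuspension_flux > 0 && sediment_mass <= 0)
    stop("resuspension from a sediment with no solid mass", call. = FALSE)
  k_res <- if (resuspension_flux == 0) 0 else {
    sorbed_sed <- 1 - dissolved_fraction(kd_sed, sediment_mass, sediment_water)
    resuspension_flux * area / sediment_mass * sorbed_sed
  }
  c(k_sed = k_sed, k_res = k_res)
}

#' Biological uptake and return rates
#'
#' Uptake into primary producers is driven by primary production: the flux
#' of radionuclides into newly produced biomass is production (kg C/a)
#' times CR times the concentration of the environmental medium, expressed
#' here as a first-order rate on the medium inventory. The return flux is
#' biomass turnover, production/biomass, on the producer inventory.
#'
#' @param production primary production, kg C/a, >= 0.
#' @param biomass standing producer biomass, kg C, > 0 if production > 0.
#' @param cr concentration ratio (medium-specific basis), >= 0.
#' @param medium_denominator denominator converting the medium inventory to
#'   the concentration CR refers to: solid mass (kg dw) for terrestrial
#'   producers, water volume (m3) for aquatic producers.
#' @return numeric c(k_uptake, k_return) in /a.
#' @export
biota_rates <- function(production, biomass, cr, medium_denominator) {
  check_scalar(production, "production", min = 0)
  if (cr < 0) stop("negative CR", call. = FALSE)
  if (production == 0) return(c(k_uptake = 0, k_return = 0))
  if (biomass <= 0) stop("positive production requires positive biomass", call. = FALSE)
  k_up <- rate_or_zero(production * cr, medium_denominator, "uptake flux")
  c(k_uptake = k_up, k_return = production / biomass)
}

#' Gas exchange rates
#'
#' Element-specific degassing from surface water and upper terrestrial
#' regolith to the object atmosphere, and ventilation of the atmosphere
#' box to an external sink.
#'
#' @param degassing_rate element-specific volatilisation rate, /a (zero for
#'   non-volatile elements).
#' @param atmosphere_turnover ventilation rate of the atmosphere box, /a.
#' @return numeric c(k_degas, k_vent) in /a.
#' @export
gas_rates <- function(degassing_rate, atmosphere_turnover) {
  check_scalar(degassing_rate, "degassing_rate", min = 0)
  check_scalar(atmosphere_turnover, "atmosphere_turnover", min = 0)
  c(k_degas = degassing_rate, k_vent = atmosphere_turnover)
}

#' Wetland growth (lake infilling) rate
#'
#' As the aquatic area of an object shrinks, the annexed fraction of the
#' lake/sea bed carries its radionuclide inventory from the aquatic
#' regolith layers into the corresponding terrestrial layers.
#'
#' @param aquatic_area current aquatic area, m2, > 0 for an active rate.
#' @param daq_dt time derivative of the aquatic area, m2/a.
#' @return rate in /a: `max(0, -daq_dt) / aquatic_area`; zero when the area
#'   is constant or growing, and zero for a fully terrestrial object.
#' @export
wetland_growth_rate <- function(aquatic_area, daq_dt) {
  check_scalar(aquatic_area, "aquatic_area", min = 0)
  shrink <- max(0, -daq_dt)
  if (shrink == 0 || aquatic_area <= 0) return(0)
  shrink / aquatic_area
}
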