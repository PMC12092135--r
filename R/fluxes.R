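# Oxygen input and output fluxes with their fractionation factors.
#
# All flux amounts are moles of oxygen ATOMS over the measurement window.
# Two deliberately rounded physical constants are used by default so that
# results match the published parameterization they mirror:
# 5.38e19 oxygen atoms per ml O2 (= 2 x 2.69e19 molecules/ml by the ideal gas
# law) and 22.4 l/mol; rounded_constants = FALSE switches the Avogadro
# number and molar volume to CODATA values.

O_ATOMS_PER_ML_O2 <- 5.38e19
ATM_O2_FRACTION <- 0.21
KG_TO_MOL_WATER <- 55.56
MMHG_PER_KPA <- 7.50062
MOL_O_PER_KG_CARB <- 11.12   # 2 of 6 glucose oxygens appear in condensation water
# decarboxylation: remaining 4 of 6 glucose oxygens (22.24 = 2 x 11.12),
# all bound oxygen of fat (4 mol/kg) and protein (6 mol/kg) exchanges with
# body water via CO2; urea exports 12 mol O per kg protein
MOL_O_DECARB_CARB <- 22.24
MOL_O_DECARB_FAT <- 4
MOL_O_DECARB_PROTEIN <- 6
MOL_O_UREA_PER_KG_PROTEIN <- 12

avogadro <- function(p) if (p$rounded_constants) 6.03e23 else 6.02214076e23
molar_volume_l <- function(p) if (p$rounded_constants) 22.4 else 22.41397

input_flux_names <- c("drinking_water", "food_water", "oxidase_water",
                      "inhaled_vapour", "condensation_water",
                      "decarboxylation_oxygen")
output_flux_names <- c("faecal_bound", "faecal_water", "transcutaneous",
                       "oral_vapour", "nasal_vapour", "exhaled_co2",
                       "urea_oxygen", "urinary_water")

# saturation vapour pressure (mmHg) from the 10^(0.686 + 0.027 T) expression;
# T is in Celsius unless the audit flag asks for the literal Kelvin reading
sat_vap_mmHg <- function(temp_C, unit = "C") {
  t <- if (identical(unit, "K")) temp_C + 273.15 else temp_C
  10^(0.686 + 0.027 * t)
}

# litres of air fluxed through the lungs over the window
lung_air_litres <- function(params, totals) {
  mol_o2 <- totals$o2_ml / (molar_volume_l(params) * 1000)
  mol_o2 / params$ouf / ATM_O2_FRACTION * molar_volume_l(params)
}

#' Fractionation factors of the model fluxes
#'
#' Computes the 18/16 fractionation factor, triple-isotope exponent theta and
#' derived 17/16 factor for every model flux. Non-fractionating fluxes
#' (drinking water, food water, faecal water, urea, urinary water) carry
#' alpha = 1.
#'
#' The fractionating components are: oxidase water (from the z-value and OUF),
#' inhaled vapour (liquid-vapour equilibrium at ambient temperature), bound
#' dietary oxygen (ingredient-weighted cellulose/pre-formed-water ratio),
#' transcutaneous loss (fixed alpha), oral and nasal vapour loss
#' (liquid-vapour equilibrium at body and mid body-ambient temperature) and
#' exhaled CO2 (CO2-water equilibrium at body temperature).
#'
#' @param params a [flux_params()] object.
#' @return a data frame with columns `flux`, `alpha18`, `theta`, `alpha17`.
#' @examples
#' ff <- fractionation_factors(flux_params())
#' ff[ff$flux == "oxidase_water", ]   # alpha18 about 0.994
#' @export
fractionation_factors <- function(params) {
  p <- params
  TaK <- p$ambient_temp_C + 273.15
  TbK <- p$body_temp_C + 273.15
  TmK <- (TbK + TaK) / 2

  a_ox <- if (!is.na(p$alpha18_oxidase)) p$alpha18_oxidase else
    (1000 + (p$atmospheric_O2$d18O_permil - p$z_value_permil) / (1 - p$ouf)) /
      (1000 + p$atmospheric_O2$d18O_permil)
  eq_alpha <- function(TK) exp((11.36e5 / TK^2 - 4.2e2 / TK - 2.07) / 1000)
  a_vap <- if (p$vapour_alpha_direction == "deplete") 1 / eq_alpha(TaK) else eq_alpha(TaK)
  a_bound <- sum(p$cellulose$weight * (1000 + p$cellulose$d18O_permil)) /
    (1000 + p$preformed_water$d18O_permil)
  a_oral <- 1 / eq_alpha(TbK)
  a_nasal <- 1 / eq_alpha(TmK)
  a_co2 <- exp((1.66e4 / TbK - 15.69) / 1000)

  out <- data.frame(
    flux = c(input_flux_names, output_flux_names),
    alpha18 = c(1, 1, a_ox, a_vap, a_bound, a_bound,
                1, 1, p$alpha18_transcutaneous, a_oral, a_nasal, a_co2, 1, 1),
    theta = c(1, 1, p$theta[["oxidase"]], p$theta[["vapour_equilibrium"]],
              p$theta[["bound_oxygen"]], p$theta[["bound_oxygen"]],
              1, 1, p$theta[["transcutaneous"]], p$theta[["oral"]],
              p$theta[["nasal"]], p$theta[["co2"]], 1, 1),
    stringsAsFactors = FALSE)
  out$alpha17 <- alpha17_from_theta(out$alpha18, out$theta)
  out
}

#' Vapour pressure deficit
#'
#' Tetens-form saturation vapour pressure scaled by the relative-humidity
#' deficit: the drying power of air that drives transcutaneous water loss.
#'
#' @param ambient_temp_C air temperature in degrees C.
#' @param rel_humidity relative humidity, fraction in `[0, 1]`.
#' @return a list with elements `kPa` and `mmHg`.
#' @examples
#' vapour_pressure_deficit(25, 0.45)$mmHg   # about 13.1
#' @export
vapour_pressure_deficit <- function(ambient_temp_C, rel_humidity) {
  if (any(rel_humidity < 0 | rel_humidity > 1))
    stop("rel_humidity must be in [0, 1]", call. = FALSE)
  kPa <- (610.78 * exp(ambient_temp_C / (ambient_temp_C + 237.3) * 17.2694) /
            1000) * (1 - rel_humidity)
  list(kPa = kPa, mmHg = kPa * MMHG_PER_KPA)
}

#' Oxygen input fluxes
#'
#' Computes the six oxygen inputs (moles of oxygen atoms over the window) with
#' their source pools and fractionation factors: drinking water, free water in
#' food, oxidase (metabolic) water from inhaled O2, inhaled atmospheric water
#' vapour, condensation water and decarboxylation oxygen from bound dietary
#' oxygen.
#'
#' @param params a [flux_params()] object.
#' @param totals a [flux_totals()] object.
#' @return a data frame with columns `name`, `role`, `moles_O`, `source`,
#'   `alpha18`, `theta`, `alpha17`.
#' @export
input_fluxes <- function(params, totals) {
  p <- params
  stopifnot(inherits(totals, "flux_totals"))
  leak_factor <- if (totals$water_leak_corrected) 1 else 1 - p$water_leakage
  drinking <- totals$water_ml * leak_factor / 18
  food_water <- totals$food_kg * KG_TO_MOL_WATER /
    (1 - p$food_water_content) * p$food_water_content
  oxidase <- totals$o2_ml * O_ATOMS_PER_ML_O2 / avogadro(p)
  lair <- lung_air_litres(p, totals)
  vapour <- p$rel_humidity *
    sat_vap_mmHg(p$ambient_temp_C, p$eq_sat_vap_temp_unit) / 760 /
    molar_volume_l(p) * lair
  DE <- p$digestibility * p$energy_extraction
  condensation <- totals$food_kg * (p$f_carb * MOL_O_PER_KG_CARB) * DE
  decarbox <- totals$food_kg * (p$f_carb * MOL_O_DECARB_CARB +
                                p$f_fat * MOL_O_DECARB_FAT +
                                p$f_protein * MOL_O_DECARB_PROTEIN) * DE
  vap_src <- if (p$vapour_source == "preformed") "preformed_water" else
    "food_free_water"
  ff <- fractionation_factors(p)
  ff <- ff[match(input_flux_names, ff$flux), ]
  data.frame(name = input_flux_names, role = "input",
             moles_O = c(drinking, food_water, oxidase, vapour,
                         condensation, decarbox),
             source = c("preformed_water", "food_free_water",
                        "atmospheric_O2", vap_src,
                        "preformed_water", "preformed_water"),
             alpha18 = ff$alpha18, theta = ff$theta, alpha17 = ff$alpha17,
             stringsAsFactors = FALSE)
}

#' Oxygen output fluxes
#'
#' Computes the eight oxygen outputs (moles of oxygen atoms over the window).
#' Bound oxygen in faeces is assumed zero; urinary water is the residual that
#' closes the steady-state balance against the total input.
#'
#' @param params a [flux_params()] object.
#' @param totals a [flux_totals()] object.
#' @param total_input_moles total moles of oxygen input (from
#'   [input_fluxes()]).
#' @param allow_negative_urinary if `FALSE` (default) a negative urinary
#'   residual raises an error naming the offending magnitudes; if `TRUE` the
#'   algebraic closure is kept with a warning (used by the sensitivity
#'   analysis, where extreme parameter values can overdraw the balance).
#' @return a data frame like [input_fluxes()] (outputs draw on body water, so
#'   `source` is `NA`).
#' @export
output_fluxes <- function(params, totals, total_input_moles,
                          allow_negative_urinary = FALSE) {
  p <- params
  stopifnot(inherits(totals, "flux_totals"))
  days <- totals$window_hours / 24
  faecal_bound <- 0
  faecal_water <- totals$food_kg * (1 - p$digestibility) /
    (1 - p$faecal_water_fraction) * p$faecal_water_fraction * KG_TO_MOL_WATER
  vpd <- vapour_pressure_deficit(p$ambient_temp_C, p$rel_humidity)$mmHg
  transcut <- days * p$mass_kg^(2 / 3) *
    ((p$meeh_k * vpd * p$skin_evap_rate / 1000) * 24 / 18)
  lair <- lung_air_litres(p, totals)
  exhaled_pool <- lair * sat_vap_mmHg(p$body_temp_C, p$eq_sat_vap_temp_unit) /
    760 / molar_volume_l(p)
  oral_frac <- if (!is.na(p$exhaled_oral_fraction)) p$exhaled_oral_fraction else
    p$oral_split
  nasal_frac <- if (!is.na(p$exhaled_nasal_fraction)) p$exhaled_nasal_fraction else
    p$nasal_split * (1 - p$nasal_retention)
  oral <- oral_frac * exhaled_pool
  nasal <- nasal_frac * exhaled_pool
  co2 <- 2 * totals$co2_mol
  urea <- MOL_O_UREA_PER_KG_PROTEIN * totals$food_kg * p$f_protein *
    p$digestibility * p$energy_extraction
  partial <- c(faecal_bound, faecal_water, transcut, oral, nasal, co2, urea)
  urinary <- total_input_moles - sum(partial)
  if (urinary < 0) {
    msg <- sprintf(paste0("urinary residual is negative (%.4f mol): total inputs ",
                          "%.4f mol < other outputs %.4f mol (largest: %s %.4f mol)"),
                   urinary, total_input_moles, sum(partial),
                   output_flux_names[-8][which.max(partial)], max(partial))
    if (allow_negative_urinary) warning(msg, call. = FALSE) else
      stop(msg, call. = FALSE)
  }
  ff <- fractionation_factors(p)
  ff <- ff[match(output_flux_names, ff$flux), ]
  data.frame(name = output_flux_names, role = "output",
             moles_O = c(partial, urinary), source = NA_character_,
             alpha18 = ff$alpha18, theta = ff$theta, alpha17 = ff$alpha17,
             stringsAsFactors = FALSE)
}
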