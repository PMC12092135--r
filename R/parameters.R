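# Model parameter and measured-totals containers.

#' Flux-model parameters
#'
#' Builds the full parameter set driving one evaluation of the body-water flux
#' model. Defaults are the base configuration for a deer mouse housed at 25 C
#' on the control (0.49% NaCl) diet; see `vignette("oxflux-methods")` for the
#' meaning, units and provenance of every parameter.
#'
#' @param mass_kg body mass in kg.
#' @param window_hours length of the flux-measurement window in hours
#'   (96 for the control diet, 48 for the high-salt diet).
#' @param body_temp_C,ambient_temp_C body and housing temperature in degrees C.
#' @param rel_humidity relative humidity as a fraction in `[0, 1]`.
#' @param ouf oxygen utilization fraction (oxygen extraction efficiency),
#'   strictly inside (0, 1).
#' @param z_value_permil 18O depletion of respired relative to atmospheric
#'   oxygen, permil.
#' @param meeh_k Meeh surface-area constant, cm^2 kg^(-2/3).
#' @param skin_evap_rate transcutaneous evaporation rate, mg/cm^2/h/mmHg.
#' @param faecal_water_fraction fraction of faecal mass that is water.
#' @param digestibility,energy_extraction assimilation fractions D and E.
#' @param food_water_content free-water mass fraction of the dry diet (WC).
#' @param f_carb,f_protein,f_fat diet macronutrient mass fractions; they may
#'   sum to less than 1 (remainder ash/fibre/moisture).
#' @param water_leakage fraction of recorded drinker-hopper mass loss
#'   attributed to nozzle leakage; the model multiplies supplied (raw) water
#'   intake by `1 - water_leakage`. Ignored for totals already flagged as
#'   leak-corrected (see [flux_totals()]).
#' @param preformed_water,atmospheric_O2,food_free_water [tox()] compositions
#'   of the three source pools: drinking water, atmospheric O2, and the free
#'   water in food (in equilibrium with ambient vapour).
#' @param cellulose data frame with columns `ingredient`, `d18O_permil`,
#'   `weight` giving diet-ingredient cellulose d18O and diet weight fractions
#'   (weights must sum to 1).
#' @param theta named numeric vector of triple-isotope exponents for the
#'   fractionating fluxes: `oxidase`, `vapour_equilibrium`, `bound_oxygen`,
#'   `transcutaneous`, `oral`, `nasal`, `co2`.
#' @param alpha18_transcutaneous 18/16 fractionation factor of transcutaneous
#'   water loss.
#' @param alpha18_oxidase optional direct override of the oxidase 18/16 alpha;
#'   `NA` (default) derives it from the z-value and OUF.
#' @param oral_split,nasal_split fractions of exhaled water vapour routed
#'   through the oral and nasal cavities (must sum to 1).
#' @param nasal_retention fraction of nasally routed vapour recondensed on
#'   epithelial surfaces and retained before exhalation.
#' @param exhaled_oral_fraction,exhaled_nasal_fraction optional direct
#'   overrides of the fractions of the exhaled vapour pool lost orally and
#'   nasally; `NA` derives them from the split and retention parameters
#'   (defaults 0.50 and 0.25).
#' @param vapour_source which source pool inhaled water vapour draws on:
#'   `"preformed"` (ambient vapour in equilibrium with the liquid drinking
#'   water; default) or `"food_free_water"`.
#' @param vapour_alpha_direction how the liquid-vapour equilibrium alpha is
#'   applied to the inhaled-vapour source ratio: `"deplete"` (vapour =
#'   liquid / alpha; default, the physical direction for evaporation) or
#'   `"enrich"` (vapour = liquid * alpha).
#' @param eq_sat_vap_temp_unit unit fed to the `10^(0.686 + 0.027 T)`
#'   saturation-vapour expression: `"C"` (default, the only physical choice)
#'   or `"K"` (audit flag reproducing a literal published reading).
#' @param rounded_constants logical; `TRUE` (default) uses the rounded
#'   constants 6.03e23 (Avogadro) and 22.4 l/mol for reproducibility, `FALSE`
#'   the CODATA values.
#' @return an object of class `flux_params` (a validated named list).
#' @seealso [treatment_params()] for the shipped treatment configurations,
#'   [body_water_model()] to run the model.
#' @examples
#' p <- flux_params()
#' p$ouf
#' @export
flux_params <- function(mass_kg = 0.02,
                        window_hours = 96,
                        body_temp_C = 38,
                        ambient_temp_C = 25,
                        rel_humidity = 0.45,
                        ouf = 0.25,
                        z_value_permil = 10.5,
                        meeh_k = 1100,
                        skin_evap_rate = 0.025,
                        faecal_water_fraction = 0.55,
                        digestibility = 0.85,
                        energy_extraction = 1.0,
                        food_water_content = 0.09,
                        f_carb = 0.672,
                        f_protein = 0.254,
                        f_fat = 0.074,
                        water_leakage = 0.10,
                        preformed_water = tox_from_cap(-4, 20),
                        atmospheric_O2 = tox_from_cap(24.046, -441),
                        food_free_water = tox_from_cap(-16.41, 30),
                        cellulose = data.frame(
                          ingredient = c("corn", "wheat", "soybean"),
                          d18O_permil = c(26, 26.9, 25.9),
                          weight = c(0.43, 0.37, 0.20)),
                        theta = c(oxidase = 0.5179,
                                  vapour_equilibrium = 0.529,
                                  bound_oxygen = 0.525,
                                  transcutaneous = 0.5235,
                                  oral = 0.529,
                                  nasal = 0.529,
                                  co2 = 0.5248),
                        alpha18_transcutaneous = 0.982,
                        alpha18_oxidase = NA_real_,
                        oral_split = 0.50,
                        nasal_split = 0.50,
                        nasal_retention = 0.50,
                        exhaled_oral_fraction = NA_real_,
                        exhaled_nasal_fraction = NA_real_,
                        vapour_source = c("preformed", "food_free_water"),
                        vapour_alpha_direction = c("deplete", "enrich"),
                        eq_sat_vap_temp_unit = c("C", "K"),
                        rounded_constants = TRUE) {
  p <- list(mass_kg = mass_kg, window_hours = window_hours,
            body_temp_C = body_temp_C, ambient_temp_C = ambient_temp_C,
            rel_humidity = rel_humidity, ouf = ouf,
            z_value_permil = z_value_permil, meeh_k = meeh_k,
            skin_evap_rate = skin_evap_rate,
            faecal_water_fraction = faecal_water_fraction,
            digestibility = digestibility,
            energy_extraction = energy_extraction,
            food_water_content = food_water_content,
            f_carb = f_carb, f_protein = f_protein, f_fat = f_fat,
            water_leakage = water_leakage,
            preformed_water = preformed_water,
            atmospheric_O2 = atmospheric_O2,
            food_free_water = food_free_water,
            cellulose = cellulose, theta = theta,
            alpha18_transcutaneous = alpha18_transcutaneous,
            alpha18_oxidase = alpha18_oxidase,
            oral_split = oral_split, nasal_split = nasal_split,
            nasal_retention = nasal_retention,
            exhaled_oral_fraction = exhaled_oral_fraction,
            exhaled_nasal_fraction = exhaled_nasal_fraction,
            vapour_source = match.arg(vapour_source),
            vapour_alpha_direction = match.arg(vapour_alpha_direction),
            eq_sat_vap_temp_unit = match.arg(eq_sat_vap_temp_unit),
            rounded_constants = isTRUE(rounded_constants))
  validate_flux_params(p)
  structure(p, class = "flux_params")
}

validate_flux_params <- function(p) {
  fr <- c("rel_humidity", "faecal_water_fraction", "digestibility",
          "energy_extraction", "food_water_content", "f_carb", "f_protein",
          "f_fat", "oral_split", "nasal_split", "nasal_retention")
  for (f in fr) {
    v <- p[[f]]
    if (!is.numeric(v) || v < 0 || v > 1)
      stop(sprintf("parameter '%s' must be a fraction in [0, 1]", f), call. = FALSE)
  }
  if (p$water_leakage < 0 || p$water_leakage >= 1)
    stop("water_leakage must be in [0, 1)", call. = FALSE)
  if (p$ouf <= 0 || p$ouf >= 1)
    stop("ouf must be strictly inside (0, 1)", call. = FALSE)
  if (abs(p$oral_split + p$nasal_split - 1) > 1e-9)
    stop("oral_split + nasal_split must equal 1", call. = FALSE)
  if (p$f_carb + p$f_protein + p$f_fat > 1 + 1e-9)
    stop("diet macronutrient fractions must sum to at most 1", call. = FALSE)
  if (abs(sum(p$cellulose$weight) - 1) > 1e-9)
    stop("cellulose ingredient weights must sum to 1", call. = FALSE)
  for (f in c("preformed_water", "atmospheric_O2", "food_free_water"))
    if (!inherits(p[[f]], "tox") || nrow(p[[f]]) != 1L)
      stop(sprintf("'%s' must be a single-row tox composition", f), call. = FALSE)
  need <- c("oxidase", "vapour_equilibrium", "bound_oxygen", "transcutaneous",
            "oral", "nasal", "co2")
  if (!all(need %in% names(p$theta)))
    stop("theta must name all fractionating fluxes: ",
         paste(setdiff(need, names(p$theta)), collapse = ", "), call. = FALSE)
  if (p$window_hours <= 0) stop("window_hours must be positive", call. = FALSE)
  invisible(p)
}

#' @export
print.flux_params <- function(x, ...) {
  cat("Body-water flux model parameters\n")
  cat(sprintf("  mass %.3g kg, window %g h, body %g C, ambient %g C, rh %.2f\n",
              x$mass_kg, x$window_hours, x$body_temp_C, x$ambient_temp_C,
              x$rel_humidity))
  cat(sprintf("  OUF %.2f, z-value %.1f permil, digestibility %.2f, leakage %.2f\n",
              x$ouf, x$z_value_permil, x$digestibility, x$water_leakage))
  cat(sprintf("  diet: carb %.3f / protein %.3f / fat %.3f, free water %.2f\n",
              x$f_carb, x$f_protein, x$f_fat, x$food_water_content))
  cat(sprintf("  sources (d18O permil / 17O-excess per meg): drinking %.2f/%.0f, atm O2 %.3f/%.0f, food water %.2f/%.0f\n",
              x$preformed_water$d18O_permil, x$preformed_water$cap17O_permeg,
              x$atmospheric_O2$d18O_permil, x$atmospheric_O2$cap17O_permeg,
              x$food_free_water$d18O_permil, x$food_free_water$cap17O_permeg))
  invisible(x)
}

#' Treatment-specific model parameters
#'
#' Returns the [flux_params()] configuration for one housing-temperature by
#' diet treatment cell, as shipped in `inst/extdata/treatment_configs.csv`
#' (relative humidity, window length, diet composition, ambient-vapour d18O,
#' and diet cellulose ingredient weights per treatment).
#'
#' @param diet `"0.49"` (control) or `"4"` (high-salt), percent NaCl.
#' @param temp_C housing temperature: 25, 18 or 15.
#' @param food_d18O optional override of the food free-water d18O (permil),
#'   for sampling dates where the monthly ambient-vapour value differs from
#'   the shipped one.
#' @param ... further arguments passed to [flux_params()] (e.g. `mass_kg`).
#' @return a `flux_params` object.
#' @examples
#' treatment_params("4", 25)$window_hours   # 48
#' @export
treatment_params <- function(diet = c("0.49", "4"), temp_C = c(25, 18, 15),
                             food_d18O = NULL, ...) {
  diet <- match.arg(as.character(diet), c("0.49", "4"))
  temp_C <- match.arg(as.character(temp_C), c("25", "18", "15"))
  cfg <- utils::read.csv(system.file("extdata", "treatment_configs.csv",
                                     package = "oxflux"),
                         stringsAsFactors = FALSE)
  row <- cfg[cfg$diet == diet & cfg$temp_C == as.numeric(temp_C), ]
  if (nrow(row) != 1L) stop("no shipped configuration for that treatment cell")
  d18 <- if (is.null(food_d18O)) row$food_d18O else food_d18O
  flux_params(ambient_temp_C = row$temp_C,
              rel_humidity = row$rel_humidity,
              window_hours = row$window_hours,
              f_carb = row$f_carb, f_protein = row$f_protein, f_fat = row$f_fat,
              food_free_water = tox_from_cap(d18, row$food_cap17O),
              cellulose = data.frame(
                ingredient = c("corn", "wheat", "soybean"),
                d18O_permil = c(row$cell_corn_d18O, row$cell_wheat_d18O,
                                row$cell_soy_d18O),
                weight = c(row$w_corn, row$w_wheat, row$w_soy)),
              ...)
}

#' Measured flux totals over one window
#'
#' Container for the windowed metabolic totals the model consumes. CO2 may be
#' supplied either in ml (the phenotyping system's native unit, converted at
#' 22.4 l/mol) or directly in moles of CO2 molecules.
#'
#' @param o2_ml total O2 consumed over the window, ml STP.
#' @param food_kg food consumed, kg.
#' @param water_ml drinking-water intake, ml. By default this is taken as the
#'   raw hopper mass loss and the model applies the leakage correction; set
#'   `water_leak_corrected = TRUE` for values already corrected (e.g. by
#'   [correct_water_intake()]), which the model then uses as-is.
#' @param window_hours window length in hours (usually 48 or 96).
#' @param co2_mol total CO2 exhaled, moles of CO2 molecules.
#' @param co2_ml alternative to `co2_mol`: total CO2 in ml STP.
#' @param water_leak_corrected logical flag, see `water_ml`.
#' @return an object of class `flux_totals`.
#' @examples
#' flux_totals(o2_ml = 5582, co2_mol = 0.21417, food_kg = 0.01297,
#'             water_ml = 10.44, window_hours = 96)
#' @export
flux_totals <- function(o2_ml, food_kg, water_ml, window_hours,
                        co2_mol = NULL, co2_ml = NULL,
                        water_leak_corrected = FALSE) {
  if (is.null(co2_mol) == is.null(co2_ml))
    stop("supply exactly one of co2_mol or co2_ml", call. = FALSE)
  if (is.null(co2_mol)) co2_mol <- co2_ml_to_mol(co2_ml)
  vals <- c(o2_ml = o2_ml, co2_mol = co2_mol, food_kg = food_kg,
            water_ml = water_ml)
  if (any(vals < 0)) stop("flux totals must be non-negative", call. = FALSE)
  if (window_hours < 0) stop("window_hours must be non-negative", call. = FALSE)
  structure(list(o2_ml = o2_ml, co2_mol = co2_mol, food_kg = food_kg,
                 water_ml = water_ml, window_hours = window_hours,
                 water_leak_corrected = isTRUE(water_leak_corrected)),
            class = "flux_totals")
}

#' Convert a CO2 volume to moles
#'
#' @param co2_ml CO2 volume in ml STP.
#' @param molar_volume_l molar volume used for the conversion (default the
#'   rounded 22.4 l/mol used throughout the model).
#' @return moles of CO2 molecules.
#' @export
co2_ml_to_mol <- function(co2_ml, molar_volume_l = 22.4) {
  co2_ml / 1000 / molar_volume_l
}

#' @export
print.flux_totals <- function(x, ...) {
  cat(sprintf(paste0("Measured flux totals over %g h: O2 %.0f ml, CO2 %.5f mol, ",
                     "food %.4f kg, water %.2f ml%s\n"),
              x$window_hours, x$o2_ml, x$co2_mol, x$food_kg, x$water_ml,
              if (x$water_leak_corrected) " (leak-corrected)" else " (raw)"))
  invisible(x)
}

#' Read or write model parameters as YAML
#'
#' Serializes a [flux_params()] object to a YAML configuration file and back.
#' Compositions are stored as `d18O_permil` / `cap17O_permeg` pairs.
#'
#' @param params a `flux_params` object.
#' @param path file path.
#' @return `read_flux_params()` returns a `flux_params` object;
#'   `write_flux_params()` returns `path` invisibly.
#' @export
write_flux_params <- function(params, path) {
  stopifnot(inherits(params, "flux_params"))
  p <- unclass(params)
  for (f in c("preformed_water", "atmospheric_O2", "food_free_water"))
    p[[f]] <- list(d18O_permil = params[[f]]$d18O_permil,
                   cap17O_permeg = params[[f]]$cap17O_permeg)
  p$cellulose <- as.list(params$cellulose)
  p$theta <- as.list(params$theta)
  yaml::write_yaml(p, path)
  invisible(path)
}

#' @rdname write_flux_params
#' @export
read_flux_params <- function(path) {
  p <- yaml::read_yaml(path)
  for (f in c("preformed_water", "atmospheric_O2", "food_free_water"))
    p[[f]] <- tox_from_cap(p[[f]]$d18O_permil, p[[f]]$cap17O_permeg)
  p$cellulose <- data.frame(ingredient = unlist(p$cellulose$ingredient),
                            d18O_permil = unlist(p$cellulose$d18O_permil),
                            weight = unlist(p$cellulose$weight))
  p$theta <- unlist(p$theta)
  do.call(flux_params, p)
}
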