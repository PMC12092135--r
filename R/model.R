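# Steady-state assembly of the body-water prediction and the user-facing
# model object.

#' Assemble the steady-state body-water composition
#'
#' Combines input and output flux tables into the steady-state isotope ratio
#' of body water. For each isotope x in \{17, 18\},
#' `R_x(BW) = sum_i f_i * alpha_x,i * R_x(source_i) / sum_j f_j * alpha_x,j`,
#' where `f_i` and `f_j` are fractional contributions within the input and
#' output pools, input source ratios come from
#' [ratios_from_composition()] applied to the parameter source pools, and all
#' outputs draw on body water.
#'
#' @param inputs,outputs flux tables from [input_fluxes()] and
#'   [output_fluxes()].
#' @param params the [flux_params()] used to build them.
#' @param ref a [ref_ratios()] object.
#' @param tol relative tolerance on the input/output mole balance.
#' @return a list with the predicted [tox()] composition (`composition`),
#'   named fraction vectors `input_fractions` and `output_fractions`, and
#'   `urinary_moles`.
#' @export
predict_body_water <- function(inputs, outputs, params, ref = ref_ratios(),
                               tol = 1e-9) {
  tin <- sum(inputs$moles_O); tout <- sum(outputs$moles_O)
  if (abs(tin - tout) > tol * max(tin, tout))
    stop(sprintf("flux balance not closed: inputs %.6f mol, outputs %.6f mol",
                 tin, tout), call. = FALSE)
  fi <- inputs$moles_O / tin
  fo <- outputs$moles_O / tout
  srcs <- lapply(c(preformed_water = "preformed_water",
                   atmospheric_O2 = "atmospheric_O2",
                   food_free_water = "food_free_water"),
                 function(f) ratios_from_composition(params[[f]], ref))
  r18_src <- vapply(inputs$source, function(s) srcs[[s]]$r18, numeric(1))
  r17_src <- vapply(inputs$source, function(s) srcs[[s]]$r17, numeric(1))
  r18 <- sum(fi * inputs$alpha18 * r18_src) / sum(fo * outputs$alpha18)
  r17 <- sum(fi * inputs$alpha17 * r17_src) / sum(fo * outputs$alpha17)
  comp <- composition_from_ratios(r17, r18, ref)
  list(composition = comp,
       input_fractions = stats::setNames(fi, inputs$name),
       output_fractions = stats::setNames(fo, outputs$name),
       urinary_moles = outputs$moles_O[outputs$name == "urinary_water"])
}

#' Body-water triple-oxygen flux model
#'
#' Evaluates the full steady-state oxygen mass balance for one animal over one
#' measurement window: six inputs ([input_fluxes()]), eight outputs with the
#' urinary residual closing the balance ([output_fluxes()]), fractionation
#' factors ([fractionation_factors()]) and the assembled prediction of
#' d18O, d17O and the 17O-excess of body water ([predict_body_water()]).
#'
#' @param params a [flux_params()] object.
#' @param totals a [flux_totals()] object (measured O2, CO2, food and water
#'   over the window).
#' @param ref a [ref_ratios()] object.
#' @param allow_negative_urinary passed to [output_fluxes()].
#' @return an object of class `bw_model` with components `params`, `totals`,
#'   `fluxes` (both flux tables bound together), `prediction` (a [tox()]
#'   composition), `input_fractions`, `output_fractions`, `urinary_moles`.
#'   Methods: `print`, `summary`, `coef`, `predict`, `plot`, `simulate`.
#' @examples
#' m <- body_water_model(flux_params(),
#'                       flux_totals(o2_ml = 5582, co2_mol = 0.21417,
#'                                   food_kg = 0.01297, water_ml = 10.44,
#'                                   window_hours = 96))
#' m
#' predict(m)$cap17O_permeg
#' @export
body_water_model <- function(params = flux_params(), totals,
                             ref = ref_ratios(),
                             allow_negative_urinary = FALSE) {
  stopifnot(inherits(params, "flux_params"), inherits(totals, "flux_totals"))
  ins <- input_fluxes(params, totals)
  outs <- output_fluxes(params, totals, sum(ins$moles_O),
                        allow_negative_urinary = allow_negative_urinary)
  pred <- predict_body_water(ins, outs, params, ref)
  structure(list(params = params, totals = totals,
                 fluxes = rbind(ins, outs),
                 prediction = pred$composition,
                 input_fractions = pred$input_fractions,
                 output_fractions = pred$output_fractions,
                 urinary_moles = pred$urinary_moles,
                 ref = ref),
            class = "bw_model")
}

#' @export
print.bw_model <- function(x, ...) {
  cat("Steady-state body-water triple-oxygen flux model\n")
  cat(sprintf("  window %g h, total oxygen flux %.4f mol\n",
              x$totals$window_hours,
              sum(x$fluxes$moles_O[x$fluxes$role == "input"])))
  cat(sprintf("  predicted body water: d18O %+.3f permil, d17O %+.3f permil, 17O-excess %.1f per meg\n",
              x$prediction$d18O_permil, x$prediction$d17O_permil,
              x$prediction$cap17O_permeg))
  invisible(x)
}

#' @export
summary.bw_model <- function(object, ...) {
  structure(list(model = object), class = "summary.bw_model")
}

#' @export
print.summary.bw_model <- function(x, ...) {
  m <- x$model
  print(m)
  f <- m$fluxes
  f$fraction <- c(m$input_fractions, m$output_fractions)
  cat("\nFluxes (moles of O over the window):\n")
  print(data.frame(flux = f$name, role = f$role,
                   moles_O = round(f$moles_O, 5),
                   fraction = round(f$fraction, 4),
                   alpha18 = round(f$alpha18, 6),
                   alpha17 = round(f$alpha17, 6)), row.names = FALSE)
  invisible(x)
}

#' @export
coef.bw_model <- function(object, ...) {
  p <- object$params
  c(mass_kg = p$mass_kg, window_hours = p$window_hours,
    body_temp_C = p$body_temp_C, ambient_temp_C = p$ambient_temp_C,
    rel_humidity = p$rel_humidity, ouf = p$ouf,
    z_value_permil = p$z_value_permil, meeh_k = p$meeh_k,
    skin_evap_rate = p$skin_evap_rate,
    faecal_water_fraction = p$faecal_water_fraction,
    digestibility = p$digestibility, energy_extraction = p$energy_extraction,
    food_water_content = p$food_water_content,
    f_carb = p$f_carb, f_protein = p$f_protein, f_fat = p$f_fat,
    water_leakage = p$water_leakage)
}

#' Predict body water for a fitted flux model
#'
#' Returns the model's predicted body-water composition; with `newdata` (a
#' [flux_totals()] object) the model is re-evaluated for new measured totals
#' under the same parameters.
#'
#' @param object a `bw_model`.
#' @param newdata optional [flux_totals()].
#' @param ... unused.
#' @return a [tox()] composition.
#' @export
predict.bw_model <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$prediction)
  body_water_model(object$params, newdata, ref = object$ref)$prediction
}

#' Plot flux fractional contributions
#'
#' Barplots of the fractional contribution of each oxygen input and output.
#'
#' @param x a `bw_model`.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.bw_model <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(8, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::barplot(x$input_fractions, las = 2, ylab = "fraction of O input",
                    main = "inputs", ...)
  graphics::barplot(x$output_fractions, las = 2, ylab = "fraction of O output",
                    main = "outputs", ...)
  invisible(x)
}

#' Simulate measured body-water values from a model
#'
#' Adds measurement-level noise to the model prediction the way replicate
#' distillation and analysis scatter body-water measurements: independent
#' Gaussian noise on d18O and on the 17O-excess (d17O follows, so the implied
#' d17O/d18O noise is strongly correlated, as observed).
#'
#' @param object a `bw_model`.
#' @param nsim number of simulated measurements.
#' @param seed optional integer seed.
#' @param sd_d18O standard deviation of d18O noise, permil.
#' @param sd_cap17O standard deviation of 17O-excess noise, per meg.
#' @param ... unused.
#' @return a [tox()] data frame with `nsim` rows.
#' @export
simulate.bw_model <- function(object, nsim = 1, seed = NULL,
                              sd_d18O = 0.1, sd_cap17O = 8, ...) {
  if (!is.null(seed)) set.seed(seed)
  d18 <- object$prediction$d18O_permil + stats::rnorm(nsim, 0, sd_d18O)
  cap <- object$prediction$cap17O_permeg + stats::rnorm(nsim, 0, sd_cap17O)
  tox_from_cap(d18, cap)
}
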