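test_that("input fluxes match hand-derived base values", {
  ins <- input_fluxes(flux_params(), base_totals())
  m <- setNames(ins$moles_O, ins$name)
  # frozen from direct evaluation of the flux expressions
  expect_equal(m[["drinking_water"]], 10.44 * 0.9 / 18, tolerance = 1e-12)
  expect_equal(m[["food_water"]], 0.0712694373626374, tolerance = 1e-9)
  expect_equal(m[["oxidase_water"]], 0.498029187396352, tolerance = 1e-9)
  expect_equal(m[["inhaled_vapour"]], 0.0645329371329377, tolerance = 1e-9)
  expect_equal(m[["condensation_water"]], 0.08238211968, tolerance = 1e-9)
  expect_equal(m[["decarboxylation_oxygen"]], 0.18482882936, tolerance = 1e-9)
  expect_true(all(ins$source[ins$name %in%
    c("condensation_water", "decarboxylation_oxygen")] == "preformed_water"))
  # leak-corrected totals are used as-is
  tot2 <- flux_totals(5582, co2_mol = 0.21417, food_kg = 0.01297,
                      water_ml = 9.396, window_hours = 96,
                      water_leak_corrected = TRUE)
  ins2 <- input_fluxes(flux_params(), tot2)
  expect_equal(ins2$moles_O[ins2$name == "drinking_water"],
               m[["drinking_water"]], tolerance = 1e-12)
})

test_that("fractionation factors match their closed forms", {
  ff <- fractionation_factors(flux_params())
  a <- setNames(ff$alpha18, ff$flux)
  expect_equal(a[["oxidase_water"]], 0.994155861487993, tolerance = 1e-12)
  expect_equal(a[["exhaled_co2"]], 1.03837861653225, tolerance = 1e-12)
  # vapour equilibrium at 25 C, applied in the depleting direction
  expect_equal(a[["inhaled_vapour"]], 1 / 1.00934404686161, tolerance = 1e-12)
  expect_equal(a[["condensation_water"]], 1.03043473895582, tolerance = 1e-12)
  expect_equal(a[["decarboxylation_oxygen"]], a[["condensation_water"]])
  # equilibrium sanity: oral loss depletes, vapour equilibrium factor > 1
  expect_lt(a[["oral_vapour"]], 1)
  p_enrich <- flux_params(vapour_alpha_direction = "enrich")
  expect_gt(fractionation_factors(p_enrich)$alpha18[
    fractionation_factors(p_enrich)$flux == "inhaled_vapour"], 1)
  # non-fractionating fluxes carry alpha = 1
  nf <- c("drinking_water", "food_water", "faecal_water", "urea_oxygen",
          "urinary_water")
  expect_true(all(ff$alpha18[ff$flux %in% nf] == 1))
  expect_true(all(ff$alpha17[ff$flux %in% nf] == 1))
  # alpha17 follows the theta law everywhere
  expect_equal(ff$alpha17, ff$alpha18^ff$theta, tolerance = 1e-14)
  # direct oxidase override bypasses the z-value formula
  p2 <- flux_params(alpha18_oxidase = 0.99)
  expect_equal(fractionation_factors(p2)$alpha18[
    fractionation_factors(p2)$flux == "oxidase_water"], 0.99)
})

test_that("vapour pressure deficit matches the Tetens form", {
  expect_equal(vapour_pressure_deficit(25, 1)$kPa, 0)
  v <- vapour_pressure_deficit(25, 0.45)
  expect_equal(v$kPa, 1.74212106705749, tolerance = 1e-9)
  expect_equal(v$mmHg, 13.0669881179927, tolerance = 1e-9)
  expect_equal(vapour_pressure_deficit(0, 0)$kPa, 0.61078, tolerance = 1e-9)
  expect_error(vapour_pressure_deficit(25, 1.2), "rel_humidity")
})

test_that("output fluxes match hand-derived base values and close the balance", {
  p <- flux_params(); tot <- base_totals()
  ins <- input_fluxes(p, tot)
  outs <- output_fluxes(p, tot, sum(ins$moles_O))
  m <- setNames(outs$moles_O, outs$name)
  expect_equal(m[["faecal_bound"]], 0)
  expect_equal(m[["faecal_water"]], 0.13211242, tolerance = 1e-9)
  expect_equal(m[["transcutaneous"]], 0.141208307735865, tolerance = 1e-9)
  expect_equal(m[["urea_oxygen"]], 0.033602676, tolerance = 1e-9)
  expect_equal(m[["exhaled_co2"]], 2 * 0.21417, tolerance = 1e-12)
  # nasal loss is half the nasally routed half of the exhaled pool
  expect_equal(m[["nasal_vapour"]], m[["oral_vapour"]] / 2, tolerance = 1e-12)
  # urinary residual closes the balance exactly
  expect_equal(sum(outs$moles_O), sum(ins$moles_O), tolerance = 1e-12)
  expect_gt(m[["urinary_water"]], 0)
  # trivial conservation closure
  outs2 <- output_fluxes(p, tot, sum(outs$moles_O[outs$name != "urinary_water"]) + 0.4)
  expect_equal(outs2$moles_O[outs2$name == "urinary_water"], 0.4, tolerance = 1e-12)
})

test_that("negative urinary residual errors unless explicitly allowed", {
  p <- flux_params(); tot <- base_totals()
  expect_error(output_fluxes(p, tot, 0.1), "urinary residual is negative")
  expect_warning(out <- output_fluxes(p, tot, 0.1, allow_negative_urinary = TRUE),
                 "urinary")
  expect_lt(out$moles_O[out$name == "urinary_water"], 0)
})

test_that("CO2 totals are accepted in ml or moles equivalently", {
  t1 <- flux_totals(5582, co2_ml = 0.21417 * 22400, food_kg = 0.01297,
                    water_ml = 10.44, window_hours = 96)
  expect_equal(t1$co2_mol, 0.21417, tolerance = 1e-12)
  expect_error(flux_totals(5582, food_kg = 0.01, water_ml = 1, window_hours = 96),
               "exactly one")
  expect_error(flux_totals(-1, co2_mol = 0.2, food_kg = 0.01, water_ml = 1,
                           window_hours = 96), "non-negative")
})
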