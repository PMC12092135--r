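# shared fixtures built in code

base_totals <- function() {
  flux_totals(o2_ml = 5582, co2_mol = 0.21417, food_kg = 0.01297,
              water_ml = 10.44, window_hours = 96)
}

# Table-4-style treatment-cell evaluation: group metabolic means under the
# shipped treatment configuration (water reported post leak correction)
cell_model <- function(diet, temp_C, o2_ml_min, rq, food_g_day, water_ml_day,
                       mass_g) {
  p <- treatment_params(diet, temp_C, mass_kg = mass_g / 1000)
  w <- p$window_hours
  tot <- flux_totals(o2_ml = o2_ml_min * 60 * w,
                     co2_ml = o2_ml_min * rq * 60 * w,
                     food_kg = food_g_day * (w / 24) / 1000,
                     water_ml = water_ml_day * (w / 24),
                     window_hours = w, water_leak_corrected = TRUE)
  body_water_model(p, tot)
}

treatment_cells <- function() {
  list(c049_25 = cell_model("0.49", 25, 0.95, 0.87, 3.48, 2.42, 19.19),
       c049_cold = cell_model("0.49", 15, 1.33, 0.88, 4.00, 2.86, 19.96),
       c4_25 = cell_model("4", 25, 0.96, 0.80, 3.14, 5.60, 19.12),
       c4_cold = cell_model("4", 15, 1.39, 0.87, 4.48, 6.19, 19.62))
}

# minimal analysis-run water layout: two bracketing standards + 5 controls
run_waters <- function(extra_samples = NULL) {
  w <- data.frame(
    water_id = c("USGS50", "USGS47", paste0("ctrl", 1:5)),
    water_role = c("standard", "standard", rep("control", 5)),
    d18O = c(1.12, -26.78, -2, -6, -10, -16, -22),
    stringsAsFactors = FALSE)
  w$d17O <- d17O_from_cap(w$d18O, c(20, 10, 25, 30, 20, 15, 10))
  if (!is.null(extra_samples)) w <- rbind(w, extra_samples)
  w
}

standard_defs <- function(waters = run_waters()) {
  s <- waters[waters$water_role == "standard", ]
  data.frame(name = s$water_id, known_d17O = s$d17O, known_d18O = s$d18O,
             known_d2H = 8 * s$d18O + 10)
}

control_defs <- function(waters = run_waters()) {
  s <- waters[waters$water_role == "control", ]
  data.frame(name = s$water_id, known_d17O = s$d17O, known_d18O = s$d18O)
}
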