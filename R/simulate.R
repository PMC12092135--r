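# Seeded synthetic-data generator: phenotyping traces, body-water values and
# isotope analysis runs with known ground truth.
#
# The generator emulates the structure of a metabolic phenotyping experiment
# on caged deer mice -- 5-min respirometry cadence, hopper mass steps, sensor
# gaps, drinker leakage, occasional spill/caching days -- with group-level
# means and SDs for each housing-temperature x diet treatment cell. It makes
# no behavioural claims beyond those moments; see the methods vignette.

#' Treatment configuration for the simulator
#'
#' Group means and SDs of the metabolic phenotype (O2 intake, respiratory
#' quotient, food and water intake, body mass) for the four treatment cells,
#' together with the housing conditions and flux window the cell was measured
#' under.
#'
#' @param diet `"0.49"` or `"4"` (percent NaCl).
#' @param cold `FALSE` for 25 C housing, `TRUE` for the pooled 15/18 C cell
#'   (represented by 15 C, the final housing temperature, at 68% rh).
#' @param n_mice number of mice.
#' @return a list of class `treatment_config`.
#' @export
treatment_config <- function(diet = c("0.49", "4"), cold = FALSE, n_mice = 8) {
  diet <- match.arg(as.character(diet), c("0.49", "4"))
  key <- paste0(diet, if (cold) "_cold" else "_25")
  tab <- list(
    "0.49_25"   = list(o2 = c(0.95, 0.23), rq = c(0.87, 0.01),
                       food = c(3.48, 1.49), water = c(2.42, 0.40),
                       mass = c(19.19, 1.17), temp = 25, rh = 0.45, win = 96),
    "0.49_cold" = list(o2 = c(1.33, 0.19), rq = c(0.88, 0.01),
                       food = c(4.00, 0.70), water = c(2.86, 0.36),
                       mass = c(19.96, 1.01), temp = 15, rh = 0.68, win = 96),
    "4_25"      = list(o2 = c(0.96, 0.12), rq = c(0.80, 0.03),
                       food = c(3.14, 1.35), water = c(5.60, 1.29),
                       mass = c(19.12, 0.98), temp = 25, rh = 0.45, win = 48),
    "4_cold"    = list(o2 = c(1.39, 0.18), rq = c(0.87, 0.03),
                       food = c(4.48, 0.98), water = c(6.19, 0.74),
                       mass = c(19.62, 1.28), temp = 15, rh = 0.68, win = 48))
  cfg <- tab[[key]]
  structure(list(label = key, diet = diet, cold = cold, n_mice = n_mice,
                 o2_ml_min = cfg$o2, rq = cfg$rq, food_g_day = cfg$food,
                 water_ml_day = cfg$water, body_mass_g = cfg$mass,
                 ambient_temp_C = cfg$temp, rel_humidity = cfg$rh,
                 window_hours = cfg$win),
            class = "treatment_config")
}

# hopper trace: cumulative mass with Poisson-timed lognormal consumption
# events summing to the daily total (drops), no refills within the horizon
hopper_trace <- function(times, daily_totals, start_mass, events_per_day = 30) {
  t0 <- times[1]
  drops <- numeric(length(times))
  for (d in seq_along(daily_totals)) {
    if (daily_totals[d] <= 0) next
    n_ev <- max(1L, stats::rpois(1, events_per_day))
    ev_t <- t0 + ((d - 1) + sort(stats::runif(n_ev))) * 86400
    sizes <- stats::rlnorm(n_ev, 0, 0.5)
    sizes <- sizes / sum(sizes) * daily_totals[d]
    idx <- findInterval(as.numeric(ev_t), as.numeric(times))
    for (k in seq_along(idx)) if (idx[k] >= 1 && idx[k] <= length(times))
      drops[idx[k]] <- drops[idx[k]] + sizes[k]
  }
  start_mass - cumsum(drops)
}

#' Simulate a metabolic phenotyping experiment
#'
#' Generates per-mouse 5-min respirometry and hopper traces for one treatment
#' cell. Gas rates follow a first-order autoregressive process around each
#' mouse's daily mean with a sinusoidal diel cycle; hopper masses are monotone
#' step functions with Poisson event times; configurable pathologies are
#' injected: sensor gaps (short, fillable and long), bulk drinker leakage
#' inflating recorded water loss, and rare spill/caching days exceeding the
#' QC thresholds.
#'
#' @param cfg a [treatment_config()].
#' @param days number of days simulated.
#' @param seed integer seed; regeneration with the same seed is identical.
#' @param leakage drinker leakage fraction: recorded hopper water loss is
#'   `true intake / (1 - leakage)`.
#' @param diel_amplitude diel cycle amplitude as a fraction of the mean rate.
#' @param ar_phi,ar_sd AR(1) coefficient and innovation SD (fraction of mean)
#'   of the gas-rate process.
#' @param gap_spec list of gap durations (minutes) to cut per mouse, e.g.
#'   `list(short = 45, long = 120, tiny = 20)`; `NULL` for no gaps.
#' @param spill_prob,cache_prob per-day probability of a water-spill /
#'   food-caching artefact day (recorded intake far above the QC threshold).
#' @return a list with `records` (the phenotyping table, gaps cut out),
#'   `truth` (per-mouse daily true intakes and rates, plus injected
#'   pathologies), and `cfg`.
#' @export
simulate_phenotyping <- function(cfg, days = 5, seed = 1, leakage = 0.10,
                                 diel_amplitude = 0.2, ar_phi = 0.9,
                                 ar_sd = 0.1,
                                 gap_spec = list(short = 45, long = 120,
                                                 tiny = 20),
                                 spill_prob = 0.02, cache_prob = 0.02) {
  stopifnot(inherits(cfg, "treatment_config"))
  set.seed(seed)
  t0 <- as.POSIXct("2023-06-01 00:00:00", tz = "UTC")
  times <- seq(t0, by = 300, length.out = days * 288)
  recs <- list(); truths <- list()
  for (m in seq_len(cfg$n_mice)) {
    cage <- sprintf("cage%02d", m)
    o2_mean <- max(0.05, stats::rnorm(1, cfg$o2_ml_min[1], cfg$o2_ml_min[2]))
    rq <- max(0.6, stats::rnorm(1, cfg$rq[1], cfg$rq[2]))
    mass <- stats::rnorm(1, cfg$body_mass_g[1], cfg$body_mass_g[2])
    food_day <- pmax(0.2, stats::rnorm(days, cfg$food_g_day[1], cfg$food_g_day[2]))
    water_day <- pmax(0.2, stats::rnorm(days, cfg$water_ml_day[1], cfg$water_ml_day[2]))
    # AR(1) around diel-modulated mean, truncated at zero
    n <- length(times)
    diel <- 1 + diel_amplitude * sin(2 * pi * (as.numeric(times - t0) / 86400))
    eps <- stats::rnorm(n, 0, ar_sd * o2_mean)
    ar <- stats::filter(eps, ar_phi, method = "recursive")
    o2 <- pmax(0, o2_mean * diel + as.numeric(ar))
    co2 <- pmax(0, o2 * rq + stats::rnorm(n, 0, 0.01))
    spill <- stats::runif(days) < spill_prob
    cache <- stats::runif(days) < cache_prob
    water_rec <- water_day / (1 - leakage)
    water_rec[spill] <- water_rec[spill] + 25
    food_rec <- food_day
    food_rec[cache] <- food_rec[cache] + 28
    rec <- data.frame(timestamp = times, cage_id = cage,
                      o2_ml_min = o2, co2_ml_min = co2,
                      water_g = hopper_trace(times, water_rec, 250),
                      food_g = hopper_trace(times, food_rec, 400),
                      body_mass_g = mass, stringsAsFactors = FALSE)
    gaps <- list()
    if (!is.null(gap_spec)) {
      gap_starts <- t0 + (seq_along(gap_spec) * 86400 * days / (length(gap_spec) + 1))
      for (g in seq_along(gap_spec)) {
        gs <- gap_starts[g]; ge <- gs + gap_spec[[g]] * 60
        cut <- rec$timestamp > gs & rec$timestamp < ge
        rec <- rec[!cut, , drop = FALSE]
        gaps[[names(gap_spec)[g]]] <- c(start = gs, minutes = gap_spec[[g]])
      }
    }
    recs[[cage]] <- rec
    truths[[cage]] <- list(o2_mean_ml_min = o2_mean, rq = rq,
                           body_mass_g = mass,
                           true_water_ml_day = water_day,
                           true_food_g_day = food_day,
                           recorded_water_ml_day = water_rec,
                           recorded_food_g_day = food_rec,
                           spill_days = which(spill), cache_days = which(cache),
                           gaps = gaps,
                           true_o2_trace = o2, true_co2_trace = co2,
                           trace_times = times)
  }
  list(records = do.call(rbind, c(recs, list(make.row.names = FALSE))),
       truth = truths, cfg = cfg, seed = seed, leakage = leakage)
}

#' Simulate body-water compositions for a cohort
#'
#' Runs the flux model on each mouse's true windowed totals to obtain the true
#' body-water composition, then adds measurement noise: Gaussian on d18O and
#' (independently) on the 17O-excess, so the implied d17O noise is strongly
#' correlated with d18O as in replicate distillation data.
#'
#' @param sim output of [simulate_phenotyping()].
#' @param params a [flux_params()] for the treatment (defaults to the shipped
#'   configuration of the simulated cell).
#' @param sd_d18O,sd_cap17O measurement noise, permil / per meg.
#' @param seed integer seed.
#' @return a data frame with one row per mouse: true and measured d18O, d17O
#'   and 17O-excess, plus the totals used.
#' @export
simulate_body_water <- function(sim, params = NULL, sd_d18O = 0.1,
                                sd_cap17O = 8, seed = 1) {
  cfg <- sim$cfg
  if (is.null(params))
    params <- treatment_params(cfg$diet, cfg$ambient_temp_C)
  set.seed(seed)
  win_d <- cfg$window_hours / 24
  rows <- lapply(names(sim$truth), function(cage) {
    tr <- sim$truth[[cage]]
    idx <- seq_len(win_d * 288)  # first window of the trace
    dsel <- seq_len(win_d)
    tot <- flux_totals(o2_ml = sum(tr$true_o2_trace[idx]) * 5,
                       co2_ml = sum(tr$true_co2_trace[idx]) * 5,
                       food_kg = sum(tr$true_food_g_day[dsel]) / 1000,
                       water_ml = sum(tr$true_water_ml_day[dsel]),
                       window_hours = cfg$window_hours,
                       water_leak_corrected = TRUE)
    m <- body_water_model(params, tot)
    data.frame(cage_id = cage,
               true_d18O = m$prediction$d18O_permil,
               true_d17O = m$prediction$d17O_permil,
               true_cap17O = m$prediction$cap17O_permeg,
               o2_ml = tot$o2_ml, food_kg = tot$food_kg,
               water_ml = tot$water_ml, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  meas <- tox_from_cap(out$true_d18O + stats::rnorm(nrow(out), 0, sd_d18O),
                       out$true_cap17O + stats::rnorm(nrow(out), 0, sd_cap17O))
  out$meas_d18O <- meas$d18O_permil
  out$meas_d17O <- meas$d17O_permil
  out$meas_cap17O <- meas$cap17O_permeg
  out
}

#' Simulate a water-isotope analysis run
#'
#' Generates raw injections for samples, two standards and control waters,
#' inverting a known stretching/offset so the correction machinery can be
#' tested end to end: `raw = (true - offset) / stretching + noise`.
#'
#' @param waters data frame with columns `water_id`, `water_role`
#'   (`"sample"`, `"standard"` or `"control"`), `d17O`, `d18O` (true values,
#'   permil), optionally `d2H`.
#' @param stretching,offset named numeric (names `d17O`, `d18O`, `d2H`):
#'   the instrument response to invert.
#' @param sigma_d18O injection noise SD on d18O (permil); d17O noise is
#'   correlated so that the 17O-excess noise has SD `sigma_cap_permeg`.
#' @param sigma_cap_permeg injection-level 17O-excess noise SD, per meg.
#' @param n_injections range of injections per replicate (uniform draw).
#' @param n_outliers number of planted gross-outlier injections (added to the
#'   first sample water, displaced by +10 SD).
#' @param run_id run identifier.
#' @param seed integer seed.
#' @return an injection table suitable for [fit_correction()] etc.
#' @export
simulate_analysis_run <- function(waters,
                                  stretching = c(d17O = 1.0, d18O = 1.0, d2H = 1.0),
                                  offset = c(d17O = 0, d18O = 0, d2H = 0),
                                  sigma_d18O = 0.05, sigma_cap_permeg = 10,
                                  n_injections = c(5, 11), n_outliers = 0,
                                  run_id = "run01", seed = 1) {
  set.seed(seed)
  if (is.null(waters$d2H)) waters$d2H <- 8 * waters$d18O + 10
  rows <- lapply(seq_len(nrow(waters)), function(i) {
    n <- sample(seq(n_injections[1], n_injections[2]), 1)
    d18 <- waters$d18O[i] + stats::rnorm(n, 0, sigma_d18O)
    cap <- cap_delta17(waters$d17O[i], waters$d18O[i]) +
      stats::rnorm(n, 0, sigma_cap_permeg)
    d17 <- d17O_from_cap(d18, cap)
    d2h <- waters$d2H[i] + stats::rnorm(n, 0, 10 * sigma_d18O)
    data.frame(run_id = run_id, water_id = waters$water_id[i],
               water_role = waters$water_role[i],
               replicate_id = 1L,
               raw_d17O = (d17 - offset[["d17O"]]) / stretching[["d17O"]],
               raw_d18O = (d18 - offset[["d18O"]]) / stretching[["d18O"]],
               raw_d2H = (d2h - offset[["d2H"]]) / stretching[["d2H"]],
               stringsAsFactors = FALSE)
  })
  run <- do.call(rbind, rows)
  if (n_outliers > 0) {
    sample_ids <- waters$water_id[waters$water_role == "sample"]
    if (length(sample_ids)) {
      idx <- which(run$water_id == sample_ids[1])[seq_len(n_outliers)]
      run$raw_d18O[idx] <- run$raw_d18O[idx] + 10 * max(sigma_d18O, 0.01)
    }
  }
  run
}
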