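# QC and aggregation of metabolic phenotyping time series.
#
# Input layout (long format, one row per cage measurement on a nominal 5-min
# cadence): timestamp (POSIXct or ISO-8601 string), cage_id, o2_ml_min,
# co2_ml_min, water_g, food_g, optionally body_mass_g. Hopper columns are
# cumulative masses; intake is read from mass drops.

#' Read a phenotyping CSV
#'
#' @param path CSV with columns `timestamp` (ISO-8601), `cage_id`,
#'   `o2_ml_min`, `co2_ml_min`, `water_g`, `food_g` and optionally
#'   `body_mass_g`.
#' @param tz timezone for timestamp parsing.
#' @return a data frame sorted by cage and time.
#' @export
read_phenotyping <- function(path, tz = "UTC") {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  x$timestamp <- as.POSIXct(x$timestamp, tz = tz)
  x[order(x$cage_id, x$timestamp), , drop = FALSE]
}

#' Fill respirometry gaps
#'
#' Fills gaps in the gas-rate series at the nominal cadence. Gaps of
#' `short_gap_min` (35-60 min by default) are filled with the mean O2 and CO2
#' rate of the preceding 3 h of observed records; longer gaps with the mean of
#' the preceding 24 h (researcher presence around long interruptions elevates
#' rates, so the wider lookback is the safer baseline). Gaps shorter than the
#' lower bound are left missing. Filled records never feed later fills, and
#' observed records are never altered.
#'
#' @param series phenotyping data frame (see [read_phenotyping()]).
#' @param cadence_min nominal cadence in minutes.
#' @param short_gap_min two-element numeric: the short-gap range in minutes.
#' @param lookback_short_h,lookback_long_h lookback horizons in hours.
#' @return a list with `series` (input plus filled rows, flagged by the
#'   logical column `filled`) and `gaps` (one row per gap: cage, start, end,
#'   duration, action taken).
#' @export
fill_gaps <- function(series, cadence_min = 5, short_gap_min = c(35, 60),
                      lookback_short_h = 3, lookback_long_h = 24) {
  series <- series[order(series$cage_id, series$timestamp), , drop = FALSE]
  if (is.null(series$filled)) series$filled <- FALSE
  reports <- list(); added <- list()
  for (cage in unique(series$cage_id)) {
    s <- series[series$cage_id == cage & !series$filled, , drop = FALSE]
    dt <- as.numeric(diff(s$timestamp), units = "mins")
    gaps <- which(dt > cadence_min + 1e-6)
    for (g in gaps) {
      dur <- dt[g]
      start <- s$timestamp[g]
      if (dur < short_gap_min[1]) {
        reports[[length(reports) + 1]] <- data.frame(
          cage_id = cage, gap_start = start, duration_min = dur,
          action = "left_missing")
        next
      }
      lookback_h <- if (dur <= short_gap_min[2]) lookback_short_h else
        lookback_long_h
      look <- s[s$timestamp > start - lookback_h * 3600 &
                  s$timestamp <= start & !is.na(s$o2_ml_min), , drop = FALSE]
      if (nrow(look) == 0L) {
        warning(sprintf("cage %s: gap at series start (%s) has no lookback; left unfilled",
                        cage, format(start)), call. = FALSE)
        reports[[length(reports) + 1]] <- data.frame(
          cage_id = cage, gap_start = start, duration_min = dur,
          action = "unfillable")
        next
      }
      times <- seq(start + cadence_min * 60, by = cadence_min * 60,
                   length.out = max(0, floor(dur / cadence_min) - 1))
      times <- times[times < s$timestamp[g + 1]]
      if (length(times)) {
        fill <- s[rep(g, length(times)), , drop = FALSE]
        fill$timestamp <- times
        fill$o2_ml_min <- mean(look$o2_ml_min, na.rm = TRUE)
        fill$co2_ml_min <- mean(look$co2_ml_min, na.rm = TRUE)
        # hoppers interpolate linearly across the gap (no events observable)
        for (col in intersect(c("water_g", "food_g", "body_mass_g"), names(s))) {
          fill[[col]] <- stats::approx(as.numeric(s$timestamp[c(g, g + 1)]),
                                       s[[col]][c(g, g + 1)],
                                       xout = as.numeric(times))$y
        }
        fill$filled <- TRUE
        added[[length(added) + 1]] <- fill
      }
      reports[[length(reports) + 1]] <- data.frame(
        cage_id = cage, gap_start = start, duration_min = dur,
        action = if (dur <= short_gap_min[2]) "filled_short" else "filled_long")
    }
  }
  out <- rbind(series, do.call(rbind, added))
  out <- out[order(out$cage_id, out$timestamp), , drop = FALSE]
  rownames(out) <- NULL
  gaps <- if (length(reports)) do.call(rbind, reports) else
    data.frame(cage_id = character(), gap_start = as.POSIXct(character()),
               duration_min = numeric(), action = character())
  list(series = out, gaps = gaps)
}

#' Daily food and water intake from hopper traces
#'
#' Reads consumption from hopper mass drops: intake on a calendar day is the
#' sum of negative mass increments (refills, which raise the mass, are
#' ignored).
#'
#' @param series phenotyping data frame.
#' @return a data frame with one row per cage-day: `date`, `cage_id`,
#'   `water_ml` (1 g = 1 ml), `food_g`, and an empty `flags` column.
#' @export
daily_intakes <- function(series) {
  series <- series[order(series$cage_id, series$timestamp), , drop = FALSE]
  res <- list()
  for (cage in unique(series$cage_id)) {
    s <- series[series$cage_id == cage, , drop = FALSE]
    day <- as.Date(s$timestamp[-1])
    dw <- -pmin(diff(s$water_g), 0)
    df <- -pmin(diff(s$food_g), 0)
    agg <- stats::aggregate(cbind(water_ml = dw, food_g = df),
                            by = list(date = day), FUN = sum)
    agg$cage_id <- cage
    res[[cage]] <- agg
  }
  out <- do.call(rbind, res)
  out$flags <- ""
  rownames(out) <- NULL
  out[order(out$cage_id, out$date), c("date", "cage_id", "water_ml", "food_g",
                                      "flags")]
}

#' Correct water intake for drinker leakage
#'
#' Automated drinker hoppers overestimate intake through nozzle drip and
#' spillage; a bulk fraction of the recorded mass loss is removed.
#'
#' @param water_ml numeric vector of daily water intakes (ml).
#' @param leakage_fraction fraction of recorded intake attributed to leakage,
#'   in `[0, 1)`.
#' @return corrected intakes.
#' @examples
#' correct_water_intake(11.6)   # 10.44
#' @export
correct_water_intake <- function(water_ml, leakage_fraction = 0.10) {
  if (leakage_fraction < 0 || leakage_fraction >= 1)
    stop("leakage_fraction must be in [0, 1)", call. = FALSE)
  if (any(water_ml < 0)) stop("water_ml must be non-negative", call. = FALSE)
  water_ml * (1 - leakage_fraction)
}

#' Replace unrealistic daily intakes
#'
#' Days whose water or food intake exceeds a plausibility threshold (water
#' spilled into the cage, or food cached rather than eaten) are replaced with
#' the mean of the same cage's unflagged days, and flagged.
#'
#' @param daily daily-intake data frame (see [daily_intakes()]).
#' @param water_max_ml,food_max_g replacement thresholds.
#' @return the data frame with offending values replaced and
#'   `replaced_outlier` appended to their `flags`.
#' @export
replace_unrealistic <- function(daily, water_max_ml = 12, food_max_g = 8) {
  for (cage in unique(daily$cage_id)) {
    idx <- which(daily$cage_id == cage)
    for (col in c("water_ml", "food_g")) {
      thr <- if (col == "water_ml") water_max_ml else food_max_g
      bad <- daily[[col]][idx] > thr
      if (!any(bad)) next
      if (all(bad))
        stop(sprintf("cage %s: all days exceed the %s threshold; no replacement basis",
                     cage, col), call. = FALSE)
      repl <- mean(daily[[col]][idx][!bad])
      daily[[col]][idx[bad]] <- repl
      daily$flags[idx[bad]] <- paste0(daily$flags[idx[bad]], "+replaced_outlier")
    }
  }
  daily
}

#' Windowed flux totals
#'
#' Integrates QC'd gas rates and sums QC'd daily intakes over the window
#' `(end_time - window_hours, end_time]`, returning a [flux_totals()] object
#' ready for [body_water_model()]. Gas rates are integrated as rate x cadence
#' for each record present; missing slots contribute zero length (not zero
#' rate). Daily intakes are included for days whose date falls inside the
#' window.
#'
#' @param series gap-filled phenotyping series for one cage.
#' @param daily QC'd daily-intake table for the same cage (water already
#'   leak-corrected or not, see `water_leak_corrected`).
#' @param end_time window end (POSIXct).
#' @param window_hours window length in hours.
#' @param cadence_min nominal cadence in minutes.
#' @param water_leak_corrected whether `daily$water_ml` has already had the
#'   leakage correction applied (passed through to [flux_totals()]).
#' @param require_coverage if `TRUE` (default), error when more than one
#'   nominal cadence slot in the window is missing from the gas series.
#' @return a [flux_totals()] object.
#' @export
window_totals <- function(series, daily, end_time, window_hours,
                          cadence_min = 5, water_leak_corrected = TRUE,
                          require_coverage = TRUE) {
  if (length(unique(series$cage_id)) > 1L)
    stop("window_totals expects a single cage", call. = FALSE)
  end_time <- as.POSIXct(end_time, tz = attr(series$timestamp, "tzone") %||% "UTC")
  start <- end_time - window_hours * 3600
  if (window_hours == 0)
    return(flux_totals(0, co2_mol = 0, food_kg = 0, water_ml = 0,
                       window_hours = 0,
                       water_leak_corrected = water_leak_corrected))
  # a record at time t stands for the slot (t, t + cadence]
  s <- series[series$timestamp >= start & series$timestamp < end_time, ,
              drop = FALSE]
  expected <- window_hours * 60 / cadence_min
  if (require_coverage && nrow(s) < expected - 1) {
    stop(sprintf("window not covered: %d of %d cadence slots present between %s and %s",
                 nrow(s), round(expected), format(start), format(end_time)),
         call. = FALSE)
  }
  o2_ml <- sum(s$o2_ml_min) * cadence_min
  co2_ml <- sum(s$co2_ml_min) * cadence_min
  d <- daily[daily$date >= as.Date(start) & daily$date < as.Date(end_time), ,
             drop = FALSE]
  flux_totals(o2_ml = o2_ml, co2_ml = co2_ml,
              food_kg = sum(d$food_g) / 1000, water_ml = sum(d$water_ml),
              window_hours = window_hours,
              water_leak_corrected = water_leak_corrected)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
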