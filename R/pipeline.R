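# End-to-end orchestration: predictions per sample, comparison with measured
# grand means, and treatment contrasts.

#' Model predictions for a cohort
#'
#' Evaluates the flux model once per (mouse, sampling occasion) row of a
#' schedule of windowed totals, using the treatment's configuration.
#'
#' @param schedule data frame with one row per sample: `mouse_id`, `diet`,
#'   `temp_C`, and the windowed totals `o2_ml`, `co2_ml` (or `co2_mol`),
#'   `food_kg`, `water_ml`, `window_hours`, optionally `food_d18O` (per-date
#'   ambient-vapour override) and `water_leak_corrected` (default `TRUE`:
#'   totals come out of the QC chain already corrected).
#' @param ... passed to [treatment_params()] (e.g. `mass_kg`).
#' @return the schedule with predicted `pred_d18O`, `pred_d17O`,
#'   `pred_cap17O` columns appended; rows whose model evaluation fails are
#'   kept with `NA` predictions and a warning.
#' @export
run_predictions <- function(schedule, ...) {
  preds <- lapply(seq_len(nrow(schedule)), function(i) {
    row <- schedule[i, ]
    tryCatch({
      params <- treatment_params(row$diet, row$temp_C,
                                 food_d18O = row$food_d18O %||% NULL, ...)
      tot <- if (!is.null(row$co2_mol) && !is.na(row$co2_mol))
        flux_totals(row$o2_ml, co2_mol = row$co2_mol, food_kg = row$food_kg,
                    water_ml = row$water_ml, window_hours = row$window_hours,
                    water_leak_corrected = row$water_leak_corrected %||% TRUE)
      else
        flux_totals(row$o2_ml, co2_ml = row$co2_ml, food_kg = row$food_kg,
                    water_ml = row$water_ml, window_hours = row$window_hours,
                    water_leak_corrected = row$water_leak_corrected %||% TRUE)
      p <- body_water_model(params, tot)$prediction
      c(p$d18O_permil, p$d17O_permil, p$cap17O_permeg)
    }, error = function(e) {
      warning(sprintf("row %d (%s): %s", i, row$mouse_id, conditionMessage(e)),
              call. = FALSE)
      c(NA_real_, NA_real_, NA_real_)
    })
  })
  preds <- do.call(rbind, preds)
  schedule$pred_d18O <- preds[, 1]
  schedule$pred_d17O <- preds[, 2]
  schedule$pred_cap17O <- preds[, 3]
  schedule
}

#' Compare predictions with measured values
#'
#' Joins predictions to measured grand means on (mouse, occasion), computes
#' per-sample absolute differences, per-group and overall mean absolute
#' differences (MAD +/- SD), and flags samples whose 17O-excess disagreement
#' reaches `flag_cap17O` per meg.
#'
#' @param predictions data frame with `mouse_id`, `occasion`, `group`,
#'   `pred_d18O`, `pred_cap17O`.
#' @param measured data frame with `mouse_id`, `occasion`, `meas_d18O`,
#'   `meas_cap17O`.
#' @param flag_cap17O flag threshold, per meg.
#' @return an object of class `validation_report`: list with `samples` (the
#'   joined per-sample table), `groups` (per-group MAD), `overall` (MAD +/-
#'   SD and the maximum absolute 17O-excess difference).
#' @export
compare_predictions <- function(predictions, measured, flag_cap17O = 30) {
  j <- merge(predictions, measured, by = c("mouse_id", "occasion"))
  if (nrow(j) == 0L) stop("no (mouse, occasion) keys in common", call. = FALSE)
  j$abs_diff_d18O <- abs(j$pred_d18O - j$meas_d18O)
  j$abs_diff_cap17O <- abs(j$pred_cap17O - j$meas_cap17O)
  j$flagged <- j$abs_diff_cap17O >= flag_cap17O
  if (is.null(j$group)) j$group <- "all"
  groups <- stats::aggregate(
    cbind(mad_d18O = j$abs_diff_d18O, mad_cap17O = j$abs_diff_cap17O),
    by = list(group = j$group), FUN = mean)
  overall <- list(mad_d18O = mean(j$abs_diff_d18O),
                  sd_d18O = stats::sd(j$abs_diff_d18O),
                  mad_cap17O = mean(j$abs_diff_cap17O),
                  sd_cap17O = stats::sd(j$abs_diff_cap17O),
                  max_cap17O = max(j$abs_diff_cap17O),
                  n = nrow(j), n_flagged = sum(j$flagged))
  structure(list(samples = j, groups = groups, overall = overall),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  o <- x$overall
  cat(sprintf("Validation over %d samples\n", o$n))
  cat(sprintf("  d18O  MAD %.2f +/- %.2f permil\n", o$mad_d18O, o$sd_d18O))
  cat(sprintf("  17O-excess MAD %.1f +/- %.1f per meg (max %.1f, %d sample(s) >= flag)\n",
              o$mad_cap17O, o$sd_cap17O, o$max_cap17O, o$n_flagged))
  invisible(x)
}

#' Plot a validation report
#'
#' Predicted versus measured 17O-excess with the 1:1 line.
#'
#' @param x a `validation_report`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.validation_report <- function(x, ...) {
  s <- x$samples
  graphics::plot(s$meas_cap17O, s$pred_cap17O,
                 xlab = "measured 17O-excess (per meg)",
                 ylab = "predicted 17O-excess (per meg)", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Paired treatment contrast
#'
#' Paired t-test on per-mouse differences between two treatments, via
#' [stats::t.test()]. Zero-variance nonzero differences (infinite t) are
#' flagged rather than erroring.
#'
#' @param values_a,values_b paired per-mouse values (same mice, same order).
#' @param alternative passed to [stats::t.test()] (default two-sided; the
#'   directional hypotheses of the study design can be tested with
#'   `"greater"`/`"less"`).
#' @return a list with `t`, `df`, `p_value`, `mean_diff`, `degenerate`.
#' @examples
#' paired_treatment_test(c(1, 2, 3), c(2, 3, 5))$t   # -4
#' @export
paired_treatment_test <- function(values_a, values_b,
                                  alternative = "two.sided") {
  if (length(values_a) != length(values_b))
    stop("paired vectors must have equal length", call. = FALSE)
  if (length(values_a) < 2L) stop("need at least 2 pairs", call. = FALSE)
  d <- values_a - values_b
  if (stats::sd(d) == 0) {
    return(list(t = if (mean(d) == 0) 0 else sign(mean(d)) * Inf,
                df = length(d) - 1L, p_value = if (mean(d) == 0) 1 else 0,
                mean_diff = mean(d), degenerate = TRUE))
  }
  tt <- stats::t.test(values_a, values_b, paired = TRUE,
                      alternative = alternative)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_diff = unname(tt$estimate),
       degenerate = FALSE)
}
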