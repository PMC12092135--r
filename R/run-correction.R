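# VSMOW-SLAP normalization of water-isotope analysis runs.
#
# A run is a long table of injections: run_id, water_id, water_role
# (sample/standard/control), replicate_id (distillation replicate), raw_d17O,
# raw_d18O, raw_d2H. Two bracketing standards of known composition define a
# per-isotope two-point stretching/offset correction; control waters of known
# composition gate run acceptance.

iso_cols <- c(d17O = "raw_d17O", d18O = "raw_d18O", d2H = "raw_d2H")

#' Flag outlier injections
#'
#' Single-pass rule: an injection is an outlier in a quantity when it lies
#' more than `k` standard deviations from the initial mean of that quantity.
#' At most `max_frac` of the injections are removed; when the rule flags
#' more, only the most deviant are dropped.
#'
#' @param x numeric vector.
#' @param k SD multiplier (default 2).
#' @param max_frac maximum fraction removed (default 0.2).
#' @return logical vector, `TRUE` for injections to keep.
#' @export
flag_outliers <- function(x, k = 2, max_frac = 0.2) {
  n <- length(x)
  if (n < 3L || stats::sd(x) == 0) return(rep(TRUE, n))
  z <- abs(x - mean(x)) / stats::sd(x)
  out <- z > k
  max_out <- floor(max_frac * n)
  if (sum(out) > max_out) {
    out <- rep(FALSE, n)
    if (max_out > 0) out[order(z, decreasing = TRUE)[seq_len(max_out)]] <- TRUE
  }
  !out
}

#' Fit a two-standard stretching/offset correction
#'
#' Per isotope, solves `corrected = stretching * raw + offset` exactly through
#' the two standards' outlier-trimmed raw means and known values:
#' `stretching = (known_A - known_B) / (rawmean_A - rawmean_B)`.
#'
#' @param run injection table for one analysis run.
#' @param standards data frame with columns `name`, `known_d17O`,
#'   `known_d18O`, `known_d2H` for exactly two standards present in the run.
#' @param outlier_k,outlier_max_frac passed to [flag_outliers()].
#' @return an object of class `correction_model`: a data frame with columns
#'   `isotope`, `stretching`, `offset`.
#' @export
fit_correction <- function(run, standards, outlier_k = 2,
                           outlier_max_frac = 0.2) {
  if (nrow(standards) != 2L)
    stop("exactly two standards are required", call. = FALSE)
  raw_means <- sapply(standards$name, function(nm) {
    inj <- run[run$water_id == nm, , drop = FALSE]
    if (nrow(inj) < 2L)
      stop(sprintf("standard '%s' missing or has < 2 injections", nm),
           call. = FALSE)
    vapply(iso_cols, function(col) {
      x <- inj[[col]]
      mean(x[flag_outliers(x, outlier_k, outlier_max_frac)])
    }, numeric(1))
  })  # 3 x 2 matrix: rows d17O/d18O/d2H, cols standards
  known <- t(as.matrix(standards[paste0("known_", names(iso_cols))]))
  if (any(abs(raw_means[, 1] - raw_means[, 2]) < 1e-12))
    stop("degenerate fit: the two standards have equal raw means", call. = FALSE)
  stretching <- (known[, 1] - known[, 2]) / (raw_means[, 1] - raw_means[, 2])
  offset <- known[, 1] - stretching * raw_means[, 1]
  structure(data.frame(isotope = names(iso_cols), stretching = stretching,
                       offset = offset, row.names = NULL),
            class = c("correction_model", "data.frame"))
}

#' Apply a correction model to injections
#'
#' @param run injection table.
#' @param correction a `correction_model` from [fit_correction()].
#' @return the table with corrected columns `d17O`, `d18O`, `d2H` and the
#'   per-injection `cap17O` (per meg) computed from corrected deltas.
#' @export
apply_correction <- function(run, correction) {
  for (i in seq_along(iso_cols)) {
    iso <- names(iso_cols)[i]
    cm <- correction[correction$isotope == iso, ]
    run[[iso]] <- cm$stretching * run[[iso_cols[i]]] + cm$offset
  }
  run$cap17O <- cap_delta17(run$d17O, run$d18O)
  run
}

#' Summarize one water within a run
#'
#' Applies the correction to every injection of one water, computes the
#' per-injection 17O-excess, removes outlier injections (per quantity, on the
#' corrected values), and returns mean, SD and n for each quantity.
#'
#' @param run injection table (one run).
#' @param water_id the water to summarize.
#' @param correction a `correction_model`.
#' @param outlier_k,outlier_max_frac passed to [flag_outliers()].
#' @return a one-row data frame with `mean_`, `sd_` and `n_` columns for
#'   `d17O`, `d18O` and `cap17O`.
#' @export
summarize_water <- function(run, water_id, correction, outlier_k = 2,
                            outlier_max_frac = 0.2) {
  inj <- run[run$water_id == water_id, , drop = FALSE]
  if (nrow(inj) < 3L)
    stop(sprintf("water '%s': %d injections; at least 3 required",
                 water_id, nrow(inj)), call. = FALSE)
  inj <- apply_correction(inj, correction)
  out <- list(water_id = water_id)
  for (q in c("d17O", "d18O", "cap17O")) {
    keep <- flag_outliers(inj[[q]], outlier_k, outlier_max_frac)
    out[[paste0("mean_", q)]] <- mean(inj[[q]][keep])
    out[[paste0("sd_", q)]] <- stats::sd(inj[[q]][keep])
    out[[paste0("n_", q)]] <- sum(keep)
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Control-water QC gate for a run
#'
#' A control water fails when its corrected mean differs from its known value
#' by at least 0.15 permil in d17O, or 0.3 permil in d18O, or 15 per meg in
#' the 17O-excess. The run is rejected when more than `max_failing` controls
#' fail.
#'
#' @param run injection table (one run).
#' @param controls data frame with columns `name`, `known_d17O`,
#'   `known_d18O` (known 17O-excess derived from these).
#' @param correction a `correction_model`.
#' @param thresholds named numeric: `d17O` and `d18O` in permil, `cap17O` in
#'   per meg; a deviation at or beyond a threshold fails.
#' @param max_failing maximum number of failing controls tolerated.
#' @return an object of class `run_qc`: a list with `run_id`, `n_controls`,
#'   `n_failing`, `accepted`, and a `deviations` data frame.
#' @export
qc_run <- function(run, controls, correction,
                   thresholds = c(d17O = 0.15, d18O = 0.3, cap17O = 15),
                   max_failing = 2) {
  if (nrow(controls) < 1L) stop("at least one control water required", call. = FALSE)
  devs <- do.call(rbind, lapply(seq_len(nrow(controls)), function(i) {
    s <- summarize_water(run, controls$name[i], correction)
    known_cap <- cap_delta17(controls$known_d17O[i], controls$known_d18O[i])
    data.frame(name = controls$name[i],
               dev_d17O = s$mean_d17O - controls$known_d17O[i],
               dev_d18O = s$mean_d18O - controls$known_d18O[i],
               dev_cap17O = s$mean_cap17O - known_cap)
  }))
  devs$failing <- abs(devs$dev_d17O) >= thresholds[["d17O"]] |
    abs(devs$dev_d18O) >= thresholds[["d18O"]] |
    abs(devs$dev_cap17O) >= thresholds[["cap17O"]]
  structure(list(run_id = unique(run$run_id)[1],
                 n_controls = nrow(devs),
                 n_failing = sum(devs$failing),
                 accepted = sum(devs$failing) <= max_failing,
                 deviations = devs),
            class = "run_qc")
}

#' @export
print.run_qc <- function(x, ...) {
  cat(sprintf("Analysis run %s: %d controls, %d failing -> %s\n",
              x$run_id, x$n_controls, x$n_failing,
              if (x$accepted) "ACCEPTED" else "REJECTED"))
  invisible(x)
}

#' Grand mean across distillation replicates
#'
#' Unweighted mean of per-replicate corrected means for one sample (replicates
#' are never weighted by their injection counts, since precision varies
#' between runs, not with n). The 17O-excess is recomputed from the grand-mean
#' deltas. Replicate spread beyond `consistency` (0.3 permil d18O, 15 per meg
#' 17O-excess by default, the expected distillation repeatability) is flagged
#' with a warning.
#'
#' @param replicate_means data frame of per-replicate summaries with columns
#'   `mean_d17O`, `mean_d18O` (e.g. rows from [summarize_water()] across
#'   runs/replicates of one sample).
#' @param consistency named numeric thresholds for the replicate-consistency
#'   warning.
#' @return a one-row data frame: `d17O`, `d18O`, `cap17O`, `n_replicates`,
#'   `consistent`.
#' @export
grand_mean <- function(replicate_means,
                       consistency = c(d18O = 0.3, cap17O = 15)) {
  n <- nrow(replicate_means)
  if (n < 1L) stop("no accepted replicates", call. = FALSE)
  d17 <- mean(replicate_means$mean_d17O)
  d18 <- mean(replicate_means$mean_d18O)
  caps <- cap_delta17(replicate_means$mean_d17O, replicate_means$mean_d18O)
  consistent <- diff(range(replicate_means$mean_d18O)) <= consistency[["d18O"]] &&
    diff(range(caps)) <= consistency[["cap17O"]]
  if (!consistent)
    warning("replicate spread exceeds the expected distillation repeatability",
            call. = FALSE)
  data.frame(d17O = d17, d18O = d18, cap17O = cap_delta17(d17, d18),
             n_replicates = n, consistent = consistent)
}
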