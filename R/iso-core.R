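# Triple-oxygen isotope algebra.
#
# Conventions used throughout the package:
#   * delta values in permil vs VSMOW
#   * 17O-excess (cap-delta-prime-17O) in per meg (1 per meg = 0.001 permil)
#   * fractionation factors alpha and exponents theta dimensionless
#   * the reference slope relating linearized d17O and d18O is 0.528

#' Reference slope of the triple-oxygen reference line
#' @keywords internal
LAMBDA_REF <- 0.528

#' Linearize a delta value
#'
#' Converts a conventional delta value (permil) to its linearized (logarithmic)
#' form, `1000 * ln(1 + delta/1000)`, written delta-prime. The linearized scale
#' makes mass-dependent fractionation laws exactly log-linear, which is why the
#' 17O-excess is defined on it.
#'
#' @param delta_permil numeric vector of delta values in permil; must be
#'   greater than -1000 (an isotope ratio is strictly positive).
#' @return linearized delta values in permil.
#' @seealso [from_linearized()] for the exact inverse.
#' @examples
#' linearize(24.046)
#' from_linearized(linearize(-4))
#' @export
linearize <- function(delta_permil) {
  check_delta(delta_permil)
  1000 * log1p(delta_permil / 1000)
}

#' Invert the linearization of a delta value
#'
#' @param delta_prime_permil numeric vector of linearized delta values (permil).
#' @return conventional delta values in permil.
#' @export
from_linearized <- function(delta_prime_permil) {
  1000 * expm1(delta_prime_permil / 1000)
}

check_delta <- function(x, what = "delta value") {
  if (any(!is.na(x) & x <= -1000))
    stop(sprintf("%s must be > -1000 permil (isotope ratios are positive)", what),
         call. = FALSE)
  invisible(x)
}

#' 17O-excess of a (d17O, d18O) pair
#'
#' Computes the 17O-excess as the deviation of the linearized d17O from the
#' reference line of slope 0.528 through the linearized d18O:
#' `1e6 * (ln(1 + d17O/1000) - 0.528 * ln(1 + d18O/1000))`, in per meg.
#'
#' @param d17O,d18O delta values in permil vs VSMOW (> -1000).
#' @param lambda slope of the reference line (default 0.528).
#' @return 17O-excess in per meg.
#' @seealso [d17O_from_cap()] for the inverse given d18O.
#' @examples
#' cap_delta17(-2.094041, -4)   # drinking water near +20 per meg
#' @export
cap_delta17 <- function(d17O, d18O, lambda = LAMBDA_REF) {
  check_delta(d17O, "d17O")
  check_delta(d18O, "d18O")
  1e6 * (log1p(d17O / 1000) - lambda * log1p(d18O / 1000))
}

#' Recover d17O from d18O and the 17O-excess
#'
#' Closed-form inversion of [cap_delta17()]:
#' `d17O = 1000 * (exp(0.528 * ln(1 + d18O/1000) + cap/1e6) - 1)`.
#' Sources are usually reported as a (d18O, 17O-excess) pair; this builds the
#' implied d17O.
#'
#' @param d18O delta value in permil (> -1000).
#' @param cap17O_permeg 17O-excess in per meg.
#' @param lambda slope of the reference line (default 0.528).
#' @return d17O in permil.
#' @export
d17O_from_cap <- function(d18O, cap17O_permeg, lambda = LAMBDA_REF) {
  check_delta(d18O, "d18O")
  1000 * expm1(lambda * log1p(d18O / 1000) + cap17O_permeg / 1e6)
}

#' Derive the 17/16 fractionation factor from alpha-18 and theta
#'
#' Applies the triple-isotope exponent: `alpha17 = alpha18 ^ theta`
#' (equivalently `exp(theta * ln(alpha18))`).
#'
#' @param alpha18 18/16 fractionation factor(s), strictly positive.
#' @param theta triple-isotope exponent(s); mass-dependent processes fall in
#'   roughly 0.51-0.53.
#' @return 17/16 fractionation factor(s).
#' @examples
#' alpha17_from_theta(0.994156, 0.5179)
#' @export
alpha17_from_theta <- function(alpha18, theta) {
  if (any(alpha18 <= 0))
    stop("alpha18 must be strictly positive", call. = FALSE)
  exp(theta * log(alpha18))
}

#' Absolute isotope ratios of VSMOW
#'
#' The package default uses the literature values 18O/16O = 0.0020052 and
#' 17O/16O = 0.0003799. Delta values and the 17O-excess are provably invariant
#' to this choice (the reference cancels in any ratio round trip), so any
#' consistent published pair may be substituted.
#'
#' @param r18 absolute 18O/16O ratio of the reference water.
#' @param r17 absolute 17O/16O ratio of the reference water.
#' @return an object of class `ref_ratios`.
#' @export
ref_ratios <- function(r18 = 0.0020052, r17 = 0.0003799) {
  if (r18 <= 0 || r17 <= 0) stop("reference ratios must be positive", call. = FALSE)
  structure(list(r18_vsmow = r18, r17_vsmow = r17), class = "ref_ratios")
}

#' Triple-oxygen composition
#'
#' Constructs a triple-oxygen composition from delta values in permil vs
#' VSMOW. The linearized deltas and the 17O-excess are always derived from the
#' stored deltas, never stored independently, so the defining relationship
#' holds by construction.
#'
#' @param d17O,d18O delta values in permil (> -1000); recycled to a common
#'   length.
#' @return a data frame of class `tox` with columns `d17O_permil`,
#'   `d18O_permil`, `d17O_prime_permil`, `d18O_prime_permil`,
#'   `cap17O_permeg`.
#' @seealso [tox_from_cap()] to build a composition from (d18O, 17O-excess).
#' @examples
#' tox(d17O = -2.094041, d18O = -4)
#' tox_from_cap(d18O = 24.046, cap17O_permeg = -441)  # atmospheric O2
#' @export
tox <- function(d17O, d18O) {
  check_delta(d17O, "d17O")
  check_delta(d18O, "d18O")
  n <- max(length(d17O), length(d18O))
  out <- data.frame(d17O_permil = rep_len(d17O, n),
                    d18O_permil = rep_len(d18O, n))
  out$d17O_prime_permil <- linearize(out$d17O_permil)
  out$d18O_prime_permil <- linearize(out$d18O_permil)
  out$cap17O_permeg <- cap_delta17(out$d17O_permil, out$d18O_permil)
  class(out) <- c("tox", "data.frame")
  out
}

#' @rdname tox
#' @param cap17O_permeg 17O-excess in per meg.
#' @export
tox_from_cap <- function(d18O, cap17O_permeg) {
  tox(d17O_from_cap(d18O, cap17O_permeg), d18O)
}

#' @export
print.tox <- function(x, ...) {
  cat("Triple-oxygen composition (permil vs VSMOW; 17O-excess in per meg)\n")
  print(data.frame(d17O = round(x$d17O_permil, 4),
                   d18O = round(x$d18O_permil, 4),
                   cap17O = round(x$cap17O_permeg, 2)), ...)
  invisible(x)
}

#' Absolute isotope ratios of a composition
#'
#' @param comp a [tox()] composition.
#' @param ref a [ref_ratios()] object.
#' @return a data frame with columns `r18` and `r17` (absolute ratios).
#' @seealso [composition_from_ratios()] for the exact inverse.
#' @export
ratios_from_composition <- function(comp, ref = ref_ratios()) {
  stopifnot(inherits(comp, "tox"), inherits(ref, "ref_ratios"))
  data.frame(r18 = ref$r18_vsmow * (1 + comp$d18O_permil / 1000),
             r17 = ref$r17_vsmow * (1 + comp$d17O_permil / 1000))
}

#' Composition from absolute isotope ratios
#'
#' @param r17,r18 absolute 17O/16O and 18O/16O ratios.
#' @param ref a [ref_ratios()] object.
#' @return a [tox()] composition.
#' @export
composition_from_ratios <- function(r17, r18, ref = ref_ratios()) {
  stopifnot(inherits(ref, "ref_ratios"))
  tox(d17O = (r17 / ref$r17_vsmow - 1) * 1000,
      d18O = (r18 / ref$r18_vsmow - 1) * 1000)
}
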