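# Delta-notation <-> atomic-fraction arithmetic for 13C and 15N tracers.
# All deltas are per mil (permil) against the fixed international reference
# ratios; atomic fractions are dimensionless in (0, 1).

.R_REF <- c(C = 0.0111797, N = 0.0036765)

.check_element <- function(element) {
  if (length(element) != 1L || !element %in% c("C", "N"))
    stop("element must be \"C\" or \"N\", got: ", paste(element, collapse = ", "),
         call. = FALSE)
  element
}

#' Reference heavy:light isotope ratio
#'
#' The fixed international reference ratios used throughout the package:
#' 0.0111797 for carbon (VPDB) and 0.0036765 for nitrogen (atmospheric N2).
#'
#' @param element `"C"` or `"N"`.
#' @return The dimensionless heavy:light reference ratio.
#' @examples
#' reference_ratio("C")
#' reference_ratio("N")
#' @export
reference_ratio <- function(element = c("C", "N")) {
  element <- match.arg(element)
  unname(.R_REF[element])
}

#' Convert a delta value to a heavy:light isotope ratio
#'
#' Inverts the delta definition deltaX = (R_sample / R_ref - 1) * 1000, so
#' `R_sample = R_ref * (delta / 1000 + 1)`.
#'
#' @param delta Delta value(s) in per mil. Must exceed -1000 permil (a heavy
#'   isotope ratio must remain positive).
#' @param element `"C"` or `"N"`; selects the reference ratio.
#' @return Heavy:light ratio(s), strictly positive.
#' @examples
#' delta_to_ratio(0, "C")     # the reference ratio itself
#' delta_to_ratio(1000, "C")  # doubled
#' @export
delta_to_ratio <- function(delta, element = c("C", "N")) {
  element <- match.arg(element)
  if (any(!is.finite(delta)) || any(delta <= -1000))
    stop("delta must be finite and > -1000 permil (element ", element, ")",
         call. = FALSE)
  .R_REF[[element]] * (delta / 1000 + 1)
}

#' Convert a heavy:light ratio to the atomic fraction of the heavy isotope
#'
#' `F = R / (R + 1)`: the proportion of the element's atoms that are the
#' heavy isotope.
#'
#' @param ratio Heavy:light isotope ratio(s), strictly positive.
#' @return Atomic fraction(s) in (0, 1), strictly increasing in `ratio`.
#' @examples
#' ratio_to_fraction(1)                    # equal heavy and light: 0.5
#' ratio_to_fraction(reference_ratio("C"))
#' @export
ratio_to_fraction <- function(ratio) {
  if (any(!is.finite(ratio)) || any(ratio <= 0))
    stop("isotope ratio must be finite and > 0", call. = FALSE)
  ratio / (ratio + 1)
}

#' Convert an atomic fraction back to delta notation
#'
#' Inverse of `ratio_to_fraction()` followed by `delta_to_ratio()`:
#' `R = F / (1 - F)`, then `delta = (R / R_ref - 1) * 1000`. Needed by the
#' synthetic generator, which forward-simulates measured deltas from true
#' tracer contents.
#'
#' @param fraction Atomic fraction(s), strictly inside (0, 1).
#' @param element `"C"` or `"N"`.
#' @return Delta value(s) in per mil.
#' @examples
#' fraction_to_delta(ratio_to_fraction(reference_ratio("C")), "C")  # ~0
#' @export
fraction_to_delta <- function(fraction, element = c("C", "N")) {
  element <- match.arg(element)
  if (any(!is.finite(fraction)) || any(fraction <= 0) || any(fraction >= 1))
    stop("atomic fraction must lie strictly inside (0, 1)", call. = FALSE)
  r <- fraction / (1 - fraction)
  (r / .R_REF[[element]] - 1) * 1000
}

#' Delta value to atomic fraction (convenience chain)
#'
#' @param delta Delta value(s) in per mil.
#' @param element `"C"` or `"N"`.
#' @return Atomic fraction(s).
#' @export
delta_to_fraction <- function(delta, element = c("C", "N")) {
  ratio_to_fraction(delta_to_ratio(delta, match.arg(element)))
}

#' Excess (above-background) atomic fraction
#'
#' `E = F_sample - F_control`. The result is returned signed: a sample
#' slightly below its control (possible by measurement noise in unlabeled
#' material) yields a small negative excess. Clamping is deliberately NOT done
#' here; downstream reporting flags negative rates instead, so that the error
#' structure is preserved for the statistics.
#'
#' @param f_sample Atomic fraction(s) of the experimental sample.
#' @param f_control Atomic fraction(s) of the paired unlabeled control.
#' @return Signed excess fraction(s), `abs(value) < 1`.
#' @examples
#' excess_fraction(0.0150, 0.0110)
#' @export
excess_fraction <- function(f_sample, f_control) {
  for (f in list(f_sample, f_control))
    if (any(!is.finite(f)) || any(f <= 0) || any(f >= 1))
      stop("atomic fractions must lie strictly inside (0, 1)", call. = FALSE)
  f_sample - f_control
}
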