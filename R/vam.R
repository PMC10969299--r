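#' Build the vascular hysteresis loop from paired GE/SE first-pass curves
#'
#' The parametric curve of `y = dR2_GE(t)` against `x = (dR2_SE(t))^(3/2)`
#' over the first-pass frames. Negative spin-echo excursions are floored at 0
#' before the 3/2 power; the loop is closed by connecting the last point back
#' to the first. Because the gradient-echo bolus (larger vessels) and the
#' spin-echo bolus (microvessels) peak at slightly different times, the curve
#' encloses an area whose traversal direction encodes which vessel population
#' leads.
#'
#' @param ge_times,ge_values gradient-echo curve (times in s).
#' @param se_times,se_values spin-echo curve on the same time base.
#' @param window optional frame indices restricting to the first pass.
#' @return Object of class `hysteresis_loop`: `x`, `y`, `times`, `closed`.
#' @export
build_vhl <- function(ge_times, ge_values, se_times = ge_times, se_values,
                      window = NULL) {
  if (length(ge_times) != length(se_times) ||
      max(abs(ge_times - se_times)) > 1e-9)
    stop("GE and SE curves must share a time base")
  if (!is.null(window)) {
    ge_values <- ge_values[window]; se_values <- se_values[window]
    ge_times <- ge_times[window]
  }
  x <- pmax(se_values, 0)^1.5
  y <- ge_values
  if (length(x) < 8L) warning("fewer than 8 loop points")
  structure(list(x = x, y = y, times = ge_times, closed = TRUE),
            class = "hysteresis_loop")
}

#' Peak-ratio descriptor of the hysteresis loop
#'
#' `Q_max = max(dR2_GE) / max((dR2_SE)^(3/2))`: the ratio of the
#' gradient-echo peak to the 3/2-power spin-echo peak, the scaling factor of
#' the microvessel-density and vessel-size equations. (The source typography
#' prints the denominator with a GE subscript, inconsistent with the loop's
#' axes; the spin-echo reading is adopted and recorded.)
#'
#' @param ge_values,se_values first-pass curve values (or fitted peaks).
#' @return Scalar Q_max; NA with a warning if the SE peak is not positive.
#' @export
compute_qmax <- function(ge_values, se_values) {
  pg <- max(ge_values); ps <- max(pmax(se_values, 0))^1.5
  if (!is.finite(ps) || ps <= 0) return(NA_real_)
  pg / ps
}

#' Microvessel type indicator: signed area of the hysteresis loop
#'
#' Shoelace formula over the ordered loop points, signed so that a clockwise
#' traversal (in the x-right, y-up plane) is positive. Positive values mark
#' arteriole-dominated voxels (gradient-echo bolus leads), negative values
#' venule/capillary-dominated ones.
#'
#' @param loop `hysteresis_loop`, or a list/data.frame with `x`, `y`.
#' @return Signed area (arbitrary units).
#' @export
compute_mti <- function(loop) {
  x <- loop$x; y <- loop$y
  n <- length(x)
  if (n < 3L) stop("a loop needs at least 3 points")
  j <- c(2:n, 1L)
  shoelace <- 0.5 * sum(x * y[j] - x[j] * y)   # positive = counter-clockwise
  -shoelace
}

#' Microvessel density map value
#'
#' Adopted parse of the density equation:
#' `MVD = (Q_max / beta) * (CBV / (2^4 * pi^2 * ADC * R^4))^(1/3)` with `R`
#' the mean vessel lumen radius. Lengths in mm, so MVD is in 1/mm^2. The
#' parse identifier is recorded in map metadata by the map-level wrapper.
#'
#' @param qmax Q_max value(s).
#' @param cbv blood volume fraction(s).
#' @param adc apparent diffusion coefficient(s), mm^2/s.
#' @param consts [vam_constants()].
#' @return MVD value(s), 1/mm^2 (NA where ADC or inputs are not positive).
#' @export
compute_mvd <- function(qmax, cbv, adc, consts = vam_constants()) {
  out <- (qmax / consts$beta) *
    (cbv / (2^4 * pi^2 * adc * consts$mean_radius_mm^4))^(1 / 3)
  out[!is.finite(out) | adc <= 0 | cbv <= 0 | qmax <= 0] <- NA_real_
  out
}

#' Vessel size index map value
#'
#' Adopted parse: `VSI = (CBV * ADC * beta^3 / (2 pi Q_max^3))^(1/2)`,
#' in mm (reported in micrometres by the map-level wrapper).
#'
#' @inheritParams compute_mvd
#' @return VSI value(s) in mm (NA where Q_max is not positive).
#' @export
compute_vsi <- function(cbv, adc, qmax, consts = vam_constants()) {
  out <- sqrt(cbv * adc * consts$beta^3 / (2 * pi * qmax^3))
  out[!is.finite(out) | qmax <= 0] <- NA_real_
  out
}
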