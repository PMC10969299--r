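#' Physiological and physical constants of the qBOLD model
#'
#' The fixed constants entering the oxygen-metabolism equations: the
#' susceptibility difference between fully oxygenated and fully deoxygenated
#' haemoglobin, the microvascular haematocrit (systemic 0.42 times a 0.85
#' small-vessel correction), the proton gyromagnetic ratio, the main field
#' strength, the arterial oxygen content, the Hill coefficient of oxygen
#' binding to haemoglobin, the haemoglobin half-saturation tension, and the
#' tissue oxygen conductivity.
#'
#' The derived coupling constant `k = (4/3) * pi * gamma * delta_chi * hct * B0`
#' converts `OEF * CBV` into the reversible relaxation-rate offset R2' (in 1/s
#' per unit blood-volume fraction); with this `k` the metabolic-rate equation
#' reduces to Fick's principle `CMRO2 = Ca * CBF * OEF`, the only choice
#' consistent with the extraction-fraction equation.
#'
#' Units note: `Ca` is carried verbatim as printed in the source literature
#' ("mmol/mL"); CMRO2 is therefore reported in `Ca x flow` units without
#' further conversion.
#'
#' @param delta_chi susceptibility difference (dimensionless).
#' @param hct microvascular haematocrit fraction.
#' @param gamma gyromagnetic ratio, rad/s/T.
#' @param B0 field strength, T.
#' @param Ca arterial oxygen content (unit label carried, not converted).
#' @param h Hill coefficient.
#' @param P50 half-saturation oxygen tension, mmHg.
#' @param L tissue oxygen conductivity.
#' @return Named list of constants with derived `k`.
#' @export
physio_constants <- function(delta_chi = 0.264e-6,
                             hct = 0.42 * 0.85,
                             gamma = 2.67502e8,
                             B0 = 3,
                             Ca = 8.68,
                             h = 2.7,
                             P50 = 27,
                             L = 4.4) {
  stopifnot(delta_chi > 0, hct > 0, gamma > 0, B0 > 0, Ca > 0, h > 0,
            P50 > 0, L > 0)
  k <- (4 / 3) * pi * gamma * delta_chi * hct * B0
  list(delta_chi = delta_chi, hct = hct, gamma = gamma, B0 = B0, Ca = Ca,
       h = h, P50 = P50, L = L, k = k)
}

#' Constants of the vascular-architecture equations
#'
#' `beta` is the numerical constant of the microvessel-density equation;
#' `mean_radius_um` is the assumed mean vessel lumen radius in micrometres.
#'
#' @param beta numerical constant.
#' @param mean_radius_um mean vessel lumen radius, micrometres.
#' @return Named list, with the radius also exposed in mm (`mean_radius_mm`).
#' @export
vam_constants <- function(beta = 1.6781, mean_radius_um = 3.0) {
  stopifnot(beta > 0, mean_radius_um > 0)
  list(beta = beta, mean_radius_um = mean_radius_um,
       mean_radius_mm = mean_radius_um * 1e-3)
}
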