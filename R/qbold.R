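#' Oxygen extraction fraction map
#'
#' `OEF = (R2* - R2) / (k * CBV)` with
#' `k = (4/3) pi gamma delta_chi Hct B0` (see [physio_constants()]): the
#' reversible relaxation-rate offset divided by its susceptibility coupling to
#' the deoxygenated blood volume. Values are clamped to the physical range
#' [0, 1]; clamped voxels and voxels with non-positive CBV are flagged.
#'
#' @param r2star,r2 `volume_grid` rate maps in 1/s (or bare arrays).
#' @param cbv CBV map as a fraction (`volume_grid` or array).
#' @param mask logical array restricting the computation.
#' @param consts [physio_constants()].
#' @return `volume_grid` OEF map with validity mask.
#' @export
compute_oef <- function(r2star, r2, cbv, mask = NULL,
                        consts = physio_constants()) {
  rs <- vol_data(r2star); rr <- vol_data(r2); cv <- vol_data(cbv)
  stopifnot(identical(dim(rs), dim(rr)), identical(dim(rs), dim(cv)))
  if (is.null(mask)) mask <- array(TRUE, dim(rs))
  idx <- which(mask)
  oef <- numeric(length(idx))
  ok <- cv[idx] > 0
  raw <- (rs[idx][ok] - rr[idx][ok]) / (consts$k * cv[idx][ok])
  oef[ok] <- pmin(pmax(raw, 0), 1)
  clamped <- logical(length(idx)); clamped[ok] <- raw < 0 | raw > 1
  out <- array(0, dim(rs)); out[idx] <- oef
  valid <- array(FALSE, dim(rs)); valid[idx] <- ok & !clamped
  sp <- if (inherits(r2star, "volume_grid")) r2star$spacing else c(1, 1, 1)
  volume_grid(out, spacing = sp, valid = valid, meta = list(map = "OEF"))
}

#' Cerebral metabolic rate of oxygen map
#'
#' `CMRO2 = Ca * CBF * (R2* - R2) / (k * CBV)`, which with the adopted
#' coupling constant is identically `Ca * CBF * OEF` (Fick's principle).
#' Computed through the clamped OEF map, so values are nonnegative wherever
#' CBF is. Units are `Ca x flow` (the arterial oxygen content's printed unit
#' is carried, not converted).
#'
#' @param cbf CBF map (relative units).
#' @inheritParams compute_oef
#' @return `volume_grid` CMRO2 map.
#' @export
compute_cmro2 <- function(cbf, cbv, r2star, r2, mask = NULL,
                          consts = physio_constants()) {
  oef <- compute_oef(r2star, r2, cbv, mask = mask, consts = consts)
  cf <- vol_data(cbf)
  out <- consts$Ca * cf * oef$data
  valid <- oef$valid & (cf >= 0)
  volume_grid(out, spacing = oef$spacing, valid = valid,
              meta = list(map = "CMRO2", units = "Ca x flow"))
}

#' Capillary oxygen tension map
#'
#' `capiPO2 = P50 * (2/OEF - 1)^(1/h)` (Gjedde form of the haemoglobin
#' dissociation model): at complete extraction (OEF = 1) the capillary
#' tension equals the half-saturation constant P50; the tension diverges as
#' OEF approaches 0, so such voxels are flagged invalid.
#'
#' @param oef OEF map (fractions in (0, 1]).
#' @param mask logical array restricting the computation.
#' @param consts [physio_constants()].
#' @return `volume_grid` capiPO2 map in mmHg.
#' @export
compute_capipo2 <- function(oef, mask = NULL, consts = physio_constants()) {
  oe <- vol_data(oef)
  if (is.null(mask)) mask <- array(TRUE, dim(oe))
  idx <- which(mask)
  ok <- oe[idx] > 0 & oe[idx] <= 1
  po2 <- numeric(length(idx))
  po2[ok] <- consts$P50 * (2 / oe[idx][ok] - 1)^(1 / consts$h)
  out <- array(0, dim(oe)); out[idx] <- po2
  valid <- array(FALSE, dim(oe)); valid[idx] <- ok
  if (inherits(oef, "volume_grid") && !is.null(oef$valid)) valid <- valid & oef$valid
  sp <- if (inherits(oef, "volume_grid")) oef$spacing else c(1, 1, 1)
  volume_grid(out, spacing = sp, valid = valid, meta = list(map = "capiPO2"))
}

#' Mitochondrial (tissue) oxygen tension map
#'
#' `mitoPO2 = capiPO2 - CMRO2 / L`: the capillary tension minus the
#' diffusion-limited drop set by the tissue oxygen conductivity. Negative
#' results (oxygen demand exceeding supply at the model's conductivity) are
#' clamped to 0 and flagged.
#'
#' @param capipo2 capillary oxygen tension map, mmHg.
#' @param cmro2 CMRO2 map.
#' @param mask logical array restricting the computation.
#' @param consts [physio_constants()].
#' @return `volume_grid` mitoPO2 map in mmHg.
#' @export
compute_mitopo2 <- function(capipo2, cmro2, mask = NULL,
                            consts = physio_constants()) {
  cp <- vol_data(capipo2); cm <- vol_data(cmro2)
  stopifnot(identical(dim(cp), dim(cm)))
  if (is.null(mask)) mask <- array(TRUE, dim(cp))
  raw <- cp - cm / consts$L
  out <- pmax(raw, 0) * mask
  valid <- (raw >= 0) & mask
  for (m in list(capipo2, cmro2))
    if (inherits(m, "volume_grid") && !is.null(m$valid)) valid <- valid & m$valid
  sp <- if (inherits(capipo2, "volume_grid")) capipo2$spacing else c(1, 1, 1)
  volume_grid(out, spacing = sp, valid = valid, meta = list(map = "mitoPO2"))
}
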