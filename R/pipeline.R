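#' Compute all twelve biomarker maps for one patient bundle
#'
#' Runs the full mapping chain on raw series: relaxation-rate maps from the
#' multi-echo GE/SE acquisitions, ADC from the two-point DWI, splitting of a
#' hybrid DSC acquisition if present, concentration conversion, automatic AIF
#' selection (separately for GE and SE data), per-voxel gamma-variate
#' first-pass fits, CBV / microvascular CBV / CBF, the qBOLD oxygen maps, and
#' the vascular-architecture maps from the voxelwise hysteresis loops.
#'
#' Per-voxel DSC fitting is restricted to `fit_mask` (default: the tumor
#' mask), which is where the radiomic analysis reads the maps; rate and ADC
#' maps are computed over the whole brain.
#'
#' @param bundle patient bundle from [simulate_patient()] (or an equivalently
#'   shaped list of acquired series plus masks).
#' @param fit_mask logical array of voxels for the per-voxel DSC fits.
#' @param consts [physio_constants()].
#' @param vamc [vam_constants()].
#' @param lambda SVD truncation for the CBF deconvolution.
#' @return List of class `patient_maps`: named `volume_grid`s
#'   (`ceT1w`, `FLAIR`, `ADC`, `CBV`, `CBF`, `OEF`, `CMRO2`, `capiPO2`,
#'   `mitoPO2`, `uCBV`, `MVD`, `VSI`, `MTI`, `R2star`, `R2`), plus masks,
#'   AIF reports, and the label.
#' @export
map_patient <- function(bundle, fit_mask = NULL,
                        consts = physio_constants(), vamc = vam_constants(),
                        lambda = 0.2) {
  brain <- bundle$gt$brain_mask
  tumor <- bundle$gt$tumor_mask
  if (is.null(fit_mask)) fit_mask <- tumor
  sp <- bundle$gt$spacing

  r2star <- fit_rate_map(bundle$ge_echo, mask = brain)
  r2 <- fit_rate_map(bundle$se_echo, mask = brain)
  adc <- compute_adc(bundle$dwi, mask = brain)

  dsc <- if (inherits(bundle$dsc, "dsc_hybrid")) split_gese(bundle$dsc) else bundle$dsc
  curves_ge <- signal_to_delta_r2(dsc$ge, mask = brain)
  curves_se <- signal_to_delta_r2(dsc$se, mask = brain)
  aif_ge <- select_aif(curves_ge, brain)
  aif_se <- select_aif(curves_se, brain)

  rows <- match(which(fit_mask), curves_ge$voxel_idx)
  rows <- rows[!is.na(rows)]
  fits_ge <- fit_first_pass_matrix(curves_ge$times, curves_ge$dr2[rows, , drop = FALSE])
  fits_se <- fit_first_pass_matrix(curves_se$times, curves_se$dr2[rows, , drop = FALSE])
  vox <- curves_ge$voxel_idx[rows]

  dm <- dim(brain)
  put <- function(vals, valid = is.finite(vals), meta = list()) {
    a <- array(0, dm); a[vox] <- ifelse(is.finite(vals), vals, 0)
    v <- array(FALSE, dm); v[vox] <- valid & is.finite(vals)
    volume_grid(a, spacing = sp, valid = v, meta = meta)
  }

  cbv_v <- compute_cbv_values(fits_ge, aif_ge)
  mcbv_v <- compute_cbv_values(fits_se, aif_se)
  cbf_v <- compute_cbf_values(curves_ge$dr2[rows, , drop = FALSE], aif_ge,
                              lambda = lambda)
  cbv <- put(cbv_v, meta = list(map = "CBV"))
  mcbv <- put(mcbv_v, meta = list(map = "uCBV"))
  cbf <- put(cbf_v, meta = list(map = "CBF", units = "relative"))

  oef <- compute_oef(r2star, r2, cbv, mask = cbv$valid, consts = consts)
  cmro2 <- compute_cmro2(cbf, cbv, r2star, r2, mask = cbv$valid, consts = consts)
  capi <- compute_capipo2(oef, mask = cbv$valid, consts = consts)
  mito <- compute_mitopo2(capi, cmro2, mask = cbv$valid, consts = consts)

  # voxelwise vascular architecture from the fitted first-pass curves
  nv <- length(vox)
  qmax_v <- mti_v <- rep(NA_real_, nv)
  both <- fits_ge$valid & fits_se$valid
  tt <- curves_ge$times
  for (i in which(both)) {
    gev <- gamma_variate(tt, fits_ge$K[i], fits_ge$t0[i], fits_ge$alpha[i], fits_ge$b[i])
    sev <- gamma_variate(tt, fits_se$K[i], fits_se$t0[i], fits_se$alpha[i], fits_se$b[i])
    qmax_v[i] <- fits_ge$peak[i] / fits_se$peak[i]^1.5
    mti_v[i] <- compute_mti(build_vhl(tt, gev, tt, sev))
  }
  adc_v <- adc$data[vox]
  mvd_v <- compute_mvd(qmax_v, cbv_v, adc_v, consts = vamc)
  vsi_v <- compute_vsi(cbv_v, adc_v, qmax_v, consts = vamc)

  parse_meta <- list(
    mvd_parse = "MVD=(Qmax/beta)*(CBV/(2^4 pi^2 ADC R^4))^(1/3)",
    vsi_parse = "VSI=(CBV*ADC*beta^3/(2 pi Qmax^3))^(1/2)",
    qmax_parse = "Qmax=max(dR2_GE)/max(dR2_SE)^(3/2)")

  maps <- list(
    ceT1w = volume_grid(vol_data(bundle$cet1w), spacing = sp),
    FLAIR = volume_grid(vol_data(bundle$flair), spacing = sp),
    ADC = adc, CBV = cbv, CBF = cbf,
    OEF = oef, CMRO2 = cmro2, capiPO2 = capi, mitoPO2 = mito,
    uCBV = mcbv,
    MVD = put(mvd_v, meta = c(list(map = "MVD", units = "1/mm^2"), parse_meta)),
    VSI = put(vsi_v * 1e3, meta = c(list(map = "VSI", units = "um"), parse_meta)),
    MTI = put(mti_v, meta = c(list(map = "MTI"), parse_meta)),
    R2star = r2star, R2 = r2)
  structure(c(maps,
              list(brain_mask = brain, tumor_mask = tumor,
                   aif_ge = aif_ge, aif_se = aif_se,
                   label = bundle$label, fit_voxels = vox,
                   fits_ge = fits_ge, fits_se = fits_se)),
            class = "patient_maps")
}

#' Map names of each radiomic data category
#'
#' Fixed, canonical map ordering per category: clinical MRI, oxygen
#' metabolism, vascular architecture, and their physio-metabolic combination.
#'
#' @param category one of "cmri", "oxymet", "vam", "oxyvam".
#' @return Character vector of map names.
#' @export
category_maps <- function(category = c("cmri", "oxymet", "vam", "oxyvam")) {
  category <- match.arg(category)
  switch(category,
         cmri = c("ceT1w", "FLAIR", "ADC", "CBV"),
         oxymet = c("OEF", "CMRO2", "capiPO2", "mitoPO2"),
         vam = c("uCBV", "MVD", "VSI", "MTI"),
         oxyvam = c("OEF", "CMRO2", "capiPO2", "mitoPO2",
                    "uCBV", "MVD", "VSI", "MTI"))
}
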