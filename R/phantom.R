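#' Phantom specification
#'
#' Describes one synthetic "patient": grid geometry, an ellipsoidal tumor, the
#' tumor class, the acquisition protocol to emulate, and the RNG seed. The two
#' protocols mirror a bicentric setting: `site_A_separate` acquires gradient-
#' echo and spin-echo DSC as two 60-frame series; `site_B_hybrid` acquires one
#' 80-frame interleaved gradient-echo/spin-echo series at double contrast dose
#' and a different repetition time.
#'
#' @param grid_shape integer length-3, voxels per axis.
#' @param voxel_size_mm isotropic voxel size, mm.
#' @param tumor_center tumor ellipsoid centre, voxel coordinates.
#' @param tumor_radii tumor ellipsoid radii, voxels (scalar or length 3).
#' @param class_label "IDHwt" or "IDHmut".
#' @param seed integer RNG seed; the same spec and seed give byte-identical output.
#' @param protocol "site_A_separate" or "site_B_hybrid".
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(64, 64, 64),
                         voxel_size_mm = 1,
                         tumor_center = grid_shape * c(0.62, 0.55, 0.5),
                         tumor_radii = c(9, 8, 8),
                         class_label = c("IDHwt", "IDHmut"),
                         seed = 1L,
                         protocol = c("site_A_separate", "site_B_hybrid")) {
  class_label <- match.arg(class_label)
  protocol <- match.arg(protocol)
  if (length(tumor_radii) == 1L) tumor_radii <- rep(tumor_radii, 3L)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 8L), voxel_size_mm > 0,
            length(tumor_center) == 3L, length(tumor_radii) == 3L,
            all(tumor_radii > 0))
  structure(list(grid_shape = as.integer(grid_shape),
                 voxel_size_mm = voxel_size_mm,
                 tumor_center = tumor_center, tumor_radii = tumor_radii,
                 class_label = class_label, seed = as.integer(seed),
                 protocol = protocol),
            class = "phantom_spec")
}

#' Class-conditional effect model for the two tumor genotypes
#'
#' Tumor-voxel distributions (mean, sd) of each ground-truth field per class,
#' plus the cohort prevalence of the wildtype class. Defaults encode the
#' oxygen-metabolic contrast between genotypes: wildtype tumors are hypoxic
#' and neovascularised (higher OEF, CBV and microvascular CBV, mostly
#' arteriole-dominated i.e. clockwise hysteresis loops), mutant tumors sit in
#' a more oxygenated, less vascularised microenvironment with higher
#' diffusivity. Magnitudes are chosen as physiologically plausible
#' (roughly two-standard-deviation class separation on OEF and CBV); they are
#' configuration, not a fit to any cohort.
#'
#' `sd` entries are the between-patient spread used when drawing a cohort;
#' within one tumor the voxel-level spread is `intra_frac` times `sd`.
#'
#' @param IDHwt,IDHmut named lists of `c(mean, sd)` per field (`oef`, `cbv`,
#'   `cbf`, `adc`, `mcbv`) plus `p_clockwise`, the probability that the
#'   tumor's vascular hysteresis loop is arteriole-dominated (clockwise).
#' @param normal scalar field values outside the tumor.
#' @param prevalence prevalence of IDHwt in a simulated cohort.
#' @param intra_frac within-tumor voxel sd as a fraction of the class sd.
#' @param effect_scale multiplier on all class-vs-normal mean differences;
#'   0 gives two identical classes (null configuration).
#' @return Object of class `class_effect_model`.
#' @export
class_effect_model <- function(
    IDHwt = list(oef = c(0.55, 0.06), cbv = c(0.085, 0.012),
                 cbf = c(65, 8), adc = c(0.95e-3, 0.12e-3),
                 mcbv = c(0.034, 0.005), p_clockwise = 0.9),
    IDHmut = list(oef = c(0.35, 0.06), cbv = c(0.050, 0.010),
                  cbf = c(48, 7), adc = c(1.25e-3, 0.15e-3),
                  mcbv = c(0.018, 0.004), p_clockwise = 0.25),
    normal = list(oef = 0.40, cbv = 0.030, cbf = 50, adc = 0.80e-3,
                  mcbv = 0.012, r2 = 12, s0 = 1000),
    prevalence = 0.74,
    intra_frac = 0.5,
    effect_scale = 1) {
  stopifnot(prevalence > 0, prevalence <= 1, intra_frac >= 0, effect_scale >= 0)
  if (effect_scale != 1) {
    mid <- lapply(c("oef", "cbv", "cbf", "adc", "mcbv"), function(f) {
      (IDHwt[[f]][1] + IDHmut[[f]][1]) / 2
    })
    names(mid) <- c("oef", "cbv", "cbf", "adc", "mcbv")
    for (f in names(mid)) {
      IDHwt[[f]][1] <- mid[[f]] + effect_scale * (IDHwt[[f]][1] - mid[[f]])
      IDHmut[[f]][1] <- mid[[f]] + effect_scale * (IDHmut[[f]][1] - mid[[f]])
    }
    pm <- (IDHwt$p_clockwise + IDHmut$p_clockwise) / 2
    IDHwt$p_clockwise <- pm + effect_scale * (IDHwt$p_clockwise - pm)
    IDHmut$p_clockwise <- pm + effect_scale * (IDHmut$p_clockwise - pm)
  }
  structure(list(IDHwt = IDHwt, IDHmut = IDHmut, normal = normal,
                 prevalence = prevalence, intra_frac = intra_frac),
            class = "class_effect_model")
}

# physiological plausibility clamps for ground-truth fields
.gt_clamp <- function(field, x) {
  switch(field,
         oef  = pmin(pmax(x, 1e-3), 1),
         cbv  = pmin(pmax(x, 1e-4), 0.2),
         mcbv = pmin(pmax(x, 1e-4), 0.2),
         adc  = pmin(pmax(x, 1e-5), 4e-3),
         cbf  = pmax(x, 0),
         x)
}

# spatially smooth field with exact first two moments inside a compartment
.coherent_field <- function(idx, shape, mean, sd, noise_cache) {
  n <- length(idx)
  if (sd <= 0 || n < 2L) return(rep(mean, n))
  z <- noise_cache[idx]
  z <- (z - mean(z)) / stats::sd(z)
  mean + sd * z
}

#' Generate ground-truth maps and masks for one phantom
#'
#' Draws per-voxel ground-truth physiology from the class-conditional effect
#' model: smooth fields inside the brain and tumor compartments, a binary
#' brain mask (large ellipsoid), the tumor ellipsoid, and a small designated
#' arterial region (earliest/tallest/narrowest bolus curves, blood volume
#' fraction 1) used by the automatic AIF search downstream. Tumor fields are
#' moment-matched: the voxel sample mean inside the tumor equals the requested
#' class mean exactly, and `sd = 0` collapses the tumor to a constant.
#'
#' @param spec `phantom_spec`.
#' @param effects `class_effect_model`.
#' @param override_means optional named list replacing tumor field means
#'   (used by [simulate_cohort()] to inject per-patient means).
#' @return List with `maps` (named list of 3-D arrays: `s0`, `r2`, `oef`,
#'   `cbv`, `mcbv`, `cbf`, `adc`, `loop_orientation`), `brain_mask`,
#'   `tumor_mask`, `arterial_mask` (logical arrays), `spec`, and `spacing`.
#' @export
make_phantom <- function(spec, effects = class_effect_model(),
                         override_means = NULL) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(effects, "class_effect_model"))
  gs <- spec$grid_shape
  set.seed(spec$seed)

  brain <- ellipsoid_mask(gs, gs / 2 + 0.5, gs * 0.46)
  tumor <- ellipsoid_mask(gs, spec$tumor_center, spec$tumor_radii)
  if (any(tumor & !brain) || !any(tumor))
    stop("tumor ellipsoid must lie fully inside the brain mask")
  art_center <- c(gs[1] * 0.30, gs[2] * 0.30, gs[3] * 0.5)
  arterial <- ellipsoid_mask(gs, art_center, max(2.2, gs[1] * 0.035)) & brain & !tumor

  cls <- effects[[spec$class_label]]
  nrm <- effects$normal
  intra <- effects$intra_frac
  noise <- smooth3d(array(stats::rnorm(prod(gs)), gs), passes = 2L)

  ib <- which(brain & !tumor)
  it <- which(tumor)
  maps <- list()
  for (f in c("oef", "cbv", "cbf", "adc", "mcbv")) {
    a <- array(0, gs)
    # mild spatial variation in normal brain (5% of the normal value)
    a[ib] <- .gt_clamp(f, .coherent_field(ib, gs, nrm[[f]], 0.05 * nrm[[f]], noise))
    m <- if (!is.null(override_means[[f]])) override_means[[f]] else cls[[f]][1]
    a[it] <- .gt_clamp(f, .coherent_field(it, gs, m, intra * cls[[f]][2], noise))
    maps[[f]] <- a
  }
  maps$cbv[arterial] <- 1      # arterial blood volume fraction ~ 1
  maps$mcbv[arterial] <- 1

  s0 <- array(0, gs); s0[brain] <- nrm$s0
  r2 <- array(0, gs); r2[brain] <- nrm$r2
  r2[it] <- nrm$r2 * 1.1       # modest tumor R2 elevation
  maps$s0 <- s0; maps$r2 <- r2

  orient <- array(1, gs)
  p_cw <- if (!is.null(override_means$p_clockwise)) override_means$p_clockwise else cls$p_clockwise
  tumor_orient <- if (stats::runif(1) < p_cw) 1 else -1
  orient[it] <- tumor_orient
  maps$loop_orientation <- orient

  list(maps = maps, brain_mask = brain, tumor_mask = tumor,
       arterial_mask = arterial, spec = spec,
       spacing = rep(spec$voxel_size_mm, 3L))
}

#' Forward-simulate a multi-echo series from ground truth
#'
#' Voxel signal decays mono-exponentially with echo time: `S0 * exp(-TE R2*)`
#' for gradient echoes, where `R2* = R2 + k * CBV * OEF` (the qBOLD reversible
#' offset), and `S0 * exp(-TE R2)` for spin echoes. Gaussian noise on the
#' magnitude is added per echo (Rician optionally).
#'
#' @param gt phantom from [make_phantom()].
#' @param echo_times echo times in ms, strictly increasing, at least 3.
#' @param kind "GE" or "SE".
#' @param noise_sd noise sd relative to the tissue baseline signal.
#' @param rician use Rician instead of Gaussian magnitude noise.
#' @param consts [physio_constants()].
#' @return Object of class `echo_series`: list of 3-D volumes, `echo_times`
#'   (ms), `kind`, `spacing`.
#' @export
simulate_echo_series <- function(gt, echo_times = c(5, 10, 15, 20, 25, 30),
                                 kind = c("GE", "SE"), noise_sd = 0,
                                 rician = FALSE, consts = physio_constants()) {
  kind <- match.arg(kind)
  stopifnot(length(echo_times) >= 3L, all(diff(echo_times) > 0))
  if (any(echo_times <= 0)) stop("echo times must be positive")
  rate <- gt$maps$r2
  if (kind == "GE") rate <- rate + consts$k * gt$maps$cbv * gt$maps$oef
  s0 <- gt$maps$s0
  base <- max(s0)
  vols <- lapply(echo_times, function(te) {
    s <- s0 * exp(-(te / 1000) * rate)
    if (noise_sd > 0) {
      eps <- array(stats::rnorm(length(s), 0, noise_sd * base), dim(s))
      if (rician) {
        eps2 <- array(stats::rnorm(length(s), 0, noise_sd * base), dim(s))
        s <- sqrt((s + eps)^2 + eps2^2)
      } else s <- s + eps
    }
    s
  })
  structure(list(volumes = vols, echo_times = echo_times, kind = kind,
                 spacing = gt$spacing),
            class = "echo_series")
}

# Canonical first-pass shapes shared by the forward model and by the
# ground-truth microvascular descriptors: arterial input (early, tall,
# narrow) and tissue response (later, dispersed), both normalised to unit
# area so that area ratios equal blood-volume fractions.
.dsc_shapes <- function() {
  list(art = list(t0 = 15, alpha = 2.5, b = 1.2),
       tis = list(t0 = 18, alpha = 3.0, b = 1.8),
       c_art = 150)   # total arterial concentration-time area, s^-1 * s
}

# protocol timing defaults: site A separate 60-frame GE + SE series;
# site B one hybrid 80-frame interleaved series, double dose, longer TR
.protocol_timing <- function(protocol) {
  if (protocol == "site_A_separate")
    list(n_frames = 60L, frame_interval = 1.5, te_ge = 30, te_se = 80,
         dose_scale = 1)
  else
    list(n_frames = 80L, frame_interval = 1.7, te_ge = 25, te_se = 85,
         dose_scale = 2)
}

.dynamic_series <- function(signal, frame_interval, echo_time, echo_kind,
                            baseline_window, spacing) {
  structure(list(signal = signal, frame_interval = frame_interval,
                 echo_time = echo_time, echo_kind = echo_kind,
                 baseline_window = baseline_window, spacing = spacing),
            class = "dynamic_series")
}

#' Forward-simulate DSC perfusion series
#'
#' Each voxel's concentration curve is a unit-area gamma-variate scaled by the
#' voxel blood volume: total blood volume for the gradient-echo series,
#' microvascular blood volume for the spin-echo series. The designated
#' arterial region carries the arterial shape (earlier, taller, narrower). The
#' spin-echo bolus is shifted in time by `shift_frames` with the sign given by
#' the voxel's loop orientation, so the gradient-echo/spin-echo hysteresis
#' loop closes clockwise (arteriole-dominated, +1) or counter-clockwise (-1).
#' Signal is formed as `S(t) = S_base * exp(-TE * dR2(t))` plus magnitude
#' noise. Site A returns two series (GE, SE); site B returns one hybrid series
#' with both echoes per frame.
#'
#' @param gt phantom from [make_phantom()].
#' @param protocol overrides the phantom's protocol if given.
#' @param timing optional list overriding `n_frames`, `frame_interval`,
#'   `te_ge`, `te_se` (ms).
#' @param dose_scale contrast dose multiplier (> 0).
#' @param noise_sd magnitude noise sd relative to baseline signal.
#' @param shift_frames gradient-echo/spin-echo bolus shift in frames.
#' @return For `site_A_separate`: list with `ge` and `se` `dynamic_series`.
#'   For `site_B_hybrid`: object of class `dsc_hybrid` with per-frame GE and
#'   SE echoes.
#' @export
simulate_dsc <- function(gt, protocol = NULL, timing = NULL, dose_scale = NULL,
                         noise_sd = 0, shift_frames = 1) {
  protocol <- if (is.null(protocol)) gt$spec$protocol else protocol
  tm <- .protocol_timing(protocol)
  if (!is.null(timing)) tm[names(timing)] <- timing
  if (!is.null(dose_scale)) tm$dose_scale <- dose_scale
  if (tm$dose_scale <= 0) stop("dose_scale must be positive")
  sh <- .dsc_shapes()
  tt <- (seq_len(tm$n_frames) - 1) * tm$frame_interval
  n_base <- sum(tt < sh$art$t0 - 2)
  if (n_base < 5L) stop("timing leaves fewer than 5 pre-bolus baseline frames")

  gs <- dim(gt$maps$cbv)
  art_unit <- gamma_variate(tt, 1, sh$art$t0, sh$art$alpha, sh$art$b) /
    gamma_variate_area(1, sh$art$alpha, sh$art$b)
  tis_unit <- gamma_variate(tt, 1, sh$tis$t0, sh$tis$alpha, sh$tis$b) /
    gamma_variate_area(1, sh$tis$alpha, sh$tis$b)
  dt_shift <- shift_frames * tm$frame_interval
  tis_unit_late <- gamma_variate(tt, 1, sh$tis$t0 + dt_shift, sh$tis$alpha, sh$tis$b) /
    gamma_variate_area(1, sh$tis$alpha, sh$tis$b)
  tis_unit_early <- gamma_variate(tt, 1, sh$tis$t0 - dt_shift, sh$tis$alpha, sh$tis$b) /
    gamma_variate_area(1, sh$tis$alpha, sh$tis$b)

  scale <- sh$c_art * tm$dose_scale
  art <- gt$arterial_mask
  cw <- gt$maps$loop_orientation > 0

  # per-voxel dR2(t): volume-scaled unit-area curves
  build_dr2 <- function(vol_frac, unit_cw, unit_ccw, arterial_shape) {
    out <- array(0, c(gs, length(tt)))
    v <- as.vector(vol_frac)
    for (k in seq_along(tt)) {
      fr <- v * ifelse(cw, unit_cw[k], unit_ccw[k]) * scale
      fr[art] <- v[art] * arterial_shape[k] * scale
      out[, , , k] <- fr
    }
    out
  }
  dr2_ge <- build_dr2(gt$maps$cbv, tis_unit, tis_unit, art_unit)
  dr2_se <- build_dr2(gt$maps$mcbv, tis_unit_late, tis_unit_early, art_unit)

  to_signal <- function(dr2, te_ms) {
    sb <- as.vector(gt$maps$s0)
    sig <- array(0, dim(dr2))
    for (k in seq_len(dim(dr2)[4]))
      sig[, , , k] <- sb * exp(-(te_ms / 1000) * dr2[, , , k])
    if (noise_sd > 0)
      sig <- sig + array(stats::rnorm(length(sig), 0, noise_sd * max(sb)), dim(sig))
    sig
  }

  if (protocol == "site_A_separate") {
    list(ge = .dynamic_series(to_signal(dr2_ge, tm$te_ge), tm$frame_interval,
                              tm$te_ge, "GE", seq_len(n_base), gt$spacing),
         se = .dynamic_series(to_signal(dr2_se, tm$te_se), tm$frame_interval,
                              tm$te_se, "SE", seq_len(n_base), gt$spacing))
  } else {
    structure(list(ge_signal = to_signal(dr2_ge, tm$te_ge),
                   se_signal = to_signal(dr2_se, tm$te_se),
                   echo_times = c(GE = tm$te_ge, SE = tm$te_se),
                   echo_tags = c("GE", "SE"),
                   frame_interval = tm$frame_interval,
                   baseline_window = seq_len(n_base), spacing = gt$spacing),
              class = "dsc_hybrid")
  }
}

#' Forward-simulate the two-point diffusion acquisition
#'
#' @param gt phantom from [make_phantom()].
#' @param noise_sd magnitude noise sd relative to the b=0 signal.
#' @return List with `s0`, `s1000` volumes and `b_values = c(0, 1000)`.
#' @export
simulate_dwi <- function(gt, noise_sd = 0) {
  s0 <- gt$maps$s0
  s1000 <- s0 * exp(-1000 * gt$maps$adc)
  if (noise_sd > 0) {
    s0 <- s0 + array(stats::rnorm(length(s0), 0, noise_sd * max(s0)), dim(s0))
    s1000 <- s1000 + array(stats::rnorm(length(s1000), 0, noise_sd * max(gt$maps$s0)), dim(s1000))
  }
  list(s0 = s0, s1000 = s1000, b_values = c(0, 1000), spacing = gt$spacing)
}

#' Forward-simulate anatomical contrasts (plumbing for the clinical category)
#'
#' Synthetic contrast-enhanced T1w and FLAIR volumes as contrast-weighted
#' composites of the ground-truth maps: enhancement tracks blood volume,
#' FLAIR hyperintensity tracks diffusivity changes. These stand in for
#' acquired anatomical scans, which the real pipeline treats as given inputs.
#'
#' @param gt phantom from [make_phantom()].
#' @param kind "ceT1w" or "FLAIR".
#' @param noise_sd noise sd relative to mean brain signal.
#' @return 3-D array.
#' @export
simulate_anatomical <- function(gt, kind = c("ceT1w", "FLAIR"), noise_sd = 0) {
  kind <- match.arg(kind)
  b <- gt$brain_mask
  img <- array(0, dim(gt$maps$s0))
  if (kind == "ceT1w") {
    img[b] <- 600 + 6000 * gt$maps$cbv[b]
  } else {
    img[b] <- 500 + 4e5 * pmax(0, gt$maps$adc[b] - 0.7e-3)
  }
  if (noise_sd > 0)
    img <- img + array(stats::rnorm(length(img), 0, noise_sd * mean(img[b])), dim(img))
  img
}

#' Simulate one complete patient bundle
#'
#' Runs all forward models for one phantom: ground truth, multi-echo GE/SE
#' relaxometry, the protocol's DSC acquisition(s), two-point DWI, and the
#' anatomical composites.
#'
#' @param spec `phantom_spec`.
#' @param effects `class_effect_model`.
#' @param noise_sd shared relative noise level for all raw series.
#' @param override_means see [make_phantom()].
#' @return Named list (a "patient bundle").
#' @export
simulate_patient <- function(spec, effects = class_effect_model(),
                             noise_sd = 0, override_means = NULL) {
  gt <- make_phantom(spec, effects, override_means = override_means)
  ge_echo <- simulate_echo_series(gt, kind = "GE", noise_sd = noise_sd)
  se_echo <- simulate_echo_series(gt, kind = "SE", noise_sd = noise_sd)
  dsc <- simulate_dsc(gt, noise_sd = noise_sd)
  dwi <- simulate_dwi(gt, noise_sd = noise_sd)
  list(spec = spec, label = spec$class_label, gt = gt,
       ge_echo = ge_echo, se_echo = se_echo, dsc = dsc, dwi = dwi,
       cet1w = simulate_anatomical(gt, "ceT1w", noise_sd = noise_sd),
       flair = simulate_anatomical(gt, "FLAIR", noise_sd = noise_sd))
}

#' Simulate a two-class cohort of patient bundles
#'
#' Class labels are allocated at the configured prevalence (stratified:
#' `round(n * prevalence)` wildtype patients, order shuffled), per-patient
#' tumor means are drawn from the class-conditional between-patient
#' distributions, and per-patient seeds are derived deterministically from the
#' cohort seed.
#'
#' @param n number of patients (>= 2).
#' @param effects `class_effect_model`.
#' @param protocol acquisition protocol for every patient.
#' @param seed cohort seed.
#' @param grid_shape,voxel_size_mm grid geometry per patient.
#' @param noise_sd relative noise level of the raw series.
#' @param lazy if TRUE, return specs/labels plus a `build(i)` closure instead
#'   of materialising every raw series at once (memory-friendly for large n).
#' @return List with `labels`, `specs`, `patient_means`, and either
#'   `patients` (list of bundles) or `build`.
#' @export
simulate_cohort <- function(n, effects = class_effect_model(),
                            protocol = "site_A_separate", seed = 1L,
                            grid_shape = c(32, 32, 32), voxel_size_mm = 1,
                            noise_sd = 0.01, lazy = FALSE) {
  stopifnot(n >= 2)
  set.seed(seed)
  n_wt <- round(effects$prevalence * n)
  labels <- sample(c(rep("IDHwt", n_wt), rep("IDHmut", n - n_wt)))
  patient_seeds <- sample.int(.Machine$integer.max - 1L, n)
  # per-patient tumor means and geometry
  draws <- lapply(seq_len(n), function(i) {
    cls <- effects[[labels[i]]]
    m <- lapply(c("oef", "cbv", "cbf", "adc", "mcbv"), function(f)
      .gt_clamp(f, stats::rnorm(1, cls[[f]][1], cls[[f]][2])))
    names(m) <- c("oef", "cbv", "cbf", "adc", "mcbv")
    m$p_clockwise <- cls$p_clockwise
    m
  })
  centers <- lapply(seq_len(n), function(i)
    grid_shape * c(stats::runif(1, 0.58, 0.66), stats::runif(1, 0.50, 0.60),
                   stats::runif(1, 0.45, 0.55)))
  radii <- lapply(seq_len(n), function(i)
    stats::runif(3, 0.14, 0.20) * grid_shape)
  specs <- lapply(seq_len(n), function(i)
    phantom_spec(grid_shape = grid_shape, voxel_size_mm = voxel_size_mm,
                 tumor_center = centers[[i]], tumor_radii = radii[[i]],
                 class_label = labels[i], seed = patient_seeds[i],
                 protocol = protocol))
  build <- function(i) simulate_patient(specs[[i]], effects,
                                        noise_sd = noise_sd,
                                        override_means = draws[[i]])
  out <- list(labels = labels, specs = specs, patient_means = draws,
              seed = seed, protocol = protocol)
  if (lazy) out$build <- build else out$patients <- lapply(seq_len(n), build)
  out
}
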