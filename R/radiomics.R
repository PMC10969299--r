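#' Grey-level discretization policy
#'
#' Two modes mirror how anatomical images and quantitative biomarker maps are
#' prepared for feature extraction. `zscore_binwidth`: z-score normalise over
#' a reference mask, then discretize with a fixed bin width (default 0.1,
#' giving on the order of 60 bins for brain images). `range_binwidth`: clip
#' to a physiologically reasonable value range and discretize with a fixed
#' per-map bin width chosen so the histogram has 60-67 bins (default
#' range/64).
#'
#' @param mode "zscore_binwidth" or "range_binwidth".
#' @param bin_width bin width in map units (z-score units for the first mode).
#' @param value_range length-2 numeric, required for `range_binwidth`.
#' @param target_bins admissible bin-count window for range mode.
#' @return Object of class `discretization_policy`.
#' @export
discretization_policy <- function(mode = c("zscore_binwidth", "range_binwidth"),
                                  bin_width = NULL, value_range = NULL,
                                  target_bins = c(60, 67)) {
  mode <- match.arg(mode)
  if (mode == "range_binwidth") {
    if (is.null(value_range) || length(value_range) != 2L ||
        diff(value_range) <= 0)
      stop("range_binwidth mode needs a valid value_range")
    if (is.null(bin_width)) bin_width <- diff(value_range) / 64
    nb <- ceiling(diff(value_range) / bin_width - 1e-9)
    if (nb < target_bins[1] || nb > target_bins[2])
      stop(sprintf("bin width gives %d bins, outside the %d-%d target window",
                   nb, target_bins[1], target_bins[2]))
  } else {
    if (is.null(bin_width)) bin_width <- 0.1
  }
  stopifnot(bin_width > 0)
  structure(list(mode = mode, bin_width = bin_width,
                 value_range = value_range, target_bins = target_bins),
            class = "discretization_policy")
}

#' Default discretization policies for the biomarker maps
#'
#' Physiologically motivated value ranges per quantitative map; each uses
#' bin width range/64 (64 bins, inside the 60-67 window). The signed MTI map
#' has no fixed physiological scale, so its range is set symmetrically from
#' the data (99th percentile of |MTI|) at preprocessing time.
#'
#' @return Named list of `discretization_policy` objects (`MTI` entry is the
#'   string "symmetric_p99", resolved per patient).
#' @export
biomarker_policies <- function() {
  rp <- function(lo, hi) discretization_policy("range_binwidth",
                                               value_range = c(lo, hi))
  list(OEF = rp(0, 1), CMRO2 = rp(0, 350),
       capiPO2 = rp(0, 100), mitoPO2 = rp(0, 100),
       CBV = rp(0, 0.2), uCBV = rp(0, 0.2), CBF = rp(0, 3),
       ADC = rp(0, 4e-3), MVD = rp(0, 5000), VSI = rp(0, 50),
       MTI = "symmetric_p99")
}

#' Normalize, resample and discretize a map for feature extraction
#'
#' Applies the policy's normalisation (z-score over `norm_mask` for
#' anatomical images, range clipping for biomarker maps), resamples image
#' (trilinearly) and mask (nearest-neighbour) to an isotropic 1 mm grid, and
#' discretizes to integer grey levels (1..n, 0 outside the mask).
#'
#' @param volume `volume_grid` or array.
#' @param mask logical array (tumor segmentation).
#' @param policy `discretization_policy`, or `"symmetric_p99"`.
#' @param norm_mask reference mask for z-scoring (default: the mask itself).
#' @param new_spacing target isotropic spacing, mm.
#' @return List: `levels` (integer array, 0 outside mask), `mask` (logical),
#'   `n_levels`, `spacing`, `policy`.
#' @export
preprocess_map <- function(volume, mask, policy, norm_mask = NULL,
                           new_spacing = 1) {
  vol <- as_volume(volume)
  stopifnot(identical(dim(vol$data), dim(mask)))
  if (!any(mask)) stop("empty mask")
  x <- vol$data
  if (identical(policy, "symmetric_p99")) {
    a <- stats::quantile(abs(x[mask]), 0.99, names = FALSE)
    if (a <= 0) a <- 1e-6
    policy <- discretization_policy("range_binwidth", value_range = c(-a, a))
  }
  stopifnot(inherits(policy, "discretization_policy"))
  if (policy$mode == "zscore_binwidth") {
    nm <- if (is.null(norm_mask)) mask else norm_mask
    mu <- mean(x[nm]); sdv <- stats::sd(x[nm])
    if (!is.finite(sdv) || sdv == 0) sdv <- 1
    x <- (x - mu) / sdv
  } else {
    x <- pmin(pmax(x, policy$value_range[1]), policy$value_range[2])
  }
  rx <- resample_volume(volume_grid(x, spacing = vol$spacing), new_spacing)
  rm <- resample_volume(volume_grid(mask * 1, spacing = vol$spacing),
                        new_spacing, method = "nearest")
  mk <- rm$data > 0.5
  if (!any(mk)) stop("mask empty after resampling")
  xv <- rx$data
  if (policy$mode == "zscore_binwidth") {
    lo <- min(xv[mk])
    lev <- floor((xv - lo) / policy$bin_width) + 1L
    n_levels <- max(lev[mk])
  } else {
    lo <- policy$value_range[1]
    n_levels <- as.integer(ceiling(diff(policy$value_range) / policy$bin_width - 1e-9))
    lev <- pmin(n_levels, floor((pmin(pmax(xv, lo), policy$value_range[2]) - lo) /
                                  policy$bin_width) + 1L)
  }
  levels <- array(0L, dim(xv))
  levels[mk] <- as.integer(lev[mk])
  list(levels = levels, mask = mk, n_levels = as.integer(n_levels),
       spacing = rx$spacing, policy = policy)
}

#' The fixed 107-feature manifest
#'
#' Stable, ordered names of the extracted feature set: 14 shape, 18
#' first-order, and 75 texture features (GLCM 24, GLRLM 16, GLSZM 16,
#' GLDM 14, NGTDM 5), following the standardized feature nomenclature.
#'
#' @return Character vector of length 107.
#' @export
feature_manifest <- function() {
  c(paste0("shape_", c("MeshVolume", "VoxelVolume", "SurfaceArea",
                       "SurfaceVolumeRatio", "Sphericity",
                       "Maximum3DDiameter", "Maximum2DDiameterSlice",
                       "Maximum2DDiameterColumn", "Maximum2DDiameterRow",
                       "MajorAxisLength", "MinorAxisLength",
                       "LeastAxisLength", "Elongation", "Flatness")),
    paste0("firstorder_", c("Energy", "TotalEnergy", "Entropy", "Minimum",
                            "Percentile10", "Percentile90", "Maximum", "Mean",
                            "Median", "InterquartileRange", "Range",
                            "MeanAbsoluteDeviation",
                            "RobustMeanAbsoluteDeviation", "RootMeanSquared",
                            "Skewness", "Kurtosis", "Variance", "Uniformity")),
    paste0("glcm_", c("Autocorrelation", "ClusterProminence", "ClusterShade",
                      "ClusterTendency", "Contrast", "Correlation",
                      "DifferenceAverage", "DifferenceEntropy",
                      "DifferenceVariance", "Id", "Idm", "Idmn", "Idn",
                      "Imc1", "Imc2", "InverseVariance", "JointAverage",
                      "JointEnergy", "JointEntropy", "MCC",
                      "MaximumProbability", "SumAverage", "SumEntropy",
                      "SumSquares")),
    paste0("glrlm_", c("ShortRunEmphasis", "LongRunEmphasis",
                       "GrayLevelNonUniformity",
                       "GrayLevelNonUniformityNormalized",
                       "RunLengthNonUniformity",
                       "RunLengthNonUniformityNormalized", "RunPercentage",
                       "GrayLevelVariance", "RunVariance", "RunEntropy",
                       "LowGrayLevelRunEmphasis", "HighGrayLevelRunEmphasis",
                       "ShortRunLowGrayLevelEmphasis",
                       "ShortRunHighGrayLevelEmphasis",
                       "LongRunLowGrayLevelEmphasis",
                       "LongRunHighGrayLevelEmphasis")),
    paste0("glszm_", c("SmallAreaEmphasis", "LargeAreaEmphasis",
                       "GrayLevelNonUniformity",
                       "GrayLevelNonUniformityNormalized",
                       "SizeZoneNonUniformity",
                       "SizeZoneNonUniformityNormalized", "ZonePercentage",
                       "GrayLevelVariance", "ZoneVariance", "ZoneEntropy",
                       "LowGrayLevelZoneEmphasis", "HighGrayLevelZoneEmphasis",
                       "SmallAreaLowGrayLevelEmphasis",
                       "SmallAreaHighGrayLevelEmphasis",
                       "LargeAreaLowGrayLevelEmphasis",
                       "LargeAreaHighGrayLevelEmphasis")),
    paste0("gldm_", c("SmallDependenceEmphasis", "LargeDependenceEmphasis",
                      "GrayLevelNonUniformity", "DependenceNonUniformity",
                      "DependenceNonUniformityNormalized",
                      "GrayLevelVariance", "DependenceVariance",
                      "DependenceEntropy", "LowGrayLevelEmphasis",
                      "HighGrayLevelEmphasis",
                      "SmallDependenceLowGrayLevelEmphasis",
                      "SmallDependenceHighGrayLevelEmphasis",
                      "LargeDependenceLowGrayLevelEmphasis",
                      "LargeDependenceHighGrayLevelEmphasis")),
    paste0("ngtdm_", c("Coarseness", "Contrast", "Busyness", "Complexity",
                       "Strength")))
}

# ---- shape features -------------------------------------------------------

.shape_features <- function(mask, spacing) {
  vv <- prod(spacing)
  idx <- which(mask, arr.ind = TRUE)
  nv <- nrow(idx)
  vol <- nv * vv
  dm <- dim(mask)
  # exposed voxel faces, spacing-aware
  face_area <- c(spacing[2] * spacing[3], spacing[1] * spacing[3],
                 spacing[1] * spacing[2])
  sa <- 0
  pad <- array(FALSE, dm + 2L)
  pad[2:(dm[1] + 1), 2:(dm[2] + 1), 2:(dm[3] + 1)] <- mask
  shifts <- list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                 c(0, 0, 1), c(0, 0, -1))
  for (s in shifts) {
    nb <- pad[2:(dm[1] + 1) + s[1], 2:(dm[2] + 1) + s[2], 2:(dm[3] + 1) + s[3]]
    ax <- which(s != 0)
    sa <- sa + sum(mask & !nb) * face_area[ax]
  }
  # boundary voxels (any exposed face) for diameters
  bnd <- mask
  for (s in shifts) {
    nb <- pad[2:(dm[1] + 1) + s[1], 2:(dm[2] + 1) + s[2], 2:(dm[3] + 1) + s[3]]
    bnd <- bnd & nb
  }
  surf <- which(mask & !bnd, arr.ind = TRUE)
  if (nrow(surf) == 0L) surf <- idx
  pts <- sweep(surf, 2, spacing, `*`)
  maxd <- function(p) if (nrow(p) < 2L) 0 else max(stats::dist(p))
  d3 <- maxd(pts)
  d_slice <- maxd(pts[, c(1, 2), drop = FALSE])   # axial plane
  d_col <- maxd(pts[, c(1, 3), drop = FALSE])
  d_row <- maxd(pts[, c(2, 3), drop = FALSE])
  # principal axes from all voxel centres
  phys <- sweep(idx, 2, spacing, `*`)
  ev <- if (nv > 3) {
    e <- eigen(stats::cov(phys), symmetric = TRUE, only.values = TRUE)$values
    pmax(e, 0)
  } else c(0, 0, 0)
  c(MeshVolume = vol, VoxelVolume = vol, SurfaceArea = sa,
    SurfaceVolumeRatio = sa / vol,
    Sphericity = (36 * pi * vol^2)^(1 / 3) / sa,
    Maximum3DDiameter = d3, Maximum2DDiameterSlice = d_slice,
    Maximum2DDiameterColumn = d_col, Maximum2DDiameterRow = d_row,
    MajorAxisLength = 4 * sqrt(ev[1]), MinorAxisLength = 4 * sqrt(ev[2]),
    LeastAxisLength = 4 * sqrt(ev[3]),
    Elongation = if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 0,
    Flatness = if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 0)
}

# ---- first-order features (on the discretized grey levels) ----------------

.firstorder_features <- function(x, vv) {
  n <- length(x)
  p <- tabulate(x) / n
  p <- p[p > 0]
  mu <- mean(x)
  q <- stats::quantile(x, c(0.10, 0.25, 0.50, 0.75, 0.90), names = FALSE, type = 7)
  rob <- x[x >= q[1] & x <= q[5]]
  c(Energy = sum(x^2), TotalEnergy = vv * sum(x^2),
    Entropy = -sum(p * log2(p)),
    Minimum = min(x), Percentile10 = q[1], Percentile90 = q[5],
    Maximum = max(x), Mean = mu, Median = q[3],
    InterquartileRange = q[4] - q[2], Range = max(x) - min(x),
    MeanAbsoluteDeviation = mean(abs(x - mu)),
    RobustMeanAbsoluteDeviation = if (length(rob)) mean(abs(rob - mean(rob))) else 0,
    RootMeanSquared = sqrt(mean(x^2)),
    Skewness = if (stats::sd(x) > 0) mean((x - mu)^3) / (mean((x - mu)^2))^1.5 else 0,
    Kurtosis = if (stats::sd(x) > 0) mean((x - mu)^4) / (mean((x - mu)^2))^2 else 0,
    Variance = mean((x - mu)^2), Uniformity = sum(p^2))
}

# ---- texture features from the C++ matrices -------------------------------

.glcm_features <- function(P) {
  ng <- nrow(P)
  tot <- sum(P)
  if (tot == 0) return(stats::setNames(rep(0, 24), NULL))
  p <- P / tot
  i <- row(p); j <- col(p)
  px <- rowSums(p); py <- colSums(p)
  mux <- sum((1:ng) * px); muy <- sum((1:ng) * py)
  sx <- sqrt(sum(((1:ng) - mux)^2 * px)); sy <- sqrt(sum(((1:ng) - muy)^2 * py))
  # diagonal and cross-diagonal distributions
  pxy_diff <- vapply(0:(ng - 1), function(k) sum(p[abs(i - j) == k]), 0)
  pxy_sum <- vapply(2:(2 * ng), function(k) sum(p[(i + j) == k]), 0)
  eps <- 2.2e-16
  da <- sum((0:(ng - 1)) * pxy_diff)
  sa <- sum((2:(2 * ng)) * pxy_sum)
  HX <- -sum(px[px > 0] * log2(px[px > 0]))
  HY <- -sum(py[py > 0] * log2(py[py > 0]))
  HXY <- -sum(p[p > 0] * log2(p[p > 0]))
  pq <- outer(px, py)
  HXY1 <- -sum(p[pq > 0] * log2(pq[pq > 0] + eps))
  HXY2 <- -sum(pq[pq > 0] * log2(pq[pq > 0]))
  imc1 <- if (max(HX, HY) > 0) (HXY - HXY1) / max(HX, HY) else 0
  imc2 <- sqrt(pmax(0, 1 - exp(-2 * (HXY2 - HXY))))
  # MCC: second largest eigenvalue of Q
  mcc <- tryCatch({
    ok <- px > 0
    Q <- matrix(0, ng, ng)
    denom <- outer(px, rep(1, ng))
    for (k in which(py > 0))
      Q <- Q + outer(p[, k], p[, k] / py[k]) / denom
    Q[!is.finite(Q)] <- 0
    e <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    if (length(e) >= 2 && e[2] > 0) sqrt(e[2]) else 0
  }, error = function(e) 0)
  c(Autocorrelation = sum(i * j * p),
    ClusterProminence = sum((i + j - mux - muy)^4 * p),
    ClusterShade = sum((i + j - mux - muy)^3 * p),
    ClusterTendency = sum((i + j - mux - muy)^2 * p),
    Contrast = sum((i - j)^2 * p),
    Correlation = if (sx > 0 && sy > 0) (sum(i * j * p) - mux * muy) / (sx * sy) else 0,
    DifferenceAverage = da,
    DifferenceEntropy = -sum(pxy_diff[pxy_diff > 0] * log2(pxy_diff[pxy_diff > 0])),
    DifferenceVariance = sum(((0:(ng - 1)) - da)^2 * pxy_diff),
    Id = sum(p / (1 + abs(i - j))),
    Idm = sum(p / (1 + (i - j)^2)),
    Idmn = sum(p / (1 + (i - j)^2 / ng^2)),
    Idn = sum(p / (1 + abs(i - j) / ng)),
    Imc1 = imc1, Imc2 = imc2,
    InverseVariance = sum(p[i != j] / (i - j)[i != j]^2),
    JointAverage = mux, JointEnergy = sum(p^2), JointEntropy = HXY,
    MCC = mcc, MaximumProbability = max(p),
    SumAverage = sa,
    SumEntropy = -sum(pxy_sum[pxy_sum > 0] * log2(pxy_sum[pxy_sum > 0])),
    SumSquares = sum((i - mux)^2 * p))
}

.glrlm_features <- function(P, np, ndirs = 13) {
  keep <- which(colSums(P) > 0)
  if (!length(keep)) keep <- 1L
  P <- P[, seq_len(max(keep)), drop = FALSE]
  nr <- sum(P)
  i <- row(P); j <- col(P)
  pg <- rowSums(P); pr <- colSums(P)
  p <- P / nr
  mug <- sum(row(p) * p); mur <- sum(col(p) * p)
  pp <- p[p > 0]
  c(ShortRunEmphasis = sum(P / col(P)^2) / nr,
    LongRunEmphasis = sum(P * col(P)^2) / nr,
    GrayLevelNonUniformity = sum(pg^2) / nr,
    GrayLevelNonUniformityNormalized = sum(pg^2) / nr^2,
    RunLengthNonUniformity = sum(pr^2) / nr,
    RunLengthNonUniformityNormalized = sum(pr^2) / nr^2,
    RunPercentage = nr / (np * ndirs),
    GrayLevelVariance = sum((row(p) - mug)^2 * p),
    RunVariance = sum((col(p) - mur)^2 * p),
    RunEntropy = -sum(pp * log2(pp)),
    LowGrayLevelRunEmphasis = sum(P / row(P)^2) / nr,
    HighGrayLevelRunEmphasis = sum(P * row(P)^2) / nr,
    ShortRunLowGrayLevelEmphasis = sum(P / (row(P)^2 * col(P)^2)) / nr,
    ShortRunHighGrayLevelEmphasis = sum(P * row(P)^2 / col(P)^2) / nr,
    LongRunLowGrayLevelEmphasis = sum(P * col(P)^2 / row(P)^2) / nr,
    LongRunHighGrayLevelEmphasis = sum(P * row(P)^2 * col(P)^2) / nr)
}

.glszm_features <- function(P, np) {
  keep <- which(colSums(P) > 0)
  if (!length(keep)) keep <- 1L
  P <- P[, seq_len(max(keep)), drop = FALSE]
  nz <- sum(P)
  pg <- rowSums(P); ps <- colSums(P)
  p <- P / nz
  mug <- sum(row(p) * p); mus <- sum(col(p) * p)
  pp <- p[p > 0]
  c(SmallAreaEmphasis = sum(P / col(P)^2) / nz,
    LargeAreaEmphasis = sum(P * col(P)^2) / nz,
    GrayLevelNonUniformity = sum(pg^2) / nz,
    GrayLevelNonUniformityNormalized = sum(pg^2) / nz^2,
    SizeZoneNonUniformity = sum(ps^2) / nz,
    SizeZoneNonUniformityNormalized = sum(ps^2) / nz^2,
    ZonePercentage = nz / np,
    GrayLevelVariance = sum((row(p) - mug)^2 * p),
    ZoneVariance = sum((col(p) - mus)^2 * p),
    ZoneEntropy = -sum(pp * log2(pp)),
    LowGrayLevelZoneEmphasis = sum(P / row(P)^2) / nz,
    HighGrayLevelZoneEmphasis = sum(P * row(P)^2) / nz,
    SmallAreaLowGrayLevelEmphasis = sum(P / (row(P)^2 * col(P)^2)) / nz,
    SmallAreaHighGrayLevelEmphasis = sum(P * row(P)^2 / col(P)^2) / nz,
    LargeAreaLowGrayLevelEmphasis = sum(P * col(P)^2 / row(P)^2) / nz,
    LargeAreaHighGrayLevelEmphasis = sum(P * row(P)^2 * col(P)^2) / nz)
}

.gldm_features <- function(P) {
  nz <- sum(P)
  # columns are dependence counts 0..26; use k+1 as the dependence size
  jsz <- matrix(rep(seq_len(ncol(P)), each = nrow(P)), nrow(P))
  pg <- rowSums(P); pd <- colSums(P)
  p <- P / nz
  mug <- sum(row(p) * p); mud <- sum(jsz * p)
  pp <- p[p > 0]
  c(SmallDependenceEmphasis = sum(P / jsz^2) / nz,
    LargeDependenceEmphasis = sum(P * jsz^2) / nz,
    GrayLevelNonUniformity = sum(pg^2) / nz,
    DependenceNonUniformity = sum(pd^2) / nz,
    DependenceNonUniformityNormalized = sum(pd^2) / nz^2,
    GrayLevelVariance = sum((row(p) - mug)^2 * p),
    DependenceVariance = sum((jsz - mud)^2 * p),
    DependenceEntropy = -sum(pp * log2(pp)),
    LowGrayLevelEmphasis = sum(P / row(P)^2) / nz,
    HighGrayLevelEmphasis = sum(P * row(P)^2) / nz,
    SmallDependenceLowGrayLevelEmphasis = sum(P / (row(P)^2 * jsz^2)) / nz,
    SmallDependenceHighGrayLevelEmphasis = sum(P * row(P)^2 / jsz^2) / nz,
    LargeDependenceLowGrayLevelEmphasis = sum(P * jsz^2 / row(P)^2) / nz,
    LargeDependenceHighGrayLevelEmphasis = sum(P * row(P)^2 * jsz^2) / nz)
}

.ngtdm_features <- function(M, np) {
  ngl <- nrow(M)
  n_i <- M[, 1]; s_i <- M[, 2]
  p_i <- n_i / np
  act <- which(p_i > 0)
  ngp <- length(act)
  iv <- seq_len(ngl)
  coarse <- sum(p_i * s_i)
  coarse <- if (coarse > 0) 1 / coarse else 1e6
  contrast <- 0; busy <- 0; complexity <- 0; strength <- 0
  if (ngp > 1) {
    grid <- expand.grid(a = act, b = act)
    pa <- p_i[grid$a]; pb <- p_i[grid$b]
    contrast <- sum(pa * pb * (grid$a - grid$b)^2) / (ngp * (ngp - 1)) *
      sum(s_i) / np
    denom <- sum(abs(grid$a * pa - grid$b * pb))
    busy <- if (denom > 0) sum(p_i * s_i) / denom else 0
    complexity <- sum(abs(grid$a - grid$b) *
                        (pa * s_i[grid$a] + pb * s_i[grid$b]) / (pa + pb)) / np
    ssum <- sum(s_i)
    strength <- if (ssum > 0) sum((pa + pb) * (grid$a - grid$b)^2) / ssum else 0
  }
  c(Coarseness = coarse, Contrast = contrast, Busyness = busy,
    Complexity = complexity, Strength = strength)
}

#' Extract the 107-feature radiomic vector from a preprocessed map
#'
#' Shape features come from the (resampled) mask geometry, first-order
#' features from the discretized grey-level distribution, and the 75 texture
#' features from grey-level co-occurrence, run-length, size-zone, dependence,
#' and neighbourhood grey-tone difference matrices accumulated over all 13
#' unique 3-D directions (merged aggregation). Deterministic for fixed input.
#'
#' @param prep output of [preprocess_map()], or a list with `levels`
#'   (integer array), `mask`, `n_levels`, `spacing`.
#' @return Named numeric vector of length 107 (a `RadiomicVector`).
#' @export
extract_features <- function(prep) {
  mask <- prep$mask
  if (sum(mask) < 8L) stop("mask smaller than 8 voxels: texture undefined")
  lev <- prep$levels
  ng <- max(prep$n_levels, max(lev))
  dims <- dim(lev)
  # crop to the mask bounding box to keep the matrix passes cheap
  rng <- lapply(1:3, function(a) range(which(apply(mask, a, any))))
  lev <- lev[rng[[1]][1]:rng[[1]][2], rng[[2]][1]:rng[[2]][2],
             rng[[3]][1]:rng[[3]][2], drop = FALSE]
  mk <- mask[rng[[1]][1]:rng[[1]][2], rng[[2]][1]:rng[[2]][2],
             rng[[3]][1]:rng[[3]][2], drop = FALSE]
  lev[!mk] <- 0L
  np <- sum(mk)
  x <- as.numeric(lev[mk])
  vv <- prod(prep$spacing)
  dimv <- as.integer(dim(lev))
  liv <- as.integer(lev)
  out <- c(.shape_features(mk, prep$spacing),
           .firstorder_features(x, vv),
           .glcm_features(.glcm_cpp(liv, dimv, ng)),
           .glrlm_features(.glrlm_cpp(liv, dimv, ng), np),
           .glszm_features(.glszm_cpp(liv, dimv, ng), np),
           .gldm_features(.gldm_cpp(liv, dimv, ng, 0L)),
           .ngtdm_features(.ngtdm_cpp(liv, dimv, ng), np))
  stats::setNames(as.numeric(out), feature_manifest())
}

#' Concatenate per-map radiomic vectors into a patient feature vector
#'
#' Maps are ordered canonically (see [category_maps()]) regardless of the
#' input order; names are prefixed with the map id. Four maps give 428
#' features; the combined physio-metabolic category gives 856.
#'
#' @param per_map named list of 107-feature vectors keyed by map name.
#' @param category data category (see [category_maps()]).
#' @return Named numeric vector of length `107 * n_maps`.
#' @export
assemble_vector <- function(per_map, category) {
  maps <- category_maps(category)
  missing <- setdiff(maps, names(per_map))
  if (length(missing))
    stop("missing feature vectors for map(s): ", paste(missing, collapse = ", "))
  out <- unlist(lapply(maps, function(m) {
    v <- per_map[[m]]
    stopifnot(length(v) == 107L)
    stats::setNames(as.numeric(v), paste0(m, "_", names(v)))
  }))
  out
}

#' Radiomic feature vector for one mapped patient
#'
#' Preprocesses each of the category's maps (z-score + fixed bin width for
#' the anatomical contrasts, physiological range clipping for biomarker
#' maps) over the tumor mask and extracts the 107 features per map.
#'
#' @param maps `patient_maps` from [map_patient()].
#' @param category data category.
#' @param policies named policy list (default [biomarker_policies()]).
#' @param new_spacing resampling target, mm.
#' @return Named numeric vector (428 or 856 features).
#' @export
patient_features <- function(maps, category = "oxymet",
                             policies = biomarker_policies(), new_spacing = 1) {
  anat <- c("ceT1w", "FLAIR")
  per_map <- list()
  for (m in category_maps(category)) {
    pol <- if (m %in% anat) discretization_policy("zscore_binwidth")
           else policies[[m]]
    prep <- preprocess_map(maps[[m]], maps$tumor_mask, pol,
                           norm_mask = if (m %in% anat) maps$brain_mask else NULL,
                           new_spacing = new_spacing)
    per_map[[m]] <- extract_features(prep)
  }
  assemble_vector(per_map, category)
}
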