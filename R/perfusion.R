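#' Split a hybrid gradient-echo/spin-echo DSC acquisition
#'
#' The hybrid single-shot acquisition records both echo kinds per dynamic
#' frame; this separates them into a gradient-echo and a spin-echo series with
#' identical timing, mirroring the site-B preprocessing.
#'
#' @param hybrid `dsc_hybrid` object.
#' @return List with `ge` and `se` `dynamic_series`.
#' @export
split_gese <- function(hybrid) {
  if (!inherits(hybrid, "dsc_hybrid")) stop("not a hybrid GESE series")
  if (is.null(hybrid$echo_tags) || !setequal(hybrid$echo_tags, c("GE", "SE")))
    stop("hybrid series echoes are not tagged GE/SE")
  list(ge = .dynamic_series(hybrid$ge_signal, hybrid$frame_interval,
                            unname(hybrid$echo_times["GE"]), "GE",
                            hybrid$baseline_window, hybrid$spacing),
       se = .dynamic_series(hybrid$se_signal, hybrid$frame_interval,
                            unname(hybrid$echo_times["SE"]), "SE",
                            hybrid$baseline_window, hybrid$spacing))
}

#' Recombine GE and SE series into a hybrid container (inverse of [split_gese()])
#' @param ge,se `dynamic_series` with identical timing.
#' @return `dsc_hybrid`.
#' @export
merge_gese <- function(ge, se) {
  stopifnot(inherits(ge, "dynamic_series"), inherits(se, "dynamic_series"),
            ge$frame_interval == se$frame_interval)
  structure(list(ge_signal = ge$signal, se_signal = se$signal,
                 echo_times = c(GE = ge$echo_time, SE = se$echo_time),
                 echo_tags = c("GE", "SE"), frame_interval = ge$frame_interval,
                 baseline_window = ge$baseline_window, spacing = ge$spacing),
            class = "dsc_hybrid")
}

#' Convert DSC signal to concentration-time curves
#'
#' Per-voxel `dR2(t) = -(1/TE) * log(S(t) / S_baseline)` with TE in seconds
#' and the baseline taken as the mean signal over the pre-bolus window.
#' Voxels with non-positive signal at any frame (where the log is undefined)
#' are flagged.
#'
#' @param series `dynamic_series`.
#' @param mask logical array of voxels to convert (default: baseline > 0).
#' @param baseline_window frame indices of the pre-bolus baseline.
#' @return List of class `dsc_curves`: `times` (s), `dr2` (voxels x frames
#'   matrix), `voxel_idx`, `flagged`, `te` (ms), `dim`.
#' @export
signal_to_delta_r2 <- function(series, mask = NULL,
                               baseline_window = series$baseline_window) {
  stopifnot(inherits(series, "dynamic_series"))
  dm <- dim(series$signal)
  nt <- dm[4]
  if (nt < 40L) warning("fewer than 40 dynamic frames")
  sig <- matrix(series$signal, ncol = nt)
  if (is.null(mask)) {
    base_all <- rowMeans(sig[, baseline_window, drop = FALSE])
    idx <- which(base_all > 0)
  } else idx <- which(mask)
  sig <- sig[idx, , drop = FALSE]
  base <- rowMeans(sig[, baseline_window, drop = FALSE])
  if (any(base <= 0)) stop("baseline mean signal must be positive inside mask")
  te_s <- series$echo_time / 1000
  flagged <- rowSums(sig <= 0) > 0L
  sig[sig <= 0] <- NA_real_
  dr2 <- -log(sig / base) / te_s
  dr2[is.na(dr2)] <- 0
  list(times = (seq_len(nt) - 1) * series$frame_interval, dr2 = dr2,
       voxel_idx = idx, flagged = flagged, te = series$echo_time,
       dim = dm[1:3], spacing = series$spacing)
}

# profile residual sum of squares of the log-linearised gamma-variate at
# fixed arrival time: log y = c0 + alpha*log(t-t0) - (t-t0)/b
.gamma_profile_fit <- function(tw, ly, t0) {
  u <- tw - t0
  X <- cbind(1, log(u), -u)
  f <- stats::.lm.fit(X, ly)
  list(rss = sum(f$residuals^2), coef = f$coefficients)
}

# Adaptive pre-conditioning for noisy curves: noise is estimated from
# frame-to-frame differences; when the peak SNR is low the curve is smoothed
# with a unit-mass [1 2 1]/4 kernel (repeatedly for very low SNR). The
# kernel preserves the curve's integral, so area-based blood-volume
# estimates stay essentially unbiased, and noise-free curves pass through
# untouched, keeping the fit exact there.
.precondition_curve <- function(values, snr_target = 10) {
  sigma <- stats::mad(diff(values)) / sqrt(2)
  if (!is.finite(sigma) || sigma == 0) return(values)
  n <- length(values)
  for (pass in 1:3) {
    snr <- max(values) / sigma
    if (snr >= snr_target) break
    values <- (c(values[1], values[-n]) + 2 * values +
                 c(values[-1], values[n])) / 4
    sigma <- sigma * sqrt(3 / 8)   # variance reduction of the kernel
  }
  values
}

#' Fit the first-pass bolus with a gamma-variate
#'
#' Fits `K * (t - t0)^alpha * exp(-(t - t0)/b)` to one concentration curve
#' over the first-pass window, which runs from the 5%-of-peak onset to the
#' first post-peak crossing of 20% of peak (recirculation exclusion). The fit
#' is profile least squares in the log domain: for fixed arrival `t0` the
#' model is linear in `(log K, alpha, 1/b)`, and `t0` is found by a coarse
#' grid followed by Brent refinement. Exact on noise-free gamma-variates.
#'
#' @param times frame times, s.
#' @param values concentration values (dR2, 1/s).
#' @param min_peak minimum peak value for a detectable bolus.
#' @return List of class `gamma_fit`: `K`, `t0`, `alpha`, `b`, `rmse`,
#'   `valid`, `window` (frame indices used), `area` (closed-form area under
#'   the fitted curve), `peak` (fitted peak value).
#' @export
fit_first_pass <- function(times, values, min_peak = 1e-6) {
  invalid <- list(K = NA_real_, t0 = NA_real_, alpha = NA_real_, b = NA_real_,
                  rmse = NA_real_, valid = FALSE, window = integer(0),
                  area = NA_real_, peak = NA_real_)
  class(invalid) <- "gamma_fit"
  values <- .precondition_curve(values)
  n <- length(values)
  pk <- which.max(values)
  peak <- values[pk]
  if (!is.finite(peak) || peak <= min_peak) return(invalid)
  # onset: last frame at/below 5% of peak before the peak
  pre <- which(values[seq_len(pk)] <= 0.05 * peak)
  w1 <- if (length(pre)) max(pre) + 1L else 1L
  # recirculation exclusion: first post-peak crossing of 20% of peak
  post <- which(values[pk:n] <= 0.20 * peak)
  w2 <- if (length(post)) pk + min(post) - 1L else n
  win <- w1:w2
  win <- win[values[win] > 0]
  if (length(win) < 4L) return(invalid)
  tw <- times[win]; ly <- log(values[win])
  dt <- if (n > 1) times[2] - times[1] else 1
  span <- max(tw) - min(tw)
  lo <- min(tw) - max(span, 3 * dt)
  hi <- min(tw) - 1e-4 * dt
  grid <- seq(lo, hi, length.out = 25L)
  rss <- vapply(grid, function(g) .gamma_profile_fit(tw, ly, g)$rss, 0)
  i <- which.min(rss)
  bracket <- c(grid[max(1L, i - 1L)], grid[min(length(grid), i + 1L)])
  opt <- stats::optimize(function(g) .gamma_profile_fit(tw, ly, g)$rss,
                         interval = bracket, tol = 1e-10)
  t0 <- opt$minimum
  cf <- .gamma_profile_fit(tw, ly, t0)$coef
  K <- exp(cf[1]); alpha <- cf[2]; b <- 1 / cf[3]
  if (!is.finite(K) || !is.finite(alpha) || !is.finite(b) ||
      alpha <= 0 || b <= 0) return(invalid)
  fitted <- gamma_variate(tw, K, t0, alpha, b)
  out <- list(K = K, t0 = t0, alpha = alpha, b = b,
              rmse = sqrt(mean((fitted - values[win])^2)),
              valid = TRUE, window = win,
              area = gamma_variate_area(K, alpha, b),
              peak = gamma_variate_peak(K, alpha, b))
  class(out) <- "gamma_fit"
  out
}

# Fit every row of a dr2 matrix; returns a data.frame-like list of parameter
# vectors. The workhorse behind the per-voxel maps.
fit_first_pass_matrix <- function(times, dr2, min_peak = 1e-6) {
  nv <- nrow(dr2)
  K <- t0 <- alpha <- b <- area <- peak <- rmse <- rep(NA_real_, nv)
  valid <- rep(FALSE, nv)
  for (v in seq_len(nv)) {
    f <- fit_first_pass(times, dr2[v, ], min_peak = min_peak)
    if (f$valid) {
      K[v] <- f$K; t0[v] <- f$t0; alpha[v] <- f$alpha; b[v] <- f$b
      area[v] <- f$area; peak[v] <- f$peak; rmse[v] <- f$rmse; valid[v] <- TRUE
    }
  }
  list(K = K, t0 = t0, alpha = alpha, b = b, area = area, peak = peak,
       rmse = rmse, valid = valid)
}

#' Automatic arterial input function selection
#'
#' Scores candidate voxels by early bolus arrival (low fitted `t0`), high
#' fitted peak, and narrow width (low `alpha * b`), combines the three
#' criteria by rank sum, and averages the fitted curves of the top `top_n`
#' voxels. Candidates are prefiltered to voxels whose raw peak reaches
#' `peak_frac` of the global maximum (arterial voxels dwarf tissue).
#'
#' @param curves `dsc_curves` from [signal_to_delta_r2()].
#' @param brain_mask logical array; at least 100 voxels must be available.
#' @param top_n number of contributing voxels to average.
#' @param peak_frac candidate prefilter threshold relative to the global peak.
#' @param min_peak minimum detectable peak for a candidate fit.
#' @return List of class `aif_result`: `times`, `values` (averaged fitted
#'   curve), `area` (mean closed-form area), `voxel_idx`, `scores`, `fits`.
#' @export
select_aif <- function(curves, brain_mask, top_n = 10L, peak_frac = 0.5,
                       min_peak = 1e-6) {
  inb <- brain_mask[curves$voxel_idx]
  if (sum(inb) < 100L) stop("need at least 100 candidate voxels inside the brain mask")
  rows <- which(inb & !curves$flagged)
  peaks <- apply(curves$dr2[rows, , drop = FALSE], 1, max)
  cand <- rows[peaks >= peak_frac * max(peaks)]
  # cap for speed; keep the tallest
  if (length(cand) > 400L)
    cand <- cand[order(peaks[match(cand, rows)], decreasing = TRUE)[1:400]]
  fits <- fit_first_pass_matrix(curves$times, curves$dr2[cand, , drop = FALSE],
                                min_peak = min_peak)
  ok <- which(fits$valid)
  if (length(ok) < 5L) stop("fewer than 5 acceptable AIF voxels")
  score <- rank(fits$t0[ok]) + rank(-fits$peak[ok]) +
    rank(fits$alpha[ok] * fits$b[ok])
  pick <- ok[order(score, rank(fits$t0[ok]))[seq_len(min(top_n, length(ok)))]]
  vals <- sapply(pick, function(v)
    gamma_variate(curves$times, fits$K[v], fits$t0[v], fits$alpha[v], fits$b[v]))
  out <- list(times = curves$times, values = rowMeans(vals),
              area = mean(fits$area[pick]),
              voxel_idx = curves$voxel_idx[cand[pick]],
              scores = score, fits = fits, picked = pick)
  class(out) <- "aif_result"
  out
}

#' Cerebral blood volume from a tissue fit and an AIF
#'
#' `CBV = area(fitted tissue first pass) / area(AIF first pass)`, areas in
#' closed form under the fitted gamma-variates, times a proportionality
#' constant (default 1, i.e. relative CBV expressed as a fraction).
#'
#' @param curve_fit `gamma_fit` for the tissue voxel.
#' @param aif `aif_result`.
#' @param scale proportionality constant.
#' @return Scalar CBV (NA if the fit is invalid).
#' @export
compute_cbv <- function(curve_fit, aif, scale = 1) {
  if (!is.finite(aif$area) || aif$area <= 0) stop("AIF has zero first-pass area")
  if (!isTRUE(curve_fit$valid)) return(NA_real_)
  scale * curve_fit$area / aif$area
}

# vectorised CBV over a fitted voxel set
compute_cbv_values <- function(fits, aif, scale = 1) {
  if (!is.finite(aif$area) || aif$area <= 0) stop("AIF has zero first-pass area")
  ifelse(fits$valid, scale * fits$area / aif$area, NA_real_)
}

#' Microvascular blood volume from spin-echo DSC
#'
#' Identical contract to [compute_cbv()], applied to spin-echo curves with an
#' AIF selected independently from the spin-echo data.
#'
#' @inheritParams compute_cbv
#' @export
compute_micro_cbv <- function(curve_fit, aif, scale = 1)
  compute_cbv(curve_fit, aif, scale = scale)

#' Cerebral blood flow by block-circulant SVD deconvolution
#'
#' Deconvolves the tissue concentration curve by the AIF using a
#' zero-padded block-circulant system, truncating singular values below
#' `lambda` times the largest. The maximum of the deconvolved residue
#' function is the (relative) CBF: a tissue curve equal to the AIF delayed by
#' a few frames deconvolves to a unit spike.
#'
#' @param tissue concentration values at the AIF's time base.
#' @param aif `aif_result` (or numeric AIF values).
#' @param lambda singular-value truncation threshold, fraction of the maximum.
#' @return List: `cbf` (max of residue), `residue`, `valid`.
#' @export
compute_cbf <- function(tissue, aif, lambda = 0.2) {
  a <- if (inherits(aif, "aif_result")) aif$values else aif
  n <- length(a)
  stopifnot(length(tissue) == n)
  if (all(tissue == 0)) return(list(cbf = 0, residue = numeric(2 * n), valid = TRUE))
  m <- 2L * n
  ap <- c(a, numeric(n)); cp <- c(tissue, numeric(n))
  D <- matrix(0, m, m)
  for (j in seq_len(m)) D[, j] <- ap[((seq_len(m) - j) %% m) + 1L]
  sv <- svd(D)
  if (max(sv$d) == 0) stop("singular AIF matrix")
  keep <- sv$d > lambda * max(sv$d) & sv$d > 0
  if (!any(keep)) return(list(cbf = 0, residue = numeric(m), valid = FALSE))
  dinv <- ifelse(keep, 1 / sv$d, 0)
  r <- sv$v %*% (dinv * crossprod(sv$u, cp))
  list(cbf = max(r), residue = as.vector(r), valid = TRUE)
}

# Precompute the truncated-SVD deconvolution operator for one AIF so that a
# whole voxel set can be deconvolved with a single matrix product.
cbf_operator <- function(aif, lambda = 0.2) {
  a <- if (inherits(aif, "aif_result")) aif$values else aif
  n <- length(a); m <- 2L * n
  ap <- c(a, numeric(n))
  D <- matrix(0, m, m)
  for (j in seq_len(m)) D[, j] <- ap[((seq_len(m) - j) %% m) + 1L]
  sv <- svd(D)
  keep <- sv$d > lambda * max(sv$d) & sv$d > 0
  dinv <- ifelse(keep, 1 / sv$d, 0)
  sv$v %*% (dinv * t(sv$u))
}

# max of residue per row of a voxels-x-frames concentration matrix
compute_cbf_values <- function(dr2, aif, lambda = 0.2, op = NULL) {
  if (is.null(op)) op <- cbf_operator(aif, lambda)
  n <- ncol(dr2)
  cp <- cbind(dr2, matrix(0, nrow(dr2), n))
  res <- cp %*% t(op)
  apply(res, 1, max)
}
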