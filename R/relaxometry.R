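#' Fit a transverse relaxation-rate map from a multi-echo series
#'
#' Per-voxel log-linear least squares: the mono-exponential decay
#' `S(TE) = S0 * exp(-TE * R)` is linear in `log S`, so the rate is the
#' negated slope of `log S` against TE. The log-linear fit is exact on
#' noise-free data and convex; voxels with any non-positive echo signal are
#' flagged invalid and set to 0.
#'
#' @param series `echo_series` (>= 3 echoes).
#' @param mask logical array of voxels to fit (default: all).
#' @return `volume_grid` of rates in 1/s with a validity mask; `meta$kind`
#'   records the echo kind.
#' @export
fit_rate_map <- function(series, mask = NULL) {
  stopifnot(inherits(series, "echo_series"))
  ne <- length(series$echo_times)
  if (ne < 3L) stop("at least 3 echoes are required")
  dm <- dim(series$volumes[[1]])
  if (is.null(mask)) mask <- array(TRUE, dm)
  idx <- which(mask)
  S <- matrix(vapply(series$volumes, function(v) v[idx],
                     numeric(length(idx))), nrow = length(idx))
  ok <- rowSums(S <= 0) == 0L
  te_s <- series$echo_times / 1000
  rate <- numeric(length(idx))
  if (any(ok)) {
    L <- log(S[ok, , drop = FALSE])
    tc <- te_s - mean(te_s)
    # slope of log S on TE, per voxel, vectorised
    rate[ok] <- -as.vector(L %*% tc) / sum(tc^2)
  }
  out <- array(0, dm); out[idx] <- rate
  valid <- array(FALSE, dm); valid[idx] <- ok
  volume_grid(out, spacing = series$spacing, valid = valid,
              meta = list(kind = series$kind))
}

#' Apparent diffusion coefficient from a two-point acquisition
#'
#' `ADC = -(1/b) * log(S / S0)` with b-values {0, 1000} s/mm^2. Degenerate
#' voxels (`S <= 0` or `S > S0`, where the log model has no physical solution)
#' are clamped to 0 and flagged invalid rather than set to NA, so downstream
#' radiomic masks stay usable.
#'
#' @param pair list with `s0`, `s1000`, `b_values` (see [simulate_dwi()]).
#' @param mask logical array (default: voxels with `s0 > 0`).
#' @return `volume_grid` of ADC in mm^2/s with a validity mask.
#' @export
compute_adc <- function(pair, mask = NULL) {
  if (is.null(pair$s1000)) stop("b=1000 volume is missing")
  if (!identical(sort(pair$b_values), c(0, 1000)))
    stop("b values must be exactly {0, 1000} s/mm^2")
  s0 <- vol_data(pair$s0); s1 <- vol_data(pair$s1000)
  stopifnot(identical(dim(s0), dim(s1)))
  if (is.null(mask)) mask <- s0 > 0
  idx <- which(mask & s0 > 0)
  ratio <- s1[idx] / s0[idx]
  ok <- ratio > 0 & ratio <= 1
  adc <- numeric(length(idx))
  adc[ok] <- -log(ratio[ok]) / 1000
  out <- array(0, dim(s0)); out[idx] <- adc
  valid <- array(FALSE, dim(s0)); valid[idx] <- ok
  sp <- if (!is.null(pair$spacing)) pair$spacing else c(1, 1, 1)
  volume_grid(out, spacing = sp, valid = valid)
}
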