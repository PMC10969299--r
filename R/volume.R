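#' Volume grid: a 3-D scalar field with voxel spacing
#'
#' Lightweight carrier for all biomarker maps and mask volumes. Holds a 3-D
#' numeric array, the isotropic-or-not voxel spacing in mm, and an optional
#' validity mask of voxels whose value could not be computed (flagged rather
#' than set to NA so downstream radiomic masks stay usable).
#'
#' @param data 3-D numeric array.
#' @param spacing numeric length-3, voxel size in mm per axis.
#' @param valid optional logical array of the same shape; TRUE = trustworthy.
#' @param meta named list of free-form metadata (e.g. equation parse ids).
#' @return An object of class `volume_grid`.
#' @export
volume_grid <- function(data, spacing = c(1, 1, 1), valid = NULL, meta = list()) {
  stopifnot(is.array(data), length(dim(data)) == 3L, length(spacing) == 3L,
            all(spacing > 0))
  if (!is.null(valid)) stopifnot(identical(dim(valid), dim(data)))
  structure(list(data = data, spacing = as.numeric(spacing),
                 valid = valid, meta = meta),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume_grid %dx%dx%d, spacing %s mm>\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 3), collapse = "x")))
  invisible(x)
}

#' @export
dim.volume_grid <- function(x) dim(x$data)

as_volume <- function(x, like = NULL) {
  if (inherits(x, "volume_grid")) return(x)
  sp <- if (!is.null(like)) like$spacing else c(1, 1, 1)
  volume_grid(x, spacing = sp)
}

vol_data <- function(x) if (inherits(x, "volume_grid")) x$data else x

#' Trilinear / nearest-neighbour resampling onto an isotropic grid
#'
#' Resamples a volume onto a new voxel spacing (default 1 mm isotropic, the
#' grid used for radiomic extraction). Intensities are interpolated
#' trilinearly; masks must use `method = "nearest"` so labels stay binary.
#'
#' @param vol `volume_grid` (or array, assumed at `spacing_in`).
#' @param new_spacing target spacing in mm (scalar or length 3).
#' @param method "trilinear" or "nearest".
#' @param spacing_in spacing of `vol` when it is a bare array.
#' @return `volume_grid` at the new spacing.
#' @export
resample_volume <- function(vol, new_spacing = 1, method = c("trilinear", "nearest"),
                            spacing_in = NULL) {
  method <- match.arg(method)
  if (!inherits(vol, "volume_grid")) {
    vol <- volume_grid(vol, spacing = if (is.null(spacing_in)) c(1, 1, 1) else spacing_in)
  }
  if (length(new_spacing) == 1L) new_spacing <- rep(new_spacing, 3L)
  old <- vol$spacing; dm <- dim(vol$data)
  if (isTRUE(all.equal(old, new_spacing))) return(vol)
  # physical extent is preserved; voxel centres at (i - 0.5) * spacing
  ndim <- pmax(1L, as.integer(round(dm * old / new_spacing)))
  centers <- lapply(1:3, function(a) ((seq_len(ndim[a]) - 0.5) * new_spacing[a]) / old[a] + 0.5)
  if (method == "nearest") {
    idx <- lapply(1:3, function(a) pmin(dm[a], pmax(1L, as.integer(round(centers[[a]])))))
    out <- vol$data[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  } else {
    g <- lapply(1:3, function(a) {
      x <- centers[[a]]
      lo <- pmin(dm[a], pmax(1L, floor(x)))
      hi <- pmin(dm[a], lo + 1L)
      w <- pmin(1, pmax(0, x - lo))
      list(lo = as.integer(lo), hi = as.integer(hi), w = w)
    })
    out <- array(0, ndim)
    dat <- vol$data
    for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
      ix <- if (cx) g[[1]]$hi else g[[1]]$lo
      iy <- if (cy) g[[2]]$hi else g[[2]]$lo
      iz <- if (cz) g[[3]]$hi else g[[3]]$lo
      wx <- if (cx) g[[1]]$w else 1 - g[[1]]$w
      wy <- if (cy) g[[2]]$w else 1 - g[[2]]$w
      wz <- if (cz) g[[3]]$w else 1 - g[[3]]$w
      w3 <- outer(outer(wx, wy), wz)
      out <- out + dat[ix, iy, iz, drop = FALSE] * w3
    }
  }
  volume_grid(out, spacing = new_spacing, meta = vol$meta)
}

# Separable box-kernel smoothing used to make phantom tissue fields spatially
# coherent. Repeating a width-3 box approximates a Gaussian.
smooth3d <- function(a, passes = 2L) {
  d <- dim(a)
  for (p in seq_len(passes)) {
    for (ax in 1:3) {
      if (d[ax] < 3L) next
      lo <- a; hi <- a
      idx_lo <- c(1L, seq_len(d[ax] - 1L))
      idx_hi <- c(seq_len(d[ax] - 1L) + 1L, d[ax])
      if (ax == 1L) { lo <- a[idx_lo, , , drop = FALSE]; hi <- a[idx_hi, , , drop = FALSE] }
      if (ax == 2L) { lo <- a[, idx_lo, , drop = FALSE]; hi <- a[, idx_hi, , drop = FALSE] }
      if (ax == 3L) { lo <- a[, , idx_lo, drop = FALSE]; hi <- a[, , idx_hi, drop = FALSE] }
      a <- (lo + a + hi) / 3
    }
  }
  a
}

# Ellipsoid / sphere mask on a voxel grid (centre and radii in voxel units).
ellipsoid_mask <- function(grid_shape, center, radii) {
  if (length(radii) == 1L) radii <- rep(radii, 3L)
  ax <- lapply(1:3, function(a) (seq_len(grid_shape[a]) - center[a]) / radii[a])
  d2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, `+`), ax[[3]]^2, `+`)
  d2 <= 1
}
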