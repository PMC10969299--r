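#' Write a volume to NIfTI-1 with a JSON sidecar
#'
#' @param vol `volume_grid` or array.
#' @param path output path (`.nii` / `.nii.gz`).
#' @param sidecar optional named list written to `<path>.json` (acquisition
#'   metadata such as echo times and frame timing).
#' @return `path`, invisibly.
#' @export
write_nifti_map <- function(vol, path, sidecar = NULL) {
  v <- as_volume(vol)
  img <- RNifti::asNifti(v$data, pixdim = v$spacing)
  RNifti::writeNifti(img, path)
  if (!is.null(sidecar))
    jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  invisible(path)
}

#' Read a NIfTI volume into a `volume_grid`
#' @param path NIfTI file path.
#' @return `volume_grid`.
#' @export
read_nifti_map <- function(path) {
  img <- RNifti::readNifti(path)
  sp <- attr(img, "pixdim")[1:3]
  volume_grid(array(as.numeric(img), dim(img)[1:3]),
              spacing = ifelse(is.finite(sp) & sp > 0, sp, 1))
}

#' Write a 4-D dynamic series to NIfTI with timing sidecar
#' @param series `dynamic_series`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_nifti_series <- function(series, path) {
  img <- RNifti::asNifti(series$signal,
                         pixdim = c(series$spacing, series$frame_interval))
  RNifti::writeNifti(img, path)
  jsonlite::write_json(list(echo_time_ms = series$echo_time,
                            frame_interval_s = series$frame_interval,
                            echo_kind = series$echo_kind,
                            baseline_frames = range(series$baseline_window)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a cohort manifest (patient ids, labels, file paths) as JSON
#' @param cohort from [simulate_cohort()].
#' @param dir output directory.
#' @param paths optional named list of per-patient file path lists.
#' @return Manifest path, invisibly.
#' @export
write_cohort_manifest <- function(cohort, dir, paths = NULL) {
  manifest <- list(
    n = length(cohort$labels), seed = cohort$seed, protocol = cohort$protocol,
    patients = lapply(seq_along(cohort$labels), function(i)
      c(list(id = sprintf("P%03d", i), label = cohort$labels[i],
             seed = cohort$specs[[i]]$seed),
        if (!is.null(paths)) paths[[i]])))
  out <- file.path(dir, "cohort_manifest.json")
  jsonlite::write_json(manifest, out, auto_unbox = TRUE, digits = NA)
  invisible(out)
}

#' Write a feature matrix with labels as CSV
#' @param features patients x features matrix with named columns.
#' @param labels class labels.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, labels, path) {
  df <- data.frame(label = labels, features, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#' @param path CSV path.
#' @return List: `features` matrix, `labels`.
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  list(features = as.matrix(df[, -1, drop = FALSE]), labels = df$label)
}
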