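#' 4D BOLD time series container
#'
#' Thin S3 container for a 4D BOLD acquisition: the voxel data, repetition
#' time, voxel geometry, brain mask, the acquisition time of the first
#' retained volume (`time_offset`, updated by preprocessing steps that drop
#' or merge volumes) and free-text provenance.
#'
#' @param data 4D numeric array (x, y, z, t).
#' @param tr Repetition time, seconds.
#' @param voxel_size Voxel edge lengths, mm.
#' @param brain_mask 3D logical array; defaults to all-TRUE.
#' @param time_offset Acquisition time of volume 1, seconds.
#' @param provenance Named list (seeds, model parameters, processing log).
#' @return An object of class `bold_series`.
#' @export
bold_series <- function(data, tr, voxel_size = c(0.391, 0.391, 1),
                        brain_mask = NULL, time_offset = 0,
                        provenance = list()) {
  stopifnot(length(dim(data)) == 4, tr > 0, dim(data)[4] >= 1)
  if (is.null(brain_mask)) brain_mask <- array(TRUE, dim = dim(data)[1:3])
  stopifnot(all(dim(brain_mask) == dim(data)[1:3]))
  if (!all(is.finite(data[rep(as.logical(brain_mask), dim(data)[4])])))
    stop("non-finite values inside the brain mask")
  structure(list(data = data, tr = tr, voxel_size = voxel_size,
                 brain_mask = brain_mask, time_offset = time_offset,
                 provenance = provenance),
            class = "bold_series")
}

#' @export
print.bold_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("BOLD series: %dx%dx%d voxels, %d volumes, TR %g s (t0 %g s)\n",
              d[1], d[2], d[3], d[4], x$tr, x$time_offset))
  invisible(x)
}

#' Number of volumes
#' @param series A `bold_series`.
#' @export
n_volumes <- function(series) dim(series$data)[4]

#' Acquisition times of the retained volumes
#' @param series A `bold_series`.
#' @return Numeric vector, seconds (start-of-volume convention).
#' @export
volume_times <- function(series) {
  series$time_offset + (seq_len(n_volumes(series)) - 1) * series$tr
}

#' Matrix view of a BOLD series
#'
#' Returns the time courses of the given voxels as a t x n_voxels matrix.
#' @param series A `bold_series`.
#' @param voxels Linear voxel indices (default: all in-mask voxels).
#' @export
series_matrix <- function(series, voxels = which(series$brain_mask)) {
  d <- dim(series$data)
  m <- matrix(series$data, prod(d[1:3]), d[4])[voxels, , drop = FALSE]
  t(m)
}

series_set_matrix <- function(series, mat, voxels = which(series$brain_mask)) {
  d <- dim(series$data)
  flat <- matrix(series$data, prod(d[1:3]), d[4])
  flat[voxels, ] <- t(mat)
  series$data <- array(flat, dim = d)
  series
}

# Append a processing-log entry to provenance.
log_step <- function(series, step, ...) {
  entry <- c(list(step = step), list(...))
  series$provenance$log <- c(series$provenance$log, list(entry))
  series
}

#' Write / read a BOLD series as NIfTI-1
#'
#' The TR is stored in the fourth pixdim slot; provenance is written as a
#' JSON sidecar next to the image when `sidecar = TRUE`.
#'
#' @param series A `bold_series`.
#' @param path Output path (.nii or .nii.gz).
#' @param sidecar Write provenance JSON alongside?
#' @export
write_bold_nifti <- function(series, path, sidecar = TRUE) {
  img <- RNifti::asNifti(series$data,
                         reference = list(pixdim = c(1, series$voxel_size, series$tr, 0, 0, 0)))
  RNifti::writeNifti(img, path)
  if (sidecar) {
    side <- sub("\\.nii(\\.gz)?$", ".json", path)
    jsonlite::write_json(
      c(list(tr = series$tr, voxel_size = series$voxel_size,
             time_offset = series$time_offset), series$provenance),
      side, auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  invisible(path)
}

#' Write a 3D volume (map, mask, correlation volume) as NIfTI-1
#' @param vol 3D numeric/logical array; NAs written as 0.
#' @param path Output path (.nii or .nii.gz).
#' @param voxel_size Voxel edge lengths, mm.
#' @export
write_volume_nifti <- function(vol, path, voxel_size = c(0.391, 0.391, 1)) {
  v <- vol + 0
  v[is.na(v)] <- 0
  img <- RNifti::asNifti(v, reference = list(pixdim = c(1, voxel_size, 1,
                                                        0, 0, 0)))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_bold_nifti
#' @param brain_mask Optional 3D logical mask to attach on read.
#' @export
read_bold_nifti <- function(path, brain_mask = NULL) {
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  bold_series(array(as.numeric(img), dim = dim(img)),
              tr = if (length(pd) >= 4 && pd[4] > 0) pd[4] else 1,
              voxel_size = pd[1:3], brain_mask = brain_mask,
              provenance = list(source = path))
}
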