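#' Preprocessing configuration
#'
#' Bundles the temporal/spatial preprocessing parameters. The stimulus-run
#' defaults mirror the standard chain: pairwise volume averaging (TR_eff
#' 4 s), discard 2 volumes, ascending-interleaved slice-time correction,
#' rigid motion correction, 2-pixel FWHM in-plane Gaussian smoothing and
#' high-pass filtering (12 s FWHM kernel metadata, operative FFT cutoff at
#' 9 cycles per run). Resting-state runs instead use a 0.1 Hz FFT low-pass.
#'
#' @param n_discard_volumes Leading volumes to drop (MR saturation).
#' @param pairwise_average Average consecutive volume pairs first?
#' @param slice_order `"ascending_interleaved"` or `"none"`.
#' @param smoothing_fwhm In-plane Gaussian FWHM, pixels (0 disables).
#' @param highpass_fwhm Temporal-smoothing kernel FWHM metadata, seconds.
#' @param highpass_cycles FFT high-pass cutoff, cycles per run (0 disables).
#' @param lowpass_hz FFT low-pass cutoff, Hz (`NULL` disables).
#' @param motion_correction `"none"` or `"rigid"`.
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(n_discard_volumes = 2, pairwise_average = TRUE,
                              slice_order = c("none", "ascending_interleaved"),
                              smoothing_fwhm = 2, highpass_fwhm = 12,
                              highpass_cycles = 9, lowpass_hz = NULL,
                              motion_correction = c("none", "rigid")) {
  slice_order <- match.arg(slice_order)
  motion_correction <- match.arg(motion_correction)
  stopifnot(n_discard_volumes >= 0, smoothing_fwhm >= 0)
  structure(list(n_discard_volumes = n_discard_volumes,
                 pairwise_average = pairwise_average,
                 slice_order = slice_order,
                 smoothing_fwhm = smoothing_fwhm,
                 highpass_fwhm = highpass_fwhm,
                 highpass_cycles = highpass_cycles,
                 lowpass_hz = lowpass_hz,
                 motion_correction = motion_correction),
            class = "preprocess_config")
}

#' Read a preprocessing configuration from YAML
#' @param path YAML file with `preprocess_config` fields.
#' @export
read_preprocess_config <- function(path) {
  do.call(preprocess_config, yaml::read_yaml(path))
}

#' Average consecutive volume pairs
#'
#' Reduces noise by replacing volumes (2i-1, 2i) with their arithmetic
#' mean, doubling the repetition time (e.g. TR 2 s -> TR_eff 4 s). An odd
#' trailing volume is dropped with a warning.
#'
#' @param series A `bold_series` with at least 2 volumes.
#' @return A `bold_series` with `floor(t/2)` volumes and doubled `tr`.
#' @export
pairwise_average <- function(series) {
  nt <- n_volumes(series)
  if (nt < 2) stop("pairwise averaging needs at least 2 volumes")
  if (nt %% 2 == 1) {
    warning("odd number of volumes; dropping the trailing volume")
    series$data <- series$data[, , , -nt, drop = FALSE]
    nt <- nt - 1
  }
  d <- dim(series$data)
  flat <- matrix(series$data, prod(d[1:3]), nt)
  avg <- (flat[, seq(1, nt, 2), drop = FALSE] +
            flat[, seq(2, nt, 2), drop = FALSE]) / 2
  series$data <- array(avg, dim = c(d[1:3], nt / 2))
  # averaged volume sits midway between its two constituents
  series$time_offset <- series$time_offset + series$tr / 2
  series$tr <- 2 * series$tr
  log_step(series, "pairwise_average")
}

#' Discard initial volumes
#'
#' Drops the first `n` volumes (MR saturation) and shifts the timing
#' metadata by `n * tr`.
#'
#' @param series A `bold_series`.
#' @param n Number of leading volumes to drop.
#' @export
discard_initial <- function(series, n) {
  nt <- n_volumes(series)
  if (n >= nt) stop("cannot discard ", n, " of ", nt, " volumes")
  if (n == 0) return(series)
  series$data <- series$data[, , , -(seq_len(n)), drop = FALSE]
  series$time_offset <- series$time_offset + n * series$tr
  log_step(series, "discard_initial", n = n)
}

#' Slice-time correction
#'
#' Resamples each slice's time courses to the acquisition time of the
#' reference slice (the first acquired) by cubic-spline interpolation,
#' clamping at the run endpoints. Ascending-interleaved order acquires the
#' odd slices first, then the even slices, evenly spread over one TR.
#'
#' @param series A `bold_series`.
#' @param slice_order `"ascending_interleaved"` or `"none"` (identity).
#' @return A `bold_series` on the same volume grid.
#' @export
slice_time_correct <- function(series,
                               slice_order = c("ascending_interleaved", "none")) {
  slice_order <- match.arg(slice_order)
  nz <- dim(series$data)[3]
  if (slice_order == "none" || nz == 1) return(series)
  acq_rank <- order(c(seq(1, nz, 2), seq(2, nz, 2)))  # slice -> acq position
  offsets <- (acq_rank - 1) / nz * series$tr
  offsets <- offsets - offsets[1]                     # reference: slice 1
  nt <- n_volumes(series)
  tgrid <- (seq_len(nt) - 1) * series$tr
  d <- dim(series$data)
  for (z in seq_len(nz)) {
    if (offsets[z] == 0) next
    sl <- matrix(series$data[, , z, ], d[1] * d[2], nt)
    # slice z sampled at tgrid + offsets[z]; evaluate at tgrid
    xout <- pmin(pmax(tgrid - offsets[z], 0), tgrid[nt])
    for (v in seq_len(nrow(sl)))
      sl[v, ] <- stats::spline(tgrid, sl[v, ], xout = xout, method = "fmm")$y
    series$data[, , z, ] <- array(sl, dim = c(d[1], d[2], nt))
  }
  log_step(series, "slice_time_correct", slice_order = slice_order)
}

#' In-plane Gaussian smoothing
#'
#' Convolves every axial slice of every volume with a 2D Gaussian of the
#' given FWHM in pixels (sigma = FWHM / 2.3548), zero-padded outside the
#' grid. Smoothing is in-plane only because slice thickness far exceeds the
#' in-plane voxel size.
#'
#' @param series A `bold_series`.
#' @param fwhm_pixels Kernel FWHM in pixels; 0 returns the input.
#' @export
gaussian_smooth <- function(series, fwhm_pixels = 2) {
  if (fwhm_pixels == 0) return(series)
  sigma <- fwhm_pixels / (2 * sqrt(2 * log(2)))
  d <- dim(series$data)
  Kx <- gauss_band(d[1], sigma)
  Ky <- gauss_band(d[2], sigma)
  # fold x: Kx %*% X for all (y,z,t) at once
  flat <- matrix(series$data, d[1], prod(d[2:4]))
  flat <- Kx %*% flat
  arr <- array(flat, dim = d)
  # fold y: permute y to the front
  arr <- aperm(arr, c(2, 1, 3, 4))
  flat <- Ky %*% matrix(arr, d[2], prod(d[c(1, 3, 4)]))
  arr <- aperm(array(flat, dim = d[c(2, 1, 3, 4)]), c(2, 1, 3, 4))
  series$data <- arr
  log_step(series, "gaussian_smooth", fwhm_pixels = fwhm_pixels)
}

# Banded Toeplitz matrix of a truncated (4 sigma) normalized Gaussian.
gauss_band <- function(n, sigma) {
  r <- min(n - 1, ceiling(4 * sigma))
  w <- stats::dnorm(-r:r, sd = sigma)
  w <- w / sum(w)
  K <- matrix(0, n, n)
  for (off in -r:r) {
    idx <- seq_len(n - abs(off))
    if (off >= 0) K[cbind(idx, idx + off)] <- w[off + r + 1]
    else K[cbind(idx - off, idx)] <- w[off + r + 1]
  }
  K
}

#' Temporal high-pass filter
#'
#' Per voxel: removes the linear trend, then zeroes every Fourier component
#' with nonzero frequency strictly below `cycles` per run length, and
#' restores the voxel mean. The kernel FWHM is carried as metadata only;
#' the cycles cutoff is the operative parameter.
#'
#' @param series A `bold_series`.
#' @param fwhm_s Temporal-smoothing kernel FWHM metadata, seconds.
#' @param cycles Cutoff in cycles per run; components at 1..cycles-1 cycles
#'   are removed. 0 returns the input.
#' @export
temporal_highpass <- function(series, fwhm_s = 12, cycles = 9) {
  if (cycles == 0) return(series)
  vox <- which(series$brain_mask)
  X <- highpass_columns(series_matrix(series, vox), cycles)
  series <- series_set_matrix(series, X, vox)
  log_step(series, "temporal_highpass", fwhm_s = fwhm_s, cycles = cycles)
}

# The same detrend + FFT high-pass applied to arbitrary columns (used to
# filter design-matrix regressors identically to the data).
highpass_columns <- function(X, cycles) {
  nt <- nrow(X)
  mu <- colMeans(X)
  tt <- seq_len(nt) - (nt + 1) / 2
  slope <- crossprod(tt, sweep(X, 2, mu)) / sum(tt^2)
  X <- X - outer(tt, as.numeric(slope)) - rep(mu, each = nt)
  F <- stats::mvfft(X)
  kill <- seq_len(nt) - 1
  drop_bins <- which(kill >= 1 & kill <= cycles - 1)
  F[drop_bins, ] <- 0
  F[nt + 1 - drop_bins, ] <- 0
  Re(stats::mvfft(F, inverse = TRUE)) / nt + rep(mu, each = nt)
}

#' Temporal FFT low-pass filter
#'
#' Zeroes every Fourier component with frequency above `cutoff_hz`.
#'
#' @param series A `bold_series`.
#' @param cutoff_hz Cutoff frequency, Hz; must be below Nyquist.
#' @export
temporal_lowpass <- function(series, cutoff_hz = 0.1) {
  nyq <- 1 / (2 * series$tr)
  if (cutoff_hz >= nyq) stop("cutoff ", cutoff_hz, " Hz is at/above Nyquist ",
                             nyq, " Hz")
  nt <- n_volumes(series)
  vox <- which(series$brain_mask)
  X <- series_matrix(series, vox)
  F <- stats::mvfft(X)
  freq <- (seq_len(nt) - 1) / (nt * series$tr)
  freq <- pmin(freq, 1 / series$tr - freq)  # two-sided
  F[freq > cutoff_hz, ] <- 0
  X <- Re(stats::mvfft(F, inverse = TRUE)) / nt
  series <- series_set_matrix(series, X, vox)
  log_step(series, "temporal_lowpass", cutoff_hz = cutoff_hz)
}

#' Standard preprocessing chains
#'
#' `preprocess_stimulus()` applies the stimulus-run chain in fixed order:
#' pairwise averaging, discard, slice-time correction, motion correction,
#' in-plane smoothing, temporal high-pass. `preprocess_resting()` applies
#' discard, slice-time correction, motion correction and the FFT low-pass.
#'
#' @param series A `bold_series`.
#' @param config A `preprocess_config`.
#' @return A preprocessed `bold_series` (motion traces, when estimated, are
#'   stored in `provenance$motion`).
#' @export
preprocess_stimulus <- function(series, config = preprocess_config()) {
  if (config$pairwise_average) series <- pairwise_average(series)
  series <- discard_initial(series, config$n_discard_volumes)
  if (config$slice_order != "none")
    series <- slice_time_correct(series, config$slice_order)
  if (config$motion_correction == "rigid") {
    mc <- rigid_motion_correct(series)
    series <- mc$series
    series$provenance$motion <- mc$motion
  }
  series <- gaussian_smooth(series, config$smoothing_fwhm)
  temporal_highpass(series, config$highpass_fwhm, config$highpass_cycles)
}

#' @rdname preprocess_stimulus
#' @export
preprocess_resting <- function(series,
                               config = preprocess_config(
                                 pairwise_average = FALSE,
                                 smoothing_fwhm = 0, highpass_cycles = 0,
                                 lowpass_hz = 0.1)) {
  series <- discard_initial(series, config$n_discard_volumes)
  if (config$slice_order != "none")
    series <- slice_time_correct(series, config$slice_order)
  if (config$motion_correction == "rigid") {
    mc <- rigid_motion_correct(series)
    series <- mc$series
    series$provenance$motion <- mc$motion
  }
  if (!is.null(config$lowpass_hz))
    series <- temporal_lowpass(series, config$lowpass_hz)
  series
}
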