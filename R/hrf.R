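#' Rat-specific two-gamma hemodynamic response function
#'
#' Parameter set for the two-gamma HRF. Defaults are the rat kernel used
#' throughout the pipeline: response peak at 16 s, undershoot peak at 40 s,
#' unit dispersions, undershoot ratio 1, onset 0.
#'
#' @param onset Delay before the response starts, seconds.
#' @param time_to_peak Time from onset to the response peak, seconds.
#' @param response_dispersion Width parameter of the response lobe, seconds.
#' @param undershoot_ratio Scaling of the undershoot lobe relative to the
#'   response lobe (0 disables the undershoot).
#' @param time_to_undershoot_peak Time from onset to the undershoot
#'   extremum, seconds.
#' @param undershoot_dispersion Width parameter of the undershoot lobe.
#' @return An object of class `hrf_params`.
#' @export
hrf_params <- function(onset = 0, time_to_peak = 16, response_dispersion = 1,
                       undershoot_ratio = 1, time_to_undershoot_peak = 40,
                       undershoot_dispersion = 1) {
  if (response_dispersion <= 0 || undershoot_dispersion <= 0)
    stop("dispersions must be positive")
  if (time_to_peak <= onset) stop("time_to_peak must exceed onset")
  if (time_to_undershoot_peak <= time_to_peak)
    stop("time_to_undershoot_peak must exceed time_to_peak")
  if (undershoot_ratio < 0) stop("undershoot_ratio must be >= 0")
  structure(list(
    onset = onset, time_to_peak = time_to_peak,
    response_dispersion = response_dispersion,
    undershoot_ratio = undershoot_ratio,
    time_to_undershoot_peak = time_to_undershoot_peak,
    undershoot_dispersion = undershoot_dispersion
  ), class = "hrf_params")
}

#' Sample the two-gamma HRF kernel
#'
#' Each lobe is a gamma density with shape = 1 + peak_time/dispersion and
#' scale = dispersion, shifted by `onset`, so that the lobe mode falls
#' exactly at the stated peak time. The kernel is the response lobe minus
#' `undershoot_ratio` times the undershoot lobe, rescaled so its maximum
#' equals 1.
#'
#' @param params An `hrf_params` object.
#' @param dt Sampling interval, seconds.
#' @param length Kernel support, seconds; must exceed the undershoot peak.
#' @return Numeric vector of kernel samples at times `seq(0, length, dt)`,
#'   with the time grid attached as attribute `time`.
#' @export
two_gamma_hrf <- function(params = hrf_params(), dt, length = 80) {
  stopifnot(inherits(params, "hrf_params"), dt > 0)
  if (length <= params$time_to_undershoot_peak)
    stop("kernel length must exceed the undershoot peak time")
  t <- seq(0, length, by = dt)
  ts <- t - params$onset
  lobe <- function(peak, disp) {
    shape <- 1 + peak / disp
    out <- numeric(base::length(ts))
    ok <- ts > 0
    out[ok] <- stats::dgamma(ts[ok], shape = shape, scale = disp)
    out
  }
  k <- lobe(params$time_to_peak, params$response_dispersion) -
    params$undershoot_ratio *
      lobe(params$time_to_undershoot_peak, params$undershoot_dispersion)
  k <- k / max(k)
  attr(k, "time") <- t
  k
}
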