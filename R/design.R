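#' Stimulus regressor: boxcar convolved with the HRF
#'
#' Builds the predicted BOLD response for a set of stimulation events: a
#' {0,1} boxcar over the events, convolved with the two-gamma HRF on a fine
#' time grid, normalized so that one isolated event peaks at exactly 1, then
#' sampled at the requested acquisition times by linear interpolation. With
#' peak normalization a regression coefficient is directly the peak %signal
#' change of an isolated response.
#'
#' @param onsets Event onsets, seconds.
#' @param duration Event duration, seconds (scalar or per event).
#' @param hrf An `hrf_params` object.
#' @param times Acquisition times to sample at, seconds.
#' @param dt_fine Fine-grid resolution for the convolution, seconds.
#' @param ramp Ramp duration, seconds; only used when `ramp_in_boxcar` is
#'   FALSE, in which case the boxcar covers only the plateau.
#' @param ramp_in_boxcar Model the full ramp+plateau as the boxcar (default)
#'   or the plateau only.
#' @return Numeric vector of regressor values at `times`.
#' @export
hrf_regressor <- function(onsets, duration, hrf = hrf_params(), times,
                          dt_fine = 0.1, ramp = 5, ramp_in_boxcar = TRUE) {
  if (length(duration) == 1) duration <- rep(duration, length(onsets))
  if (!ramp_in_boxcar) {
    onsets <- onsets + ramp
    duration <- duration - ramp
  }
  t_end <- max(times) + dt_fine
  n_fine <- ceiling(t_end / dt_fine) + 1
  tf <- (seq_len(n_fine) - 1) * dt_fine
  box <- numeric(n_fine)
  for (e in seq_along(onsets)) {
    box[tf >= onsets[e] & tf < onsets[e] + duration[e]] <- 1
  }
  kern <- two_gamma_hrf(hrf, dt = dt_fine,
                        length = max(80, hrf$time_to_undershoot_peak + 20))
  conv_open <- function(x) {
    out <- stats::convolve(x, rev(kern), type = "open") * dt_fine
    out[seq_along(x)]
  }
  # reference: one isolated event of the same duration
  ref_len <- ceiling((max(duration) + length(kern) * dt_fine) / dt_fine) + 1
  ref_box <- as.numeric((seq_len(ref_len) - 1) * dt_fine < duration[1])
  ref_peak <- max(stats::convolve(ref_box, rev(kern), type = "open") * dt_fine)
  y <- conv_open(box) / ref_peak
  stats::approx(tf, y, xout = times, rule = 2)$y
}

#' First-order GLM design matrix
#'
#' One regressor per stimulation temperature (events of that temperature
#' convolved with the HRF) plus an intercept and, optionally, a linear
#' drift column. Regressors are sampled at the effective acquisition grid
#' `t0 + (0:(n_volumes-1)) * tr_eff`.
#'
#' @param protocol A `stim_protocol`.
#' @param hrf An `hrf_params`.
#' @param n_volumes Number of volumes in the (preprocessed) series.
#' @param tr_eff Effective repetition time, seconds.
#' @param t0 Acquisition time of the first volume, seconds.
#' @param drift Include a linear drift column?
#' @param ramp_in_boxcar See [hrf_regressor()].
#' @param highpass_cycles When the series was high-pass filtered, the same
#'   cutoff (cycles per run) must be applied to the temperature regressors
#'   so that model and data live in the same subspace; 0 disables. The
#'   inter-stimulus interval (240 s) puts real response energy below a
#'   typical cutoff, so an unfiltered design against filtered data leaks
#'   misfit into the predictors.
#' @return An object of class `glm_design`: list with `X` (matrix,
#'   n_volumes x columns), `predictor_names` (the temperature columns),
#'   `tr_eff`, `times`.
#' @export
build_design <- function(protocol, hrf = hrf_params(), n_volumes, tr_eff,
                         t0 = 0, drift = FALSE, ramp_in_boxcar = TRUE,
                         highpass_cycles = 0) {
  times <- t0 + (seq_len(n_volumes) - 1) * tr_eff
  ev <- protocol$events
  if (nrow(ev) > 0 && max(ev$onset_s + ev$duration_s) > max(times) + tr_eff)
    stop("design error: protocol events extend beyond the run")
  temps <- protocol$temperatures
  cols <- list()
  for (T in temps) {
    sel <- ev$temperature_C == T
    if (!any(sel)) next
    cols[[paste0("T", T)]] <- hrf_regressor(
      ev$onset_s[sel], ev$duration_s[sel], hrf, times,
      ramp = ev$ramp_s[sel][1], ramp_in_boxcar = ramp_in_boxcar)
  }
  X <- cbind(intercept = rep(1, n_volumes))
  pred <- character(0)
  if (length(cols)) {
    P <- do.call(cbind, cols)
    if (highpass_cycles > 0) P <- highpass_columns(P, highpass_cycles)
    X <- cbind(P, X)
    pred <- names(cols)
  }
  if (drift) X <- cbind(X, drift = seq_len(n_volumes) - (n_volumes + 1) / 2)
  structure(list(X = X, predictor_names = pred, tr_eff = tr_eff,
                 times = times),
            class = "glm_design")
}

#' Export a design matrix as TSV
#' @param design A `glm_design`.
#' @param path Output path.
#' @export
write_design_tsv <- function(design, path) {
  utils::write.table(data.frame(time_s = design$times, design$X,
                                check.names = FALSE),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
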