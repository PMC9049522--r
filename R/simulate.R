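#' Simulate a stimulus-driven BOLD session
#'
#' Voxel signal model, relative to a flat baseline level:
#' \deqn{y_v(t) = B (1 + s_{k(v)}(t) + d_v u(t) + g(t) + e_v(t))}
#' where \eqn{s_k(t)} is the sum over stimulation events of the structure's
#' peak amplitude (see [model_amplitude()]) times the HRF-convolved boxcar
#' (peak-normalized to 1), \eqn{d_v u(t)} a per-voxel linear drift,
#' \eqn{g(t)} a shared AR(1) global signal and \eqn{e_v(t)} per-voxel AR(1)
#' noise. Only voxels of responsive structures carry stimulus terms; every
#' in-mask voxel carries noise. Fully determined by `seed`.
#'
#' @param atlas A `synthetic_atlas`.
#' @param protocol A `stim_protocol`.
#' @param model An `effect_model`.
#' @param hrf An `hrf_params`.
#' @param tr Repetition time, seconds.
#' @param n_volumes Number of volumes; the protocol must fit inside
#'   `n_volumes * tr`.
#' @param seed Integer seed.
#' @param baseline_level Mean signal level (arbitrary units).
#' @param ramp_in_boxcar Model ramp+plateau (default) or plateau only.
#' @return A `bold_series`.
#' @export
simulate_session <- function(atlas, protocol, model, hrf = hrf_params(),
                             tr = 2, n_volumes, seed,
                             baseline_level = 100, ramp_in_boxcar = TRUE) {
  ev <- protocol$events
  if (nrow(ev) > 0 && max(ev$onset_s + ev$duration_s) > n_volumes * tr)
    stop("design error: protocol longer than the series")
  stopifnot(model$n_structures == nrow(atlas$structure_table))
  times <- (seq_len(n_volumes) - 1) * tr
  # structure-level stimulus signals (fractional units)
  sig <- matrix(0, n_volumes, model$n_structures)
  for (T in protocol$temperatures) {
    amps <- model_amplitude(model, T)
    if (all(amps == 0)) next
    sel <- ev$temperature_C == T
    if (!any(sel)) next
    reg <- hrf_regressor(ev$onset_s[sel], ev$duration_s[sel], hrf, times,
                         ramp = ev$ramp_s[sel][1],
                         ramp_in_boxcar = ramp_in_boxcar)
    sig <- sig + outer(reg, amps / 100)
  }
  build_phantom(atlas, model, sig, tr, n_volumes, seed, baseline_level,
                provenance = list(
                  kind = "stimulus_session", seed = seed, group = model$group,
                  protocol_seed = protocol$seed, n_volumes = n_volumes))
}

#' Simulate a resting-state BOLD session
#'
#' Each structure k receives a unit-variance AR(1) latent signal; the
#' latent signals are correlated according to the planted matrix derived
#' from `model$rs_planted` (voxel-level target correlations, divided by
#' `rs_signal_fraction` internally). A voxel of structure k fluctuates as
#' \eqn{\sqrt{w} S_k(t) + \sqrt{1-w}\,\epsilon_v(t)} (w =
#' `rs_signal_fraction`), scaled to `noise_sigma` % total, plus drift and
#' global signal as in [simulate_session()]. The planted voxel-level
#' correlation between structures i and j is then exactly the requested
#' target. The planted matrix is recorded in the provenance.
#'
#' @inheritParams simulate_session
#' @param n_volumes Number of volumes (full scale: 300).
#' @return A `bold_series` with `provenance$planted_r` (the voxel-level
#'   target correlation matrix).
#' @export
simulate_resting_state <- function(atlas, model, tr = 2, n_volumes = 300,
                                   seed, baseline_level = 100) {
  stopifnot(model$n_structures == nrow(atlas$structure_table))
  w <- model$rs_signal_fraction
  Ct <- rs_target_matrix(model)        # voxel-level targets
  C <- Ct / w; diag(C) <- 1            # latent-level correlations
  if (any(abs(C[upper.tri(C)]) > 0.999))
    stop("planted correlation too high for rs_signal_fraction ", w)
  rng <- local_rng(sub_seed(seed, 17L))
  Z <- ar1_noise(n_volumes, model$n_structures, model$ar1_coefficient)
  U <- chol(C)
  S <- Z %*% U                          # latent structure signals, cov = C
  mix <- sqrt(w) * S                    # structure part of voxel signal
  ser <- build_phantom(atlas, model, NULL, tr, n_volumes, seed,
                       baseline_level,
                       latent = mix, latent_resid_frac = sqrt(1 - w),
                       provenance = list(
                         kind = "resting_state", seed = seed,
                         group = model$group, n_volumes = n_volumes,
                         planted_r = Ct))
  ser
}

# Shared phantom assembly. `sig` (t x n_struct, fractional stimulus signal)
# may be NULL. When `latent` is given (resting state), the voxel noise term
# becomes noise_sigma/100 * (latent_k + latent_resid_frac * eps_v) with eps
# unit-variance AR(1); otherwise it is noise_sigma/100 * eps_v.
build_phantom <- function(atlas, model, sig, tr, n_volumes, seed,
                          baseline_level, latent = NULL,
                          latent_resid_frac = 1, provenance = list()) {
  rng <- local_rng(sub_seed(seed, 1L))
  vox <- which(atlas$labels > 0)
  lab <- atlas$labels[vox]
  nv <- length(vox)
  ramp <- (seq_len(n_volumes) - 1) / max(1, n_volumes - 1) - 0.5
  Y <- matrix(1, n_volumes, nv)
  if (!is.null(sig)) Y <- Y + sig[, lab, drop = FALSE]
  if (!is.null(latent))
    Y <- Y + (model$noise_sigma / 100) * latent[, lab, drop = FALSE]
  if (model$drift_amplitude > 0) {
    dcoef <- stats::rnorm(nv, 0, model$drift_amplitude / 100)
    Y <- Y + outer(ramp, dcoef)
  }
  if (model$global_signal_sigma > 0) {
    g <- ar1_noise(n_volumes, 1, model$ar1_coefficient) *
      model$global_signal_sigma / 100
    Y <- Y + as.numeric(g)
  }
  if (model$noise_sigma > 0) {
    eps <- ar1_noise(n_volumes, nv, model$ar1_coefficient)
    fac <- if (is.null(latent)) 1 else latent_resid_frac
    Y <- Y + (model$noise_sigma / 100) * fac * eps
  }
  d4 <- c(dim(atlas$labels), n_volumes)
  flat <- matrix(0, prod(d4[1:3]), n_volumes)
  flat[vox, ] <- t(Y) * baseline_level
  bold_series(array(flat, dim = d4), tr = tr,
              voxel_size = atlas$voxel_size,
              brain_mask = atlas$brain_mask,
              provenance = c(provenance, list(
                noise_sigma = model$noise_sigma,
                ar1 = model$ar1_coefficient,
                drift = model$drift_amplitude,
                global_sigma = model$global_signal_sigma)))
}
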