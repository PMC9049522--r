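# Region-level phantom generator: produces the per-structure event-related
# window traces that the voxel chain (simulate -> preprocess -> GLM/FDR ->
# structure_timecourses) would deliver, directly at ROI level. The voxel
# chain is linear in the signal, so the ROI-mean trace is the planted
# response plus ROI-averaged noise; this generator is used for the
# Monte-Carlo replication and calibration studies where thousands of
# animals are needed, while the voxel chain itself is validated separately
# by parameter-recovery tests.

#' Deterministic event-window response shape
#'
#' The event-related %change window a unit-amplitude (peak 1) response
#' produces: the HRF-convolved boxcar sampled on the effective TR grid,
#' referenced to the pre-stimulus window mean.
#'
#' @param hrf An `hrf_params`.
#' @param duration Stimulus duration, seconds.
#' @param tr_eff Effective repetition time, seconds.
#' @param pre,post Window margins, time points.
#' @return Numeric vector of length `pre + ceiling(duration/tr_eff) + post`.
#' @export
roi_window_shape <- function(hrf = hrf_params(), duration = 20, tr_eff = 4,
                             pre = 10, post = 10) {
  n_during <- ceiling(duration / tr_eff)
  len <- pre + n_during + post
  times <- (seq_len(len) - 1) * tr_eff
  onset <- pre * tr_eff
  reg <- hrf_regressor(onset, duration, hrf, times)
  reg - mean(reg[seq_len(pre)])
}

#' Region-level event-window traces for one phantom animal
#'
#' For every structure and temperature, the event-related window trace in
#' %signal change: planted amplitude times the response shape, plus a
#' shared AR(1) global component and per-structure AR(1) noise with
#' standard deviation `noise_sigma * avg_factor / sqrt(n_voxels)` (the
#' pairwise volume averaging of the voxel chain shrinks AR(1) noise by
#' `avg_factor = sqrt((1 + rho) / 2)`). Each window is referenced to its
#' own pre-window mean, exactly as the ROI stage does.
#'
#' @param structure_sizes Voxel counts per structure.
#' @param model An `effect_model`.
#' @param temps Stimulation temperatures.
#' @param hrf An `hrf_params`.
#' @param tr_eff Effective TR, seconds.
#' @param pre,post Window margins, time points.
#' @param seed Per-animal seed.
#' @return Array (n_structures x window length x n_temperatures).
#' @export
simulate_roi_window_traces <- function(structure_sizes, model,
                                       temps = seq(40, 54, 2),
                                       hrf = hrf_params(), tr_eff = 4,
                                       pre = 10, post = 10, seed = 1) {
  ns <- length(structure_sizes)
  stopifnot(ns == model$n_structures)
  shape <- roi_window_shape(hrf, tr_eff = tr_eff, pre = pre, post = post)
  len <- length(shape)
  rho <- model$ar1_coefficient
  avg_factor <- sqrt((1 + rho) / 2)
  roi_sd <- model$noise_sigma * avg_factor / sqrt(structure_sizes)
  rng <- local_rng(seed)
  out <- array(NA_real_, dim = c(ns, len, length(temps)),
               dimnames = list(seq_len(ns), NULL, paste0("T", temps)))
  for (ti in seq_along(temps)) {
    amps <- model_amplitude(model, temps[ti])
    g <- as.numeric(ar1_noise(len, 1, rho)) *
      model$global_signal_sigma * avg_factor
    eps <- t(ar1_noise(len, ns, rho)) * roi_sd
    W <- outer(amps, shape) +
      matrix(g, ns, len, byrow = TRUE) + eps
    W <- W - rowMeans(W[, seq_len(pre), drop = FALSE])
    out[, , ti] <- W
  }
  out
}

#' Monte-Carlo NBS replication study at region level
#'
#' Replicates the baseline-vs-RTX network comparison: per replication, the
#' region-level traces of `n_baseline` + `n_rtx` animals are generated,
#' global regression and Fisher-z adjacency are computed per animal and
#' temperature, and the network-based statistic is evaluated per
#' temperature. Returns the matrix of NBS p-values (replications x
#' temperatures).
#'
#' @param n_reps Number of replications.
#' @param structure_sizes Voxel counts per structure (e.g. from a desk
#'   atlas).
#' @param baseline_model,rtx_model `effect_model`s for the two groups.
#' @param n_baseline,n_rtx Animals per group.
#' @param temps Stimulation temperatures.
#' @param alpha,n_perm NBS parameters.
#' @param seed Master seed.
#' @return Matrix of p-values with temperatures as column names.
#' @export
replicate_nbs_study <- function(n_reps, structure_sizes, baseline_model,
                                rtx_model, n_baseline = 18, n_rtx = 9,
                                temps = seq(40, 54, 2), alpha = 0.05,
                                n_perm = 200, seed = 1) {
  pvals <- matrix(NA_real_, n_reps, length(temps),
                  dimnames = list(NULL, paste0("T", temps)))
  for (rep_i in seq_len(n_reps)) {
    adj <- vector("list", n_baseline + n_rtx)
    grp <- rep(c("baseline", "rtx"), c(n_baseline, n_rtx))
    for (a in seq_along(grp)) {
      model <- if (grp[a] == "baseline") baseline_model else rtx_model
      tr <- simulate_roi_window_traces(
        structure_sizes, model, temps,
        seed = sub_seed(seed, rep_i * 1000L + a))
      adj[[a]] <- lapply(seq_along(temps), function(ti)
        build_adjacency(global_regression(tr[, , ti])))
    }
    for (ti in seq_along(temps)) {
      res <- nbs_unpaired(
        lapply(which(grp == "baseline"), function(a) adj[[a]][[ti]]),
        lapply(which(grp == "rtx"), function(a) adj[[a]][[ti]]),
        alpha = alpha, n_perm = n_perm,
        seed = sub_seed(seed, rep_i * 1000L + 500L + ti))
      pvals[rep_i, ti] <- res$p_value
    }
  }
  pvals
}
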