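#' Group effect model for phantom generation
#'
#' Describes how a simulated animal's brain responds to the thermal
#' stimulation and what its noise looks like. Two groups are modelled:
#'
#' * `baseline` (untreated): peak BOLD amplitude is 0 below the nociceptive
#'   threshold (48 degC) and rises linearly to `max_amplitude` %BOLD at
#'   54 degC, scaled per structure by a random gain.
#' * `rtx` (TRPV1-desensitized): flat response at every temperature except
#'   an optional small bump at 54 degC (`rtx_bump_54`).
#'
#' Only `responsive_structures` carry stimulus terms; every voxel receives
#' AR(1) noise, a linear drift and a shared global signal. For resting-state
#' phantoms, `rs_planted` plants an inter-regional correlation structure
#' (see [simulate_resting_state()]).
#'
#' @param group `"baseline"` or `"rtx"`.
#' @param n_structures Number of atlas structures the model addresses.
#' @param responsive_structures Label ids carrying stimulus responses;
#'   default: every 4th structure (25%).
#' @param max_amplitude Peak %BOLD at 54 degC for a gain-1 baseline
#'   structure.
#' @param threshold_C Temperature below which the baseline response is 0.
#' @param rtx_bump_54 %BOLD bump at 54 degC for the rtx group (0 disables).
#' @param noise_sigma Voxel noise standard deviation, % of baseline signal.
#' @param ar1_coefficient Temporal AR(1) coefficient of the noise, in [0,1).
#' @param drift_amplitude Std. dev. of the per-voxel linear drift over the
#'   run, % signal.
#' @param global_signal_sigma Std. dev. of the shared global signal, %.
#' @param gain_range Range of the per-structure amplitude gains.
#' @param rs_planted Planted resting-state correlations: `NULL` (identity),
#'   a data.frame with columns i, j, r (voxel-level target correlations), or
#'   `"functional_blocks"` to correlate structures in 4 contiguous blocks at
#'   r = 0.4.
#' @param rs_signal_fraction Fraction of voxel variance carried by the
#'   structure-level latent signal in resting-state phantoms, in (0, 1].
#' @param seed Seed for the per-structure gains.
#' @return An object of class `effect_model`.
#' @export
effect_model <- function(group = c("baseline", "rtx"), n_structures,
                         responsive_structures = NULL,
                         max_amplitude = 1.5, threshold_C = 48,
                         rtx_bump_54 = 0.3,
                         noise_sigma = 1, ar1_coefficient = 0.3,
                         drift_amplitude = 0.5, global_signal_sigma = 0.2,
                         gain_range = c(0.6, 1.4),
                         rs_planted = NULL, rs_signal_fraction = 0.9,
                         seed = 1) {
  group <- match.arg(group)
  stopifnot(n_structures >= 1, noise_sigma >= 0,
            ar1_coefficient >= 0, ar1_coefficient < 1,
            rs_signal_fraction > 0, rs_signal_fraction <= 1)
  if (is.null(responsive_structures))
    responsive_structures <- seq(1, n_structures, by = 4)
  rng <- local_rng(seed)
  gains <- stats::setNames(rep(0, n_structures), seq_len(n_structures))
  gains[responsive_structures] <-
    stats::runif(length(responsive_structures), gain_range[1], gain_range[2])
  structure(list(
    group = group, n_structures = n_structures,
    responsive_structures = as.integer(responsive_structures),
    gains = gains, max_amplitude = max_amplitude, threshold_C = threshold_C,
    rtx_bump_54 = rtx_bump_54, noise_sigma = noise_sigma,
    ar1_coefficient = ar1_coefficient, drift_amplitude = drift_amplitude,
    global_signal_sigma = global_signal_sigma,
    rs_planted = rs_planted, rs_signal_fraction = rs_signal_fraction,
    seed = seed
  ), class = "effect_model")
}

#' Peak %BOLD amplitude per structure at a given temperature
#'
#' @param model An `effect_model`.
#' @param temperature Temperature in degC.
#' @return Numeric vector (length `n_structures`) of peak %BOLD amplitudes.
#' @export
model_amplitude <- function(model, temperature) {
  base <- if (model$group == "baseline") {
    model$max_amplitude *
      max(0, (temperature - model$threshold_C) / (54 - model$threshold_C))
  } else {
    if (temperature == 54) model$rtx_bump_54 else 0
  }
  model$gains * base
}

# Resolve the planted resting-state correlation matrix (voxel-level targets).
rs_target_matrix <- function(model) {
  n <- model$n_structures
  C <- diag(n)
  pl <- model$rs_planted
  if (is.null(pl)) return(C)
  if (identical(pl, "functional_blocks")) {
    blocks <- split(seq_len(n), cut(seq_len(n), breaks = 4, labels = FALSE))
    pl <- do.call(rbind, lapply(blocks, function(b) {
      if (length(b) < 2) return(NULL)
      cmb <- utils::combn(b, 2)
      data.frame(i = cmb[1, ], j = cmb[2, ], r = 0.4)
    }))
  }
  stopifnot(all(c("i", "j", "r") %in% names(pl)))
  for (k in seq_len(nrow(pl))) {
    C[pl$i[k], pl$j[k]] <- C[pl$j[k], pl$i[k]] <- pl$r[k]
  }
  C
}
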