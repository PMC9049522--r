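#' Activated volume per brain structure
#'
#' Counts FDR-significant voxels per atlas structure and expresses the
#' whole-brain activated volume as a percentage of the brain mask.
#'
#' @param fdr_mask 3D logical array of significant voxels.
#' @param atlas A `synthetic_atlas` (or any congruent label volume wrapped
#'   in one).
#' @param brain_mask 3D logical brain mask.
#' @return List with `counts` (named integer vector per structure),
#'   `whole_brain_n`, `whole_brain_pct`.
#' @export
activated_volume <- function(fdr_mask, atlas, brain_mask = atlas$brain_mask) {
  n <- nrow(atlas$structure_table)
  act <- fdr_mask & brain_mask
  lab <- atlas$labels[act]
  counts <- tabulate(lab[lab > 0], nbins = n)
  names(counts) <- atlas$structure_table$label_id
  total <- sum(act & atlas$labels > 0)
  list(counts = counts,
       whole_brain_n = total,
       whole_brain_pct = 100 * total / max(1, sum(brain_mask)))
}

#' Event-related average time course
#'
#' Averages %signal-change windows around stimulation events over a voxel
#' set: windows span `pre` time points before stimulus onset through the
#' stimulation period (`ceiling(duration / tr_eff)` points) to `post`
#' points after it. Each window is expressed as %change from its own
#' pre-stimulus mean, so the pre-segment mean is 0 by construction.
#' Windows exceeding the run bounds are dropped with a warning.
#'
#' @param series A preprocessed `bold_series`.
#' @param onsets Event onsets, seconds (one temperature).
#' @param duration Stimulus duration, seconds.
#' @param voxels Linear voxel indices to average over.
#' @param pre,post Time points before/after the stimulation period.
#' @return Numeric trace of length `pre + ceiling(duration/tr_eff) + post`,
#'   with attribute `n_events` (windows used); NULL if no window fits or
#'   the voxel set is empty.
#' @export
event_related_average <- function(series, onsets, duration, voxels,
                                  pre = 10, post = 10) {
  if (length(voxels) == 0) return(NULL)
  roi <- if (length(voxels) == 1) {
    as.numeric(series_matrix(series, voxels))
  } else rowMeans(series_matrix(series, voxels))
  era_from_trace(roi, series$tr, series$time_offset, onsets, duration,
                 pre, post)
}

# Event-related averaging of a single (ROI-mean) trace.
era_from_trace <- function(trace, tr_eff, t0, onsets, duration,
                           pre = 10, post = 10) {
  nt <- length(trace)
  n_during <- ceiling(duration / tr_eff)
  len <- pre + n_during + post
  acc <- numeric(len)
  used <- 0
  for (on in onsets) {
    i_on <- round((on - t0) / tr_eff) + 1
    idx <- (i_on - pre):(i_on + n_during + post - 1)
    if (idx[1] < 1 || idx[len] > nt) {
      warning("event at ", on, " s exceeds run bounds; dropped")
      next
    }
    w <- trace[idx]
    base <- mean(w[seq_len(pre)])
    if (base == 0) base <- 1
    acc <- acc + 100 * (w / base - 1)
    used <- used + 1
  }
  if (used == 0) return(NULL)
  out <- acc / used
  attr(out, "n_events") <- used
  attr(out, "n_pre") <- pre
  attr(out, "n_during") <- n_during
  out
}

#' Response amplitude of an event-related trace
#'
#' Peak of the trace over the during + post segment. The pre-stimulus mean
#' is 0 by construction of [event_related_average()], so the amplitude is
#' simply the maximum of that segment (sign preserved: a negative-only
#' trace yields a non-positive amplitude).
#'
#' @param trace Trace from [event_related_average()] (or NULL).
#' @return %signal amplitude, or NA for an undefined trace.
#' @export
response_amplitude <- function(trace) {
  if (is.null(trace)) return(NA_real_)
  pre <- attr(trace, "n_pre") %||% 10
  max(trace[(pre + 1):length(trace)])
}

#' Per-structure time courses and response metrics
#'
#' The atlas-ROI second-order stage for one animal: for every structure and
#' stimulation temperature, the event-related mean BOLD time course over
#' that structure's significantly activated voxels, the derived response
#' amplitude, and the activated voxel count. Structures with no activated
#' voxels either fall back to all structure voxels (`voxel_set =
#' "activated_or_all"`, the default, which keeps every structure on a
#' common footing for network construction) or are recorded as undefined
#' (`voxel_set = "activated"`); `voxel_set = "all"` ignores the FDR mask
#' entirely.
#'
#' @param series A preprocessed `bold_series`.
#' @param atlas A `synthetic_atlas`.
#' @param protocol A `stim_protocol`.
#' @param fdr_mask 4D logical array (x, y, z, temperature) from
#'   [fdr_masks()], temperatures in `protocol$temperatures` order.
#' @param pre,post Window margins, time points.
#' @param voxel_set Voxel-selection rule (see Details).
#' @return An object of class `structure_timecourses`: list with `table`
#'   (data.frame: structure, temperature, n_activated, amplitude,
#'   trace_defined, voxels_used), `traces` (array: structure x time point x
#'   temperature), `temperatures`, `whole_brain` (data.frame per
#'   temperature: n activated, % volume).
#' @export
structure_timecourses <- function(series, atlas, protocol, fdr_mask,
                                  pre = 10, post = 10,
                                  voxel_set = c("activated_or_all",
                                                "activated", "all")) {
  voxel_set <- match.arg(voxel_set)
  temps <- protocol$temperatures
  st <- atlas$structure_table
  ns <- nrow(st)
  dur <- protocol$events$duration_s[1]
  n_during <- ceiling(dur / series$tr)
  len <- pre + n_during + post
  traces <- array(NA_real_, dim = c(ns, len, length(temps)),
                  dimnames = list(st$label_id, NULL, paste0("T", temps)))
  rows <- vector("list", ns * length(temps))
  wb <- data.frame(temperature = temps, n_activated = 0L, volume_pct = 0)
  # precompute per-structure voxel lists
  svox <- split(which(atlas$labels > 0), atlas$labels[atlas$labels > 0])
  ri <- 0
  for (ti in seq_along(temps)) {
    ev <- protocol_events(protocol, temps[ti])
    msk <- fdr_mask[, , , ti]
    av <- activated_volume(msk, atlas)
    wb$n_activated[ti] <- av$whole_brain_n
    wb$volume_pct[ti] <- av$whole_brain_pct
    act_idx <- which(msk & atlas$brain_mask)
    for (s in seq_len(ns)) {
      vox_all <- svox[[as.character(st$label_id[s])]]
      vox_act <- intersect(vox_all, act_idx)
      vox <- switch(voxel_set,
                    activated = vox_act,
                    all = vox_all,
                    activated_or_all = if (length(vox_act)) vox_act else vox_all)
      tr <- event_related_average(series, ev$onset_s, dur, vox, pre, post)
      amp <- response_amplitude(tr)
      if (!is.null(tr)) traces[s, , ti] <- tr
      ri <- ri + 1
      rows[[ri]] <- data.frame(
        structure = st$label_id[s], temperature = temps[ti],
        n_activated = length(vox_act), amplitude = amp,
        trace_defined = !is.null(tr),
        voxels_used = length(vox))
    }
  }
  structure(list(table = do.call(rbind, rows[seq_len(ri)]),
                 traces = traces, temperatures = temps,
                 whole_brain = wb, pre = pre, post = post,
                 n_during = n_during),
            class = "structure_timecourses")
}

#' Voxel-wise maximum-amplitude map
#'
#' For each temperature, computes per voxel the event-related mean %change
#' trace and takes its maximum over the during + post segment, yielding a
#' 3D maximum BOLD amplitude map per temperature.
#'
#' @param series A preprocessed `bold_series`.
#' @param protocol A `stim_protocol`.
#' @param pre,post Window margins, time points.
#' @return 4D array (x, y, z, temperature) of maximum %signal amplitudes
#'   (NA outside the brain mask), temperatures as in
#'   `protocol$temperatures`.
#' @export
max_amplitude_map <- function(series, protocol, pre = 10, post = 10) {
  temps <- protocol$temperatures
  d <- dim(series$data)[1:3]
  vox <- which(series$brain_mask)
  X <- series_matrix(series, vox)            # t x V
  nt <- nrow(X)
  dur <- protocol$events$duration_s[1]
  n_during <- ceiling(dur / series$tr)
  len <- pre + n_during + post
  out <- array(NA_real_, dim = c(d, length(temps)))
  for (ti in seq_along(temps)) {
    ev <- protocol_events(protocol, temps[ti])
    acc <- matrix(0, len, length(vox))
    used <- 0
    for (on in ev$onset_s) {
      i_on <- round((on - series$time_offset) / series$tr) + 1
      idx <- (i_on - pre):(i_on + n_during + post - 1)
      if (idx[1] < 1 || idx[len] > nt) {
        warning("event at ", on, " s exceeds run bounds; dropped")
        next
      }
      W <- X[idx, , drop = FALSE]
      base <- colMeans(W[seq_len(pre), , drop = FALSE])
      base[base == 0] <- 1
      acc <- acc + 100 * sweep(W, 2, base, "/") - 100
      used <- used + 1
    }
    if (used == 0) next
    acc <- acc / used
    mx <- apply(acc[(pre + 1):len, , drop = FALSE], 2, max)
    vol <- array(NA_real_, dim = d)
    vol[vox] <- mx
    out[, , , ti] <- vol
  }
  dimnames(out) <- list(NULL, NULL, NULL, paste0("T", temps))
  out
}

#' Tidy per-animal ROI results table
#'
#' @param stc A `structure_timecourses`.
#' @param animal,group Identifiers added as columns.
#' @return data.frame (animal, group, structure, temperature, amplitude,
#'   n_activated, voxels_used).
#' @export
roi_table <- function(stc, animal, group) {
  cbind(data.frame(animal = animal, group = group), stc$table)
}
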