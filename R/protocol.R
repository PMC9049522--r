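#' Thermal stimulation protocol
#'
#' Builds the pseudo-randomized thermal stimulation design: eight target
#' temperatures from 40 to 54 degC in 2 degC steps, each presented exactly
#' once per set. Every stimulus lasts 20 s (5 s ramp + 15 s plateau) and is
#' followed by 3 min 40 s of rest; the session opens with a 2 min lead-in
#' rest. Set orders are drawn at random under the constraint that the same
#' temperature is never presented twice in a row, including across set
#' boundaries (no habituation by double presentation).
#'
#' @param n_sets Number of stimulation sets (each containing all eight
#'   temperatures once). The full-scale session uses 3 sets.
#' @param seed Integer seed; the event order is fully determined by it.
#' @param lead_in Rest before the first stimulus, seconds.
#' @param ramp Temperature ramp duration, seconds.
#' @param plateau Plateau duration at target temperature, seconds.
#' @param inter_stimulus_rest Rest after each stimulus, seconds.
#' @param tr Volume repetition time the protocol is paired with, seconds.
#'
#' @return An object of class `stim_protocol`: a list with `events`
#'   (data.frame: onset_s, ramp_s, plateau_s, duration_s, temperature_C,
#'   set_index), `lead_in`, `inter_stimulus_rest`, `tr`, `temperatures`,
#'   `duration_s` (total session length incl. final rest) and `seed`.
#' @export
build_stimulus_protocol <- function(n_sets, seed,
                                    lead_in = 120, ramp = 5, plateau = 15,
                                    inter_stimulus_rest = 220, tr = 2) {
  stopifnot(n_sets >= 1, is.numeric(seed), length(seed) == 1)
  temps <- seq(40, 54, by = 2)
  rng <- local_rng(seed)
  order_all <- integer(0)
  last <- NA_real_
  for (s in seq_len(n_sets)) {
    # rejection-resample a permutation whose head differs from the previous
    # set's tail; for 8 temperatures 7/8 of draws are admissible
    for (attempt in 1:1000) {
      perm <- sample(temps)
      if (is.na(last) || perm[1] != last) break
      if (attempt == 1000) stop("could not satisfy no-adjacent-repeat constraint")
    }
    order_all <- c(order_all, perm)
    last <- perm[length(perm)]
  }
  n_ev <- length(order_all)
  duration <- ramp + plateau
  onsets <- lead_in + (seq_len(n_ev) - 1) * (duration + inter_stimulus_rest)
  events <- data.frame(
    onset_s = onsets,
    ramp_s = ramp,
    plateau_s = plateau,
    duration_s = duration,
    temperature_C = order_all,
    set_index = rep(seq_len(n_sets), each = length(temps))
  )
  structure(list(
    events = events,
    lead_in = lead_in,
    inter_stimulus_rest = inter_stimulus_rest,
    tr = tr,
    temperatures = temps,
    duration_s = lead_in + n_ev * (duration + inter_stimulus_rest),
    seed = seed
  ), class = "stim_protocol")
}

#' @export
print.stim_protocol <- function(x, ...) {
  cat(sprintf(
    "Stimulation protocol: %d events (%d sets x %d temperatures), %.0f s total\n",
    nrow(x$events), max(x$events$set_index), length(x$temperatures), x$duration_s))
  cat(sprintf("  lead-in %g s, stimulus %g s (%g ramp + %g plateau), rest %g s\n",
              x$lead_in, x$events$duration_s[1], x$events$ramp_s[1],
              x$events$plateau_s[1], x$inter_stimulus_rest))
  invisible(x)
}

#' Write / read a protocol event table
#'
#' Tab-separated event files carry onset_s, duration_s, temperature_C and
#' set_index, one row per stimulus.
#'
#' @param protocol A `stim_protocol`.
#' @param path Output TSV path.
#' @export
write_protocol_tsv <- function(protocol, path) {
  ev <- protocol$events[, c("onset_s", "duration_s", "temperature_C", "set_index")]
  utils::write.table(ev, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_protocol_tsv
#' @param tr Repetition time to attach, seconds.
#' @export
read_protocol_tsv <- function(path, tr = 2) {
  ev <- utils::read.delim(path)
  stopifnot(all(c("onset_s", "duration_s", "temperature_C") %in% names(ev)))
  if (is.null(ev$set_index)) ev$set_index <- 1L
  gaps <- diff(ev$onset_s) - ev$duration_s[-nrow(ev)]
  structure(list(
    events = ev,
    lead_in = ev$onset_s[1],
    inter_stimulus_rest = if (length(gaps)) gaps[1] else NA_real_,
    tr = tr,
    temperatures = sort(unique(ev$temperature_C)),
    duration_s = ev$onset_s[nrow(ev)] + ev$duration_s[nrow(ev)] +
      (if (length(gaps)) gaps[1] else 0),
    seed = NA_integer_
  ), class = "stim_protocol")
}

#' Events of one stimulation temperature
#' @param protocol A `stim_protocol`.
#' @param temperature Temperature in degC.
#' @return The matching rows of the event table.
#' @export
protocol_events <- function(protocol, temperature) {
  protocol$events[protocol$events$temperature_C == temperature, , drop = FALSE]
}
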