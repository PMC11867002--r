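#' Cyclic stimulation schedule
#'
#' Describes a cyclic DBS protocol: trains of `on_duration` seconds of
#' stimulation at `stim_frequency` Hz separated by `off_duration` seconds of
#' pause. Train onsets/offsets are in seconds from recording start.
#'
#' @param stim_frequency pulse frequency in Hz (10, 16, 20, 26 or 30 in the
#'   protocol emulated here), or NA for a baseline (no-DBS) block.
#' @param train_onsets,train_offsets train boundary times in seconds.
#' @param on_duration,off_duration cycle phase durations in seconds.
#' @param pulse_amplitude stimulation amplitude in mA (metadata only).
#' @param tol onset/offset consistency tolerance in seconds (one sample at
#'   the working sample rate is appropriate).
#' @return an object of class `stim_schedule`.
#' @export
stim_schedule <- function(stim_frequency, train_onsets, train_offsets,
                          on_duration = 5, off_duration = 3,
                          pulse_amplitude = 3, tol = 1e-3) {
  stopifnot(length(train_onsets) == length(train_offsets))
  if (length(train_onsets) > 0) {
    if (any(abs((train_offsets - train_onsets) - on_duration) > tol))
      stop("train_offsets - train_onsets must equal on_duration")
    if (is.unsorted(train_onsets, strictly = TRUE))
      stop("trains must be ordered")
    if (any(utils::head(train_offsets, -1) > utils::tail(train_onsets, -1)))
      stop("trains must be disjoint")
  }
  structure(list(stim_frequency = stim_frequency,
                 on_duration = on_duration,
                 off_duration = off_duration,
                 pulse_amplitude = pulse_amplitude,
                 train_onsets = as.numeric(train_onsets),
                 train_offsets = as.numeric(train_offsets)),
            class = "stim_schedule")
}

#' Tile a recording with ON/OFF stimulation cycles
#'
#' Trains of `on` seconds followed by `off` seconds of pause tile
#' `[0, duration]`. A train whose ON phase does not fit completely is
#' dropped; a final train whose pause is cut short is kept and flagged via
#' the `partial` attribute.
#'
#' @param duration recording duration in seconds (at least one ON phase
#'   must fit).
#' @param stim_frequency pulse frequency in Hz, or NA for baseline.
#' @param on,off ON/OFF phase durations in seconds (protocol default 5/3).
#' @param pulse_amplitude stimulation amplitude in mA.
#' @return a `stim_schedule`; `attr(, "partial")` marks an incomplete final
#'   pause.
#' @export
make_schedule <- function(duration, stim_frequency, on = 5, off = 3,
                          pulse_amplitude = 3) {
  if (duration < on)
    stop("duration must accommodate at least one complete ON phase")
  period <- on + off
  onsets <- seq(0, duration, by = period)
  onsets <- onsets[onsets + on <= duration]
  sched <- stim_schedule(stim_frequency, onsets, onsets + on,
                         on_duration = on, off_duration = off,
                         pulse_amplitude = pulse_amplitude)
  attr(sched, "partial") <- length(onsets) > 0 &&
    (onsets[length(onsets)] + period > duration)
  sched
}

#' Pulse times of a cyclic schedule
#'
#' Pulses are spaced 1/stim_frequency seconds apart within every ON phase;
#' with the 5 s trains and integer ON-phase cycle counts of the emulated
#' protocol the last pulse of each train falls exactly on the train offset,
#' the time the after-effect epochs are centered on.
#'
#' @param schedule a `stim_schedule`.
#' @return numeric vector of pulse times in seconds.
#' @export
pulse_times <- function(schedule) {
  f <- schedule$stim_frequency
  if (is.null(f) || is.na(f)) return(numeric(0))
  unlist(lapply(seq_along(schedule$train_onsets), function(i) {
    on <- schedule$train_onsets[i]
    k <- 0:floor((schedule$train_offsets[i] - on) * f + 1e-9)
    on + k / f
  }))
}

#' @export
print.stim_schedule <- function(x, ...) {
  f <- x$stim_frequency
  cat(sprintf("<stim_schedule> %s, %d trains, %g s ON / %g s OFF, %g mA\n",
              if (is.na(f)) "baseline (DBS OFF)" else sprintf("%g Hz", f),
              length(x$train_onsets), x$on_duration, x$off_duration,
              x$pulse_amplitude))
  invisible(x)
}
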