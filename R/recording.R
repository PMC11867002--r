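#' Event table
#'
#' Long-format table of time-stamped events: stimulation train boundaries,
#' individual pulses, finger taps and visual cues of the tapping task.
#'
#' @param onset event onsets in seconds.
#' @param duration event durations in seconds (0 for point events).
#' @param event_type one of `train_onset`, `train_offset`, `pulse`, `tap`,
#'   `cue_green`, `cue_red`.
#' @param condition stimulation frequency in Hz as character (e.g. "20"),
#'   or "baseline".
#' @return a `data.frame` with class `event_table`.
#' @export
event_table <- function(onset = numeric(0), duration = numeric(0),
                        event_type = character(0),
                        condition = character(0)) {
  types <- c("train_onset", "train_offset", "pulse", "tap",
             "cue_green", "cue_red")
  n <- length(onset)
  if (n > 0) {
    if (length(duration) == 1) duration <- rep(duration, n)
    if (length(condition) == 1) condition <- rep(condition, n)
  }
  stopifnot(length(duration) == n, length(event_type) == n,
            length(condition) == n)
  if (!all(event_type %in% types))
    stop("unknown event_type: ",
         paste(setdiff(event_type, types), collapse = ", "))
  if (any(duration < 0)) stop("event durations must be >= 0")
  for (ty in unique(event_type)) {
    if (is.unsorted(onset[event_type == ty]))
      stop("event onsets must be nondecreasing within a type (", ty, ")")
  }
  structure(data.frame(onset = as.numeric(onset),
                       duration = as.numeric(duration),
                       event_type = event_type,
                       condition = as.character(condition),
                       stringsAsFactors = FALSE),
            class = c("event_table", "data.frame"))
}

#' Build the event rows describing a stimulation schedule
#'
#' @param schedule a `stim_schedule`.
#' @param condition condition label; defaults to the schedule frequency.
#' @param pulses include one `pulse` event per stimulation pulse.
#' @return an `event_table`.
#' @export
events_from_schedule <- function(schedule, condition = NULL, pulses = FALSE) {
  f <- schedule$stim_frequency
  condition <- condition %||% (if (is.na(f)) "baseline" else as.character(f))
  n <- length(schedule$train_onsets)
  ev <- event_table(onset = c(schedule$train_onsets, schedule$train_offsets),
                    duration = c(rep(schedule$on_duration, n), rep(0, n)),
                    event_type = rep(c("train_onset", "train_offset"),
                                     each = n),
                    condition = condition)
  if (pulses && !is.na(f)) {
    pt <- pulse_times(schedule)
    ev <- rbind(ev, event_table(pt, 0, rep("pulse", length(pt)), condition))
  }
  ev <- ev[order(ev$onset, ev$event_type), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

#' Reconstruct a stimulation schedule from an event table
#'
#' @param events an `event_table` with `train_onset`/`train_offset` rows.
#' @param stim_frequency pulse frequency; parsed from the condition column
#'   when omitted.
#' @return a `stim_schedule`, or NULL when the table holds no trains.
#' @export
schedule_from_events <- function(events, stim_frequency = NULL) {
  on <- events$onset[events$event_type == "train_onset"]
  off <- events$onset[events$event_type == "train_offset"]
  if (length(on) == 0) return(NULL)
  if (is.null(stim_frequency)) {
    cond <- events$condition[events$event_type == "train_onset"][1]
    stim_frequency <- suppressWarnings(as.numeric(cond))
  }
  dur_on <- stats::median(off - on)
  dur_off <- if (length(on) > 1) stats::median(diff(on)) - dur_on else NA
  stim_schedule(stim_frequency, on, off, on_duration = dur_on,
                off_duration = dur_off %||% NA)
}

#' Continuous multichannel recording
#'
#' The native container for (simulated) sensor data: a channels x samples
#' matrix of field amplitudes in arbitrary units, plus sample rate, sensor
#' layout, event table and, for simulations, the generator's ground-truth
#' ledger.
#'
#' @param data channels x samples numeric matrix; rows ordered and named as
#'   `layout$channel_ids`.
#' @param sample_rate sampling rate in Hz.
#' @param layout a `sensor_layout`.
#' @param events an `event_table` (empty by default).
#' @param ground_truth optional list recording injected simulation
#'   parameters.
#' @return an object of class `raw_recording`.
#' @export
raw_recording <- function(data, sample_rate, layout,
                          events = event_table(), ground_truth = NULL) {
  data <- as.matrix(data)
  stopifnot(nrow(data) == length(layout$channel_ids), sample_rate > 0)
  if (!all(is.finite(data))) stop("all samples must be finite")
  rownames(data) <- layout$channel_ids
  dur <- ncol(data) / sample_rate
  if (nrow(events) > 0 && (any(events$onset < 0) || any(events$onset > dur)))
    stop("every event time must lie within [0, duration]")
  structure(list(data = data, sample_rate = sample_rate, layout = layout,
                 events = events, ground_truth = ground_truth),
            class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf(
    "<raw_recording> %d channels x %d samples @ %g Hz (%.1f s), %d events\n",
    nrow(x$data), ncol(x$data), x$sample_rate,
    ncol(x$data) / x$sample_rate, nrow(x$events)))
  invisible(x)
}

#' Recording duration in seconds
#' @param raw a `raw_recording`.
#' @return duration in seconds.
#' @export
recording_duration <- function(raw) ncol(raw$data) / raw$sample_rate

#' Set of trials cut from a recording
#'
#' Trials x channels x time array, either aligned to the DBS train offsets
#' (time 0 = last pulse of each train) or cut as consecutive fixed-length
#' baseline epochs.
#'
#' @param data trials x channels x time array.
#' @param times sample times in seconds relative to the alignment event.
#' @param sample_rate sampling rate in Hz.
#' @param alignment `"train_offset"` or `"consecutive"`.
#' @param condition condition label.
#' @param kept_trial_ids integer ids of the retained trials.
#' @param layout the `sensor_layout` the channels refer to.
#' @return an object of class `epoch_set`.
#' @export
epoch_set <- function(data, times, sample_rate,
                      alignment = c("train_offset", "consecutive"),
                      condition = "baseline", kept_trial_ids = NULL,
                      layout = NULL) {
  alignment <- match.arg(alignment)
  stopifnot(length(dim(data)) == 3, dim(data)[3] == length(times))
  if (alignment == "train_offset" && !any(abs(times) < 0.5 / sample_rate))
    stop("offset-aligned epochs must contain t = 0")
  if (!is.null(layout) && dim(data)[2] != length(layout$channel_ids))
    stop("channel dimension inconsistent with layout")
  kept_trial_ids <- kept_trial_ids %||% seq_len(dim(data)[1])
  dimnames(data) <- list(NULL,
                         if (is.null(layout)) dimnames(data)[[2]]
                         else layout$channel_ids,
                         NULL)
  structure(list(data = data, times = as.numeric(times),
                 sample_rate = sample_rate, alignment = alignment,
                 condition = condition, kept_trial_ids = kept_trial_ids,
                 layout = layout),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<epoch_set> %d trials x %d channels x %d samples (%s, %s), t in [%.3f, %.3f] s\n",
    d[1], d[2], d[3], x$alignment, x$condition,
    min(x$times), max(x$times)))
  invisible(x)
}

n_trials <- function(epochs) dim(epochs$data)[1]
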