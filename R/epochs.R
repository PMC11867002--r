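#' Detect DBS train offsets
#'
#' Returns one offset time per stimulation train, the time of the last
#' pulse of the train, which offset-aligned epochs are centered on. When
#' the event table carries `train_offset` events these are authoritative;
#' otherwise offsets are detected from an artifact-dominated channel as the
#' last sample exceeding 8 times the channel's median absolute deviation
#' within each ON period (pulses separated by gaps longer than one second
#' start a new train).
#'
#' @param raw a `raw_recording`.
#' @param method `"events"` or `"artifact_channel"`.
#' @param channel artifact channel id (required for
#'   `method = "artifact_channel"`).
#' @param mad_factor detection threshold in MADs.
#' @param gap minimal inter-train gap in seconds for pulse clustering.
#' @return numeric vector of offset times in seconds (empty for a baseline
#'   recording).
#' @export
detect_train_offsets <- function(raw,
                                 method = c("events", "artifact_channel"),
                                 channel = NULL, mad_factor = 8, gap = 1) {
  method <- match.arg(method)
  if (method == "events") {
    return(raw$events$onset[raw$events$event_type == "train_offset"])
  }
  if (is.null(channel)) stop("artifact_channel method needs a channel id")
  x <- abs(raw$data[channel, ])
  thr <- mad_factor * stats::mad(x)
  supra <- which(x > thr)
  if (length(supra) == 0) return(numeric(0))
  fs <- raw$sample_rate
  starts <- c(TRUE, diff(supra) > gap * fs)
  train_id <- cumsum(starts)
  last_idx <- tapply(supra, train_id, max)
  # warn about scheduled trains without any pulse
  sched_on <- raw$events$onset[raw$events$event_type == "train_onset"]
  if (length(sched_on) > length(last_idx))
    warning(length(sched_on) - length(last_idx),
            " scheduled ON period(s) without detectable pulses; skipped")
  as.numeric((last_idx - 1) / fs)
}

#' Cut offset-aligned epochs
#'
#' Extracts trials of +/- `half_width` seconds around each train offset,
#' with t = 0 at the offset sample. Offsets closer than `half_width` to
#' either record edge are dropped (no zero padding, to keep wavelet edge
#' artifacts out of the analysis) and reported via the `dropped` attribute.
#'
#' @param raw a `raw_recording`.
#' @param offsets offset times in seconds (see [detect_train_offsets()]).
#' @param half_width epoch half-width in seconds.
#' @param condition condition label (default from the event table).
#' @return an `epoch_set` aligned to `train_offset`.
#' @export
make_offset_epochs <- function(raw, offsets, half_width = 3.5,
                               condition = NULL) {
  fs <- raw$sample_rate
  dur <- recording_duration(raw)
  keep <- offsets >= half_width & offsets <= dur - half_width
  dropped <- offsets[!keep]
  if (length(dropped) > 0)
    message(length(dropped), " offset(s) within ", half_width,
            " s of a record edge dropped")
  offsets <- offsets[keep]
  hw <- round(half_width * fs)
  times <- (-hw:hw) / fs
  nch <- nrow(raw$data)
  data <- array(0, dim = c(length(offsets), nch, length(times)))
  for (i in seq_along(offsets)) {
    c0 <- round(offsets[i] * fs) + 1L
    data[i, , ] <- raw$data[, (c0 - hw):(c0 + hw)]
  }
  condition <- condition %||%
    (if (nrow(raw$events) > 0) raw$events$condition[1] else "baseline")
  ep <- epoch_set(data, times, fs, alignment = "train_offset",
                  condition = condition, layout = raw$layout)
  attr(ep, "dropped") <- dropped
  ep
}

#' Cut consecutive baseline epochs
#'
#' Splits a (DBS OFF) recording into non-overlapping back-to-back epochs of
#' `length` seconds; the trailing remainder is discarded. Used to obtain a
#' baseline lateralization estimate when no train offsets exist to align
#' to.
#'
#' @param raw a `raw_recording`.
#' @param length epoch length in seconds (default 7, matching the duration
#'   of the +/-3.5 s offset-aligned epochs).
#' @return an `epoch_set` with `alignment = "consecutive"`.
#' @export
make_consecutive_epochs <- function(raw, length = 7) {
  fs <- raw$sample_rate
  nper <- round(length * fs)
  ntr <- floor(ncol(raw$data) / nper)
  if (ntr == 0) warning("record shorter than one epoch; 0 epochs returned")
  nch <- nrow(raw$data)
  data <- array(0, dim = c(ntr, nch, nper))
  for (i in seq_len(ntr))
    data[i, , ] <- raw$data[, ((i - 1) * nper + 1):(i * nper)]
  epoch_set(data, (seq_len(nper) - 1) / fs, fs, alignment = "consecutive",
            condition = if (nrow(raw$events) > 0) raw$events$condition[1]
            else "baseline",
            layout = raw$layout)
}

#' Amplitude-based trial rejection
#'
#' Automated stand-in for visual artifact screening: for each channel the
#' per-trial peak absolute amplitude is z-scored across trials; a trial is
#' dropped when its maximum z over channels exceeds the threshold.
#'
#' @param epochs an `epoch_set` with at least 5 trials.
#' @param z_threshold rejection threshold (default 6; `Inf` disables).
#' @return the `epoch_set` with offending trials removed,
#'   `kept_trial_ids` updated and a rejection log (trial, statistic) in
#'   `attr(, "rejection_log")`.
#' @export
reject_artifacts <- function(epochs, z_threshold = 6) {
  ntr <- n_trials(epochs)
  if (ntr < 5) stop("need at least 5 trials for rejection statistics")
  peak <- apply(abs(epochs$data), c(1, 2), max)     # trials x channels
  mu <- colMeans(peak)
  sdv <- apply(peak, 2, stats::sd)
  sdv[sdv == 0] <- Inf
  z <- sweep(sweep(peak, 2, mu), 2, sdv, "/")
  stat <- apply(z, 1, max)
  bad <- stat > z_threshold
  if (mean(bad) > 0.5)
    stop(sum(bad), " of ", ntr, " trials exceed the threshold; ",
         "review z_threshold before discarding the majority of the data")
  out <- epochs
  out$data <- epochs$data[!bad, , , drop = FALSE]
  out$kept_trial_ids <- epochs$kept_trial_ids[!bad]
  attr(out, "rejection_log") <- data.frame(
    trial = epochs$kept_trial_ids[bad],
    reason = rep("peak_amplitude_z", sum(bad)),
    statistic = stat[bad])
  out
}
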