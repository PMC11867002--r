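#' Select the sensors of interest from the pulse-evoked field
#'
#' Algorithmic stand-in for visual sensor selection: a left-hemisphere
#' channel enters the ROI when its pulse-locked evoked amplitude -- the
#' average over all pulse-aligned windows, peak absolute value within
#' 5-30 ms after the pulse -- exceeds `z_thresh` times the channel's noise
#' reference. The noise reference is the SD of a "null evoked" trace built
#' the same way from windows placed at evenly spaced pulse-free times in
#' the stimulation pause, so the statistic is deterministic given the
#' input.
#'
#' @param epochs an offset-aligned `epoch_set` (pre-offset samples contain
#'   the pulses).
#' @param layout the `sensor_layout` (uses hemisphere labels).
#' @param stim_frequency pulse frequency in Hz (pulses at t = -k / f).
#' @param z_thresh evoked-field z threshold.
#' @param pre_window seconds before the offset to harvest pulses from.
#' @return character vector of selected left-channel ids; errors when
#'   empty, advising a threshold reduction.
#' @export
select_roi <- function(epochs, layout, stim_frequency, z_thresh = 4,
                       pre_window = 3) {
  fs <- epochs$sample_rate
  t <- epochs$times
  win <- c(-0.005, 0.040)                      # around each pulse
  nwin <- round(diff(win) * fs)
  rel <- seq_len(nwin) - 1L
  pulse_t <- -rev(seq(0, pre_window, by = 1 / stim_frequency))
  pulse_t <- pulse_t[pulse_t + win[1] >= t[1]]
  p_idx <- vapply(pulse_t + win[1], function(x) which.min(abs(t - x)),
                  integer(1))
  # pulse-free reference windows inside the pause (after the last pulse)
  pause_lim <- c(0.5, max(t) - diff(win))
  null_t <- seq(pause_lim[1], pause_lim[2], length.out = length(pulse_t))
  n_idx <- vapply(null_t, function(x) which.min(abs(t - x)), integer(1))
  peak_rel <- rel / fs + win[1]
  peak_sel <- peak_rel >= 0.005 & peak_rel <= 0.030
  left <- layout$channel_ids[layout$hemisphere == "left"]
  z <- vapply(left, function(ch) {
    x <- colMeans(epochs$data[, ch, , drop = FALSE][, 1, ])   # trial avg
    evoked <- rowMeans(vapply(p_idx, function(i) x[i + rel], numeric(nwin)))
    nullev <- rowMeans(vapply(n_idx, function(i) x[i + rel], numeric(nwin)))
    evoked <- evoked - mean(evoked)
    max(abs(evoked[peak_sel])) / stats::sd(nullev)
  }, numeric(1))
  roi <- left[z > z_thresh]
  if (length(roi) == 0)
    stop("no channel exceeds the evoked-field threshold; ",
         "consider lowering z_thresh (max z = ", round(max(z), 2), ")")
  attr(roi, "z") <- z
  roi
}

#' Hemispheric lateralization index
#'
#' `LI = (Left - Right) / (Left + Right)` of band-limited power aggregates;
#' positive values indicate left-hemispheric dominance. Defined for
#' non-negative aggregates; when both are zero the index is undefined and
#' returned as NA with a warning.
#'
#' @param left,right non-negative power aggregates (vectors are handled
#'   elementwise).
#' @return the index, in [-1, 1] where defined.
#' @export
lateralization_index <- function(left, right) {
  if (any(left < 0, na.rm = TRUE) || any(right < 0, na.rm = TRUE))
    stop("power aggregates must be non-negative")
  tot <- left + right
  out <- (left - right) / tot
  if (any(tot == 0, na.rm = TRUE)) {
    warning("LI undefined where Left + Right = 0; returned NA")
    out[tot == 0] <- NA_real_
  }
  out
}

#' Frequency-resolved after-effect lateralization profile
#'
#' Computes, per frequency bin of a [segment_spectrum()], the LI of the
#' ROI-averaged power: `Left` is the arithmetic mean power over the left
#' sensors of interest, `Right` the mean over their mirrored right
#' counterparts (obtained through the layout's mirror map).
#'
#' @param spectrum a `segment_spectrum`.
#' @param layout a `sensor_layout` with `mirror_map` set.
#' @param roi_left character vector of left ROI channel ids.
#' @return an object of class `li_profile` with `freqs`, `li`, `left`,
#'   `right`, `roi_left`, `roi_right`.
#' @export
aftereffect_li <- function(spectrum, layout, roi_left) {
  if (length(roi_left) == 0) stop("roi_left must not be empty")
  if (is.null(layout$mirror_map)) stop("layout has no mirror_map")
  roi_right <- unname(layout$mirror_map[roi_left])
  if (anyNA(roi_right)) stop("ROI contains unmirrored channels")
  L <- colMeans(spectrum$power[roi_left, , drop = FALSE])
  R <- colMeans(spectrum$power[roi_right, , drop = FALSE])
  structure(list(freqs = spectrum$freqs,
                 li = lateralization_index(L, R),
                 left = L, right = R,
                 roi_left = roi_left, roi_right = roi_right),
            class = "li_profile")
}

#' Baseline-normalized lateralization profile
#'
#' Subtracts the baseline (DBS OFF) LI from the after-effect LI per
#' frequency bin, yielding the normalized LI tested against zero.
#'
#' @param stim_profile,baseline_profile `li_profile`s on identical
#'   frequency grids.
#' @return a `li_profile` with an additional `normalized_li` element (and
#'   `baseline_li` carrying the subtracted values).
#' @export
normalized_li <- function(stim_profile, baseline_profile) {
  if (length(stim_profile$freqs) != length(baseline_profile$freqs) ||
      any(abs(stim_profile$freqs - baseline_profile$freqs) > 1e-9))
    stop("frequency grids of the two profiles do not match")
  out <- stim_profile
  out$baseline_li <- baseline_profile$li
  out$normalized_li <- stim_profile$li - baseline_profile$li
  out
}

#' Tapping-task lateralization by stimulation state
#'
#' LI of band-averaged power (default 14-18 Hz, the band with the
#' strongest after-effect) over the ROI during finger tapping, computed
#' separately for DBS ON and the pauses (DBS OFF). Only samples inside
#' green-cue (tapping) windows and outside wavelet edge regions enter;
#' ON-state samples start `on_lag` seconds after train onset to skip
#' stimulator transients.
#'
#' @param tfr a `tfr` of the continuous tapping recording (one trial).
#' @param schedule the session's `stim_schedule` (NULL = all OFF).
#' @param green_windows `[start, end)` matrix of tapping windows.
#' @param layout a `sensor_layout` with mirror map.
#' @param roi_left left ROI channel ids.
#' @param band frequency band in Hz.
#' @param on_lag seconds after train onset before ON samples count.
#' @return data.frame with columns `state` ("on"/"off") and `li`.
#' @export
tapping_li <- function(tfr, schedule, green_windows, layout, roi_left,
                       band = c(14, 18), on_lag = 0.5) {
  roi_right <- unname(layout$mirror_map[roi_left])
  fsel <- tfr$freqs >= band[1] & tfr$freqs <= band[2]
  if (!any(fsel)) stop("band contains no frequencies of the TFR grid")
  li <- match(roi_left, tfr$channel_ids)
  ri <- match(roi_right, tfr$channel_ids)
  if (anyNA(li) || anyNA(ri)) stop("ROI channels missing from the TFR")
  t <- tfr$times
  on_w <- if (is.null(schedule)) matrix(numeric(0), ncol = 2) else
    cbind(schedule$train_onsets + on_lag, schedule$train_offsets)
  off_w <- if (is.null(schedule))
    matrix(c(min(t), max(t)), ncol = 2)
  else {
    ends <- c(schedule$train_onsets[-1], max(t))
    cbind(schedule$train_offsets, ends)
  }
  in_windows <- function(tv, w) {
    if (nrow(w) == 0) return(rep(FALSE, length(tv)))
    Reduce(`|`, lapply(seq_len(nrow(w)),
                       function(i) tv >= w[i, 1] & tv < w[i, 2]))
  }
  green <- in_windows(t, green_windows) & tfr$valid
  res <- lapply(c(on = "on", off = "off"), function(state) {
    sel <- green & in_windows(t, if (state == "on") on_w else off_w)
    if (!any(sel)) return(NA_real_)
    Lp <- mean(tfr$power[li, fsel, sel])
    Rp <- mean(tfr$power[ri, fsel, sel])
    lateralization_index(Lp, Rp)
  })
  data.frame(state = names(res), li = unlist(res), row.names = NULL)
}

#' Tapping lateralization across conditions
#'
#' Applies [tapping_li()] per stimulation condition and drops the
#' condition whose stimulation frequency falls inside the analysis band
#' (16 Hz by default, whose artifact contaminates 14-18 Hz), with a
#' message logging the exclusion.
#'
#' @param sessions named list (by condition, e.g. `"20"`) of lists with
#'   elements `tfr`, `schedule`, `green_windows`, `layout`, `roi_left`.
#' @param band analysis band in Hz.
#' @param exclude_frequency condition to exclude (Hz).
#' @return data.frame (condition, state, li); the excluded condition is
#'   absent.
#' @export
tapping_li_table <- function(sessions, band = c(14, 18),
                             exclude_frequency = 16) {
  out <- list()
  for (cond in names(sessions)) {
    f <- suppressWarnings(as.numeric(cond))
    if (!is.na(f) && !is.na(exclude_frequency) && f == exclude_frequency) {
      message("condition ", cond,
              " Hz excluded: stimulation artifact inside the ",
              band[1], "-", band[2], " Hz band")
      next
    }
    s <- sessions[[cond]]
    tl <- tapping_li(s$tfr, s$schedule, s$green_windows, s$layout,
                     s$roi_left, band = band)
    tl$condition <- cond
    out[[cond]] <- tl
  }
  if (length(out) == 0) return(data.frame(condition = character(0),
                                          state = character(0),
                                          li = numeric(0)))
  do.call(rbind, c(out, make.row.names = FALSE))[, c("condition", "state",
                                                     "li")]
}
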