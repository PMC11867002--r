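#' Simulation configuration
#'
#' Parameterizes the synthetic cyclic-DBS generator. The signal model per
#' channel is: aperiodic 1/f background + hemisphere-weighted narrowband
#' beta (band-pass filtered Gaussian noise, so the beta envelope fluctuates
#' like real sensorimotor rhythms and phase-based entrainment checks are
#' non-trivial) + a pulse-train artifact during ON phases (1-sample
#' biphasic impulses projected onto the "wire path" channels, plus a small
#' pulse-evoked field on the left sensorimotor channels that the ROI
#' selection keys on) + a post-train response. In `induced` mode the
#' response multiplies the left-ROI beta envelope by
#' `1 + A exp(-t/tau)` after every train offset (a power boost without
#' phase alignment); in `entrainment` mode it adds a decaying sinusoid at
#' the stimulation frequency, phase-continuous with the final pulse (phase
#' alignment across trains).
#'
#' Defaults encode the emulated protocol (8 min blocks, 5 s ON / 3 s OFF,
#' stimulation at 10/16/20/26/30 Hz, 3 mA) and a beta after-effect with
#' `tau = 0.15` s so the power boost falls below the background by roughly
#' 400 ms. The beta peak is set to about twice the aperiodic background at
#' 15 Hz, a typical sensorimotor signal-to-background ratio.
#'
#' @param n_subjects cohort size.
#' @param n_channels_per_hemisphere sensors per hemisphere.
#' @param sample_rate Hz.
#' @param duration resting block length in seconds.
#' @param stim_frequencies cyclic DBS frequencies in Hz.
#' @param on_duration,off_duration,pulse_amplitude cycle parameters.
#' @param beta_center_freq,beta_bandwidth beta oscillator center/width (Hz).
#' @param beta_amplitude named vector `c(left=, right=)` of beta RMS
#'   amplitudes (arbitrary units).
#' @param noise_exponent 1/f slope of the aperiodic background.
#' @param noise_amplitude background RMS amplitude.
#' @param aftereffect_gain A, dimensionless after-effect gain (>= 0).
#' @param aftereffect_tau after-effect decay time constant in seconds (> 0).
#' @param gain_sd between-subject SD of the after-effect gain.
#' @param on_gain left-ROI beta gain during the ON phase (rises with time
#'   constant `aftereffect_tau` from train onset); 0 keeps the response
#'   strictly post-offset. Used for tapping-session simulations.
#' @param response_mode `"induced"`, `"entrainment"` or `"none"`.
#' @param artifact_amplitude pulse impulse amplitude on the wire channels.
#' @param artifact_topography optional named weight vector overriding the
#'   default wire-path projection.
#' @param evoked_amplitude amplitude of the pulse-evoked field on the left
#'   sensorimotor channels.
#' @param evoked_latency evoked-field peak latency in seconds (within the
#'   5-30 ms window the ROI criterion inspects).
#' @param tap_rate_base mean tap rate in taps/min during tapping.
#' @param tap_rate_sd between-subject SD of the base tap rate.
#' @param li_tap_coupling tap-rate reduction (taps/min) per unit LI.
#' @param tap_shape gamma shape of inter-tap intervals (4 = more regular
#'   than Poisson, as real tapping is; 1 = exponential/Poisson).
#' @param li_baseline_sd between-subject SD of the baseline beta LI.
#' @param n_tap_blocks tapping blocks per session.
#' @param red_duration,green_duration cue durations in seconds.
#' @param seed master seed; all per-subject/condition streams derive from
#'   it deterministically.
#' @return a named list with class `simulation_config`.
#' @export
simulation_config <- function(n_subjects = 14,
                              n_channels_per_hemisphere = 12,
                              sample_rate = 1000,
                              duration = 480,
                              stim_frequencies = c(10, 16, 20, 26, 30),
                              on_duration = 5, off_duration = 3,
                              pulse_amplitude = 3,
                              beta_center_freq = 15,
                              beta_bandwidth = 4,
                              beta_amplitude = c(left = 1, right = 1),
                              noise_exponent = 1.5,
                              noise_amplitude = 4.5,
                              aftereffect_gain = 0.6,
                              aftereffect_tau = 0.15,
                              gain_sd = 0.35,
                              on_gain = 0,
                              response_mode = c("induced", "entrainment",
                                                "none"),
                              artifact_amplitude = 75,
                              artifact_topography = NULL,
                              evoked_amplitude = 10,
                              evoked_latency = 0.006,
                              tap_rate_base = 120,
                              tap_rate_sd = 15,
                              li_tap_coupling = 20,
                              tap_shape = 4,
                              li_baseline_sd = 0.1,
                              n_tap_blocks = 7,
                              red_duration = 10,
                              green_duration = 15,
                              seed = 1L) {
  response_mode <- match.arg(response_mode)
  stopifnot(aftereffect_gain >= 0, aftereffect_tau > 0,
            all(beta_amplitude >= 0), noise_amplitude >= 0,
            artifact_amplitude >= 0, evoked_amplitude >= 0, tap_shape > 0)
  cfg <- as.list(environment())
  structure(cfg, class = c("simulation_config", "list"))
}

# 1/f^exponent background noise, unit SD; spectrum flattened below 0.5 Hz.
# Drawn directly in the frequency domain (Hermitian-symmetric Gaussian
# coefficients shaped by the target amplitude spectrum), one inverse FFT.
one_over_f_noise <- function(n, fs, exponent) {
  nf <- fast_fft_length(n)
  nh <- nf %/% 2L                     # nf is even for fast lengths
  fpos <- (1:nh) * fs / nf
  H <- pmax(fpos, 0.5)^(-exponent / 2)
  z <- complex(real = stats::rnorm(nh), imaginary = stats::rnorm(nh)) * H
  z[nh] <- complex(real = sqrt(2) * Re(z[nh]), imaginary = 0)  # Nyquist
  X <- c(0i, z, Conj(rev(z[-nh])))
  y <- Re(stats::fft(X, inverse = TRUE))[seq_len(n)]
  y / stats::sd(y)
}

# band-limited Gaussian oscillation, unit SD: white noise through a
# 4th-order Butterworth band-pass applied forward and backward (zero
# phase). The filter's zero-phase magnitude response |H|^2 is applied in
# the frequency domain, which for stationary Gaussian noise is the exact
# spectral equivalent of signal::filtfilt and needs a single inverse FFT.
narrowband_source <- function(n, fs, center, bandwidth) {
  lo <- max(center - bandwidth / 2, 0.5)
  hi <- min(center + bandwidth / 2, fs / 2 * 0.95)
  bf <- signal::butter(4, c(lo, hi) / (fs / 2), type = "pass")
  nf <- fast_fft_length(n)
  nh <- nf %/% 2L
  w <- 2 * pi * (1:nh) / nf                 # digital radian frequencies
  ew <- exp(-1i * w)
  horner <- function(coef) {                # evaluate at e^{-i w}, vectorized
    p <- rep(0i, length(ew))
    for (cj in rev(coef)) p <- p * ew + cj
    p
  }
  H2 <- Mod(horner(bf$b) / horner(bf$a))^2
  z <- complex(real = stats::rnorm(nh), imaginary = stats::rnorm(nh)) * H2
  z[nh] <- complex(real = sqrt(2) * Re(z[nh]), imaginary = 0)
  X <- c(0i, z, Conj(rev(z[-nh])))
  y <- Re(stats::fft(X, inverse = TRUE))[seq_len(n)]
  y / stats::sd(y)
}

# sample index range for a [a, b) time window (1-based, clipped)
window_idx <- function(a, b, fs, n) {
  i0 <- max(1L, floor(a * fs + 1e-9) + 1L)
  i1 <- min(n, ceiling(b * fs - 1e-9))
  if (i1 < i0) integer(0) else i0:i1
}

# multiplicative left-ROI beta gain envelope over the whole recording
response_gain_envelope <- function(n, fs, schedule, gain, tau, on_gain) {
  g <- rep(1, n)
  if (is.null(schedule)) return(g)
  ons <- schedule$train_onsets
  offs <- schedule$train_offsets
  dur <- n / fs
  for (i in seq_along(ons)) {
    if (on_gain > 0) {
      idx <- window_idx(ons[i], offs[i], fs, n)
      g[idx] <- 1 + on_gain * (1 - exp(-((idx - 1) / fs - ons[i]) / tau))
    }
    if (gain > 0) {
      pause_end <- if (i < length(ons)) ons[i + 1] else dur
      idx <- window_idx(offs[i], pause_end, fs, n)
      g[idx] <- 1 + gain * exp(-((idx - 1) / fs - offs[i]) / tau)
    }
  }
  g
}

# additive phase-locked decaying sinusoid at the stimulation frequency,
# phase-continuous with the final pulse of each train
entrainment_term <- function(n, fs, schedule, gain, tau) {
  e <- numeric(n)
  if (is.null(schedule) || gain <= 0) return(e)
  f <- schedule$stim_frequency
  ons <- schedule$train_onsets
  offs <- schedule$train_offsets
  dur <- n / fs
  for (i in seq_along(offs)) {
    pause_end <- if (i < length(ons)) ons[i + 1] else dur
    idx <- window_idx(offs[i], pause_end, fs, n)
    dt <- (idx - 1) / fs - offs[i]
    e[idx] <- gain * exp(-dt / tau) * sin(2 * pi * f * dt)
  }
  e
}

# pulse-evoked field kernel: gamma-shaped bump peaking near `latency` s,
# smoothly faded to zero by 3 x latency (cortical DBS-evoked responses are
# over within ~20 ms, so the tapered after-effect segment stays clean)
evoked_kernel <- function(fs, latency) {
  T3 <- 3 * latency
  tt <- seq(0, T3, by = 1 / fs)
  (tt / latency) * exp(1 - tt / latency) * 0.5 * (1 + cos(pi * tt / T3))
}

#' Simulate one resting or stimulation recording
#'
#' Generates a `raw_recording` for one subject and condition according to
#' the signal model described in [simulation_config()]. Identical seeds
#' yield bit-identical recordings.
#'
#' @param config a `simulation_config`.
#' @param subject_index integer subject id (seeds the subject stream).
#' @param stim_frequency stimulation frequency in Hz, or NA for a baseline
#'   (DBS OFF) recording.
#' @param gain after-effect gain for this subject (default: cohort-level
#'   `aftereffect_gain`).
#' @param beta_amplitude per-hemisphere beta amplitudes for this subject.
#' @param on_gain ON-phase gain override (default from config).
#' @param duration recording length override in seconds.
#' @return a `raw_recording` with a `ground_truth` ledger (injected gain,
#'   schedule, true evoked/artifact channel sets, mode, seed).
#' @export
simulate_subject <- function(config, subject_index,
                             stim_frequency = config$stim_frequencies[1],
                             gain = config$aftereffect_gain,
                             beta_amplitude = config$beta_amplitude,
                             on_gain = config$on_gain,
                             duration = config$duration) {
  mode <- config$response_mode
  if (mode == "entrainment" && (is.null(stim_frequency) ||
                                is.na(stim_frequency)))
    stop("response_mode = \"entrainment\" requires a stimulation frequency")
  fs <- config$sample_rate
  cond_code <- if (is.na(stim_frequency)) 0 else stim_frequency
  seed_i <- derive_seed(config$seed, subject_index, cond_code,
                        round(duration))
  layout <- make_grid_layout(config$n_channels_per_hemisphere)
  ids <- layout$channel_ids
  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs
  schedule <- if (is.na(stim_frequency)) NULL else
    make_schedule(duration, stim_frequency, on = config$on_duration,
                  off = config$off_duration,
                  pulse_amplitude = config$pulse_amplitude)

  data <- with_seed(seed_i, {
    X <- matrix(0, nrow = length(ids), ncol = n, dimnames = list(ids, NULL))
    for (i in seq_along(ids))
      X[i, ] <- config$noise_amplitude *
        one_over_f_noise(n, fs, config$noise_exponent)
    beta_l <- narrowband_source(n, fs, config$beta_center_freq,
                                config$beta_bandwidth)
    beta_r <- narrowband_source(n, fs, config$beta_center_freq,
                                config$beta_bandwidth)
    left <- names(layout$hemisphere)[layout$hemisphere == "left"]
    right <- names(layout$hemisphere)[layout$hemisphere == "right"]
    roi <- layout$groups$roi_left
    amp_l <- unname(beta_amplitude["left"])
    amp_r <- unname(beta_amplitude["right"])
    g <- response_gain_envelope(n, fs, schedule,
                                if (mode == "induced") gain else 0,
                                config$aftereffect_tau, on_gain)
    for (ch in left) {
      src <- if (ch %in% roi) beta_l * g else beta_l
      X[ch, ] <- X[ch, ] + amp_l * src
    }
    if (mode == "entrainment") {
      e <- entrainment_term(n, fs, schedule, gain, config$aftereffect_tau)
      for (ch in roi) X[ch, ] <- X[ch, ] + amp_l * e
    }
    for (ch in right) X[ch, ] <- X[ch, ] + amp_r * beta_r
    if (!is.null(schedule) && config$artifact_amplitude > 0) {
      pidx <- round(pulse_times(schedule) * fs) + 1L
      pidx <- pidx[pidx >= 1 & pidx <= n - 1]
      pulse_sig <- numeric(n)
      pulse_sig[pidx] <- 1
      pulse_sig[pidx + 1L] <- -1           # 1-sample biphasic impulse
      w <- config$artifact_topography
      if (is.null(w)) {
        wire <- layout$groups$wire_right
        w <- stats::setNames(0.6^(seq_along(wire) - 1), wire)
      }
      for (ch in names(w))
        X[ch, ] <- X[ch, ] + config$artifact_amplitude * w[ch] * pulse_sig
      if (config$evoked_amplitude > 0) {
        ker <- config$evoked_amplitude * evoked_kernel(fs,
                                                      config$evoked_latency)
        ev <- numeric(n)
        for (j in seq_along(ker)) {     # sparse pulse-train convolution
          tgt <- pidx + j - 1L
          tgt <- tgt[tgt <= n]
          ev[tgt] <- ev[tgt] + ker[j]
        }
        for (ch in roi) X[ch, ] <- X[ch, ] + ev
      }
    }
    X
  })

  events <- if (is.null(schedule)) event_table() else
    events_from_schedule(schedule)
  gt <- list(subject = subject_index,
             stim_frequency = if (is.na(stim_frequency)) NA else
               stim_frequency,
             response_mode = mode,
             aftereffect_gain = gain,
             aftereffect_tau = config$aftereffect_tau,
             on_gain = on_gain,
             beta_amplitude = as.list(beta_amplitude),
             train_offsets = if (is.null(schedule)) numeric(0) else
               schedule$train_offsets,
             roi_true = layout$groups$roi_left,
             wire_channels = layout$groups$wire_right,
             seed = seed_i)
  raw_recording(data, fs, layout, events, ground_truth = gt)
}

# red/green cue windows of the tapping task, as [start, end) matrices
tapping_cue_windows <- function(config) {
  period <- config$red_duration + config$green_duration
  starts <- (seq_len(config$n_tap_blocks) - 1) * period
  list(red = cbind(starts, starts + config$red_duration),
       green = cbind(starts + config$red_duration, starts + period),
       duration = config$n_tap_blocks * period)
}

# draw a gamma-renewal tap process on [a, b) at `rate` taps/min
draw_taps <- function(a, b, rate, shape) {
  if (rate <= 0) return(numeric(0))
  r_s <- rate / 60
  expected <- (b - a) * r_s
  taps <- numeric(0)
  tcur <- a
  repeat {
    nblk <- ceiling(expected + 6 * sqrt(expected + 1)) + 4
    iv <- stats::rgamma(nblk, shape = shape, rate = shape * r_s)
    tt <- tcur + cumsum(iv)
    taps <- c(taps, tt[tt < b])
    if (tt[nblk] >= b) break
    tcur <- tt[nblk]
  }
  taps
}

#' Simulate finger-tap events for one tapping session
#'
#' The task alternates `n_tap_blocks` blocks of a red fixation cross
#' (withhold) and a green fixation cross (tap as fast as possible). Tap
#' events occur only inside green windows and are drawn from a gamma
#' renewal process whose rate is negatively coupled to the current
#' lateralization index:
#' `rate = base_rate - li_tap_coupling * LI(state)`, with the ON-state LI
#' elevated by the subject's injected stimulation effect. Negative rates
#' are clipped to zero and flagged.
#'
#' @param schedule a `stim_schedule` for the session, or NULL for a
#'   baseline tapping block (all time counts as OFF).
#' @param config a `simulation_config`.
#' @param subject_li list with elements `on` and `off` (the subject's true
#'   beta LI in each stimulation state), or a single number for both.
#' @param base_rate subject base tap rate in taps/min.
#' @param seed RNG seed for the tap stream.
#' @return an `event_table` of cue and tap events; the per-segment true
#'   rates are attached as `attr(, "ground_truth")` and rate clipping as
#'   `attr(, "clipped")`.
#' @export
simulate_tapping <- function(schedule, config, subject_li,
                             base_rate = config$tap_rate_base,
                             seed = config$seed) {
  if (!is.list(subject_li))
    subject_li <- list(on = subject_li, off = subject_li)
  cues <- tapping_cue_windows(config)
  on_windows <- if (is.null(schedule))
    matrix(numeric(0), ncol = 2)
  else cbind(schedule$train_onsets, schedule$train_offsets)
  segs <- list()
  for (gi in seq_len(nrow(cues$green))) {
    gw <- cues$green[gi, , drop = FALSE]
    on_in <- intersect_windows(gw, on_windows)
    off_in <- if (nrow(on_in) == 0) gw else {
      # complement of ON within the green window
      brk <- sort(unique(c(gw[1], t(on_in), gw[2])))
      cand <- cbind(utils::head(brk, -1), utils::tail(brk, -1))
      keep <- apply(cand, 1, function(w)
        nrow(intersect_windows(matrix(w, ncol = 2), on_in)) == 0)
      cand[keep & cand[, 2] > cand[, 1], , drop = FALSE]
    }
    if (nrow(on_in) > 0)
      segs <- c(segs, lapply(seq_len(nrow(on_in)), function(i)
        c(on_in[i, ], 1)))
    if (length(off_in) > 0 && nrow(off_in) > 0)
      segs <- c(segs, lapply(seq_len(nrow(off_in)), function(i)
        c(off_in[i, ], 0)))
  }
  segs <- do.call(rbind, segs)
  segs <- segs[order(segs[, 1]), , drop = FALSE]
  li_seg <- ifelse(segs[, 3] == 1, subject_li$on, subject_li$off)
  rate_seg <- base_rate - config$li_tap_coupling * li_seg
  clipped <- any(rate_seg < 0)
  rate_seg <- pmax(rate_seg, 0)
  taps <- with_seed(seed, {
    unlist(lapply(seq_len(nrow(segs)), function(i)
      draw_taps(segs[i, 1], segs[i, 2], rate_seg[i], config$tap_shape)))
  })
  counts <- vapply(seq_len(nrow(segs)), function(i)
    sum(taps >= segs[i, 1] & taps < segs[i, 2]), numeric(1))
  ev <- event_table(
    onset = c(cues$red[, 1], cues$green[, 1], sort(taps)),
    duration = c(rep(config$red_duration, nrow(cues$red)),
                 rep(config$green_duration, nrow(cues$green)),
                 rep(0, length(taps))),
    event_type = c(rep("cue_red", nrow(cues$red)),
                   rep("cue_green", nrow(cues$green)),
                   rep("tap", length(taps))),
    condition = if (is.null(schedule) || is.na(schedule$stim_frequency))
      "baseline" else as.character(schedule$stim_frequency))
  ev <- ev[order(ev$onset), , drop = FALSE]
  rownames(ev) <- NULL
  attr(ev, "ground_truth") <- data.frame(
    start = segs[, 1], end = segs[, 2],
    state = ifelse(segs[, 3] == 1, "on", "off"),
    true_rate = rate_seg, tap_count = counts)
  attr(ev, "clipped") <- clipped
  ev
}

#' Draw per-subject simulation parameters for a cohort
#'
#' Subjects vary in after-effect gain (`aftereffect_gain` +/- `gain_sd`,
#' truncated at 0), baseline hemispheric beta asymmetry (baseline LI
#' ~ N(0, `li_baseline_sd`), mapped to per-hemisphere amplitudes at
#' constant total power) and base tap rate.
#'
#' @param config a `simulation_config`.
#' @return data.frame with one row per subject: gain, baseline LI,
#'   per-hemisphere amplitudes, base tap rate, and the true tapping-state
#'   LIs implied by gain and asymmetry.
#' @export
cohort_parameters <- function(config) {
  with_seed(derive_seed(config$seed, 999983), {
    n <- config$n_subjects
    gain <- pmax(0, stats::rnorm(n, config$aftereffect_gain,
                                 config$gain_sd))
    li0 <- stats::rnorm(n, 0, config$li_baseline_sd)
    li0 <- pmin(pmax(li0, -0.9), 0.9)
    amp_l <- sqrt(1 + li0)
    amp_r <- sqrt(1 - li0)
    base_rate <- stats::rnorm(n, config$tap_rate_base, config$tap_rate_sd)
    p_on <- amp_l^2 * (1 + gain)^2
    li_on <- (p_on - amp_r^2) / (p_on + amp_r^2)
    data.frame(subject = seq_len(n), gain = gain, baseline_li = li0,
               amp_left = amp_l, amp_right = amp_r,
               base_rate = base_rate, li_off = li0, li_on = li_on)
  })
}

#' Simulate a full cohort
#'
#' For every subject, draws individual parameters ([cohort_parameters()])
#' and generates a baseline resting recording plus, per stimulation
#' condition, a resting recording and (optionally) a tapping session
#' (MEG recording with tap/cue events merged into its event table). All
#' seeds derive deterministically from the master seed. For cohort-scale
#' Monte Carlo a `callback(subject, condition, session)` can be supplied;
#' sessions are then processed one at a time and not accumulated in
#' memory.
#'
#' @param config a `simulation_config` (`n_subjects >= 2`).
#' @param conditions stimulation frequencies to simulate.
#' @param rest,tapping which session types to generate.
#' @param tapping_duration tapping block length in seconds (default: the
#'   task length implied by the cue structure).
#' @param callback optional streaming consumer; when given, the returned
#'   `subjects` list contains the callback's return values instead of the
#'   sessions.
#' @return list with `parameters` (the ground-truth cohort table) and
#'   `subjects` (per subject: named list of sessions; each stimulation
#'   condition has `rest` and/or `tapping` entries, plus a baseline
#'   `rest`).
#' @export
simulate_cohort <- function(config, conditions = config$stim_frequencies,
                            rest = TRUE, tapping = FALSE,
                            tapping_duration = NULL, callback = NULL) {
  stopifnot(config$n_subjects >= 2)
  pars <- cohort_parameters(config)
  tdur <- tapping_duration %||% tapping_cue_windows(config)$duration
  subjects <- vector("list", config$n_subjects)
  for (s in seq_len(config$n_subjects)) {
    p <- pars[s, ]
    amp <- c(left = p$amp_left, right = p$amp_right)
    sess <- list()
    if (rest) {
      sess$baseline <- list(
        rest = simulate_subject(config, s, stim_frequency = NA,
                                gain = 0, beta_amplitude = amp))
      if (!is.null(callback)) {
        sess$baseline <- callback(s, "baseline", sess$baseline)
      }
    }
    for (f in conditions) {
      one <- list()
      if (rest)
        one$rest <- simulate_subject(config, s, stim_frequency = f,
                                     gain = p$gain, beta_amplitude = amp)
      if (tapping) {
        sched <- make_schedule(tdur, f, on = config$on_duration,
                               off = config$off_duration)
        raw <- simulate_subject(config, s, stim_frequency = f,
                                gain = p$gain, beta_amplitude = amp,
                                on_gain = p$gain, duration = tdur)
        tev <- simulate_tapping(sched, config,
                                list(on = p$li_on, off = p$li_off),
                                base_rate = p$base_rate,
                                seed = derive_seed(config$seed, s, f, 7))
        raw$events <- rbind(raw$events, tev)
        raw$events <- raw$events[order(raw$events$onset), , drop = FALSE]
        one$tapping <- list(raw = raw, schedule = sched,
                            tap_truth = attr(tev, "ground_truth"))
      }
      key <- as.character(f)
      if (!is.null(callback)) {
        sess[[key]] <- callback(s, f, one)
      } else sess[[key]] <- one
    }
    subjects[[s]] <- sess
  }
  list(parameters = pars, subjects = subjects, config = config)
}
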