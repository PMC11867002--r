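# --- reusable analysis stages ----------------------------------------------

#' Green-cue (tapping) windows from an event table
#'
#' @param events an `event_table` with `cue_green` rows.
#' @return `[start, end)` matrix in seconds.
#' @export
green_windows_from_events <- function(events) {
  g <- events[events$event_type == "cue_green", , drop = FALSE]
  cbind(g$onset, g$onset + g$duration)
}

#' Wrap a continuous recording as a single-trial epoch set
#'
#' @param raw a `raw_recording`.
#' @return an `epoch_set` with one trial spanning the whole record.
#' @export
as_continuous_epochs <- function(raw) {
  n <- ncol(raw$data)
  epoch_set(array(raw$data, dim = c(1, nrow(raw$data), n)),
            times = (seq_len(n) - 1) / raw$sample_rate,
            sample_rate = raw$sample_rate, alignment = "consecutive",
            condition = if (nrow(raw$events) > 0) raw$events$condition[1]
            else "baseline",
            layout = raw$layout)
}

#' After-effect lateralization profile of one resting recording
#'
#' Runs the resting-state after-effect chain on a single recording:
#' offset-aligned (stimulation) or consecutive (baseline) epoching,
#' amplitude-based trial rejection, short-segment spectra and the
#' ROI-based LI profile.
#'
#' @param raw a `raw_recording`.
#' @param cfg a [run_config()].
#' @param roi left ROI channel ids; mandatory for baseline recordings
#'   (which have no evoked fields to select from), selected via
#'   [select_roi()] when NULL.
#' @return an `li_profile`; the ROI used is attached.
#' @export
rest_li_profile <- function(raw, cfg = run_config(), roi = NULL) {
  sched <- schedule_from_events(raw$events)
  if (is.null(sched)) {
    if (is.null(roi)) stop("baseline recordings need an externally",
                           " selected ROI")
    ep <- make_consecutive_epochs(raw, cfg$baseline_epoch_length)
  } else {
    offs <- detect_train_offsets(raw, "events")
    ep <- make_offset_epochs(raw, offs, cfg$epoch_half_width)
  }
  ep <- reject_artifacts(ep, cfg$reject_z)
  if (is.null(roi))
    roi <- select_roi(ep, raw$layout, sched$stim_frequency, cfg$roi_z)
  sp <- segment_spectrum(ep, cfg$segment_window)
  prof <- aftereffect_li(sp, raw$layout, roi)
  prof$condition <- ep$condition
  prof
}

#' Session-averaged normalized LI for a simulated cohort
#'
#' For every subject, simulates the baseline resting block and one resting
#' block per requested stimulation condition, selects the subject's ROI
#' from the first condition's evoked fields, computes the after-effect LI
#' profile per condition and the baseline profile, and returns the
#' baseline-normalized LI. Sessions are processed one at a time, so cohort
#' memory stays at a single recording.
#'
#' @param config a `simulation_config`.
#' @param conditions stimulation frequencies to simulate.
#' @param cfg a [run_config()].
#' @param average average the normalized LI over conditions (the
#'   per-frequency group test operates on session-averaged profiles).
#' @return list with `nli` (subjects x bins, session-averaged),
#'   `per_condition` (subjects x conditions x bins), `freqs`, `rois`,
#'   `parameters`.
#' @export
cohort_aftereffect_li <- function(config,
                                  conditions = config$stim_frequencies,
                                  cfg = run_config(), average = TRUE) {
  pars <- cohort_parameters(config)
  nb <- NULL
  per_cond <- NULL
  rois <- vector("list", config$n_subjects)
  for (s in seq_len(config$n_subjects)) {
    p <- pars[s, ]
    amp <- c(left = p$amp_left, right = p$amp_right)
    roi <- NULL
    profs <- list()
    for (f in conditions) {
      raw <- simulate_subject(config, s, stim_frequency = f,
                              gain = p$gain, beta_amplitude = amp)
      prof <- rest_li_profile(raw, cfg, roi = roi)
      roi <- prof$roi_left
      profs[[as.character(f)]] <- prof
    }
    raw0 <- simulate_subject(config, s, stim_frequency = NA, gain = 0,
                             beta_amplitude = amp)
    base <- rest_li_profile(raw0, cfg, roi = roi)
    if (is.null(per_cond)) {
      nb <- length(base$freqs)
      per_cond <- array(NA_real_, dim = c(config$n_subjects,
                                          length(conditions), nb))
    }
    for (ci in seq_along(conditions)) {
      nl <- normalized_li(profs[[ci]], base)
      per_cond[s, ci, ] <- nl$normalized_li
    }
    rois[[s]] <- roi
  }
  nli <- if (average) apply(per_cond, c(1, 3), mean) else per_cond
  list(nli = nli, per_condition = per_cond,
       freqs = seq_len(nb) / diff(cfg$segment_window),
       rois = rois, parameters = pars)
}

#' After-effect persistence from the ROI beta power time course
#'
#' Baseline-corrects the ROI- and band-averaged power by its quiescent
#' level, smooths it with a short moving average and returns the first
#' post-offset down-crossing of `threshold_sd` times the quiescent SD --
#' an estimate of how long the power boost outlasts the stimulation
#' train. The mean and SD reference is the *late* part of the pause,
#' where the response has fully decayed (several time constants after the
#' offset); using the full pause would fold the response's own decay into
#' the noise floor and bias the crossing early.
#'
#' @param tfr a `tfr` of offset-aligned epochs.
#' @param roi channel ids to average.
#' @param band frequency band in Hz.
#' @param noise_window quiescent reference window in seconds.
#' @param threshold_sd persistence threshold in quiescent SDs.
#' @param smooth_s moving-average length in seconds.
#' @return persistence in seconds (NA when never above threshold).
#' @export
aftereffect_persistence <- function(tfr, roi, band = c(13, 18),
                                    noise_window = c(1, 2.845),
                                    threshold_sd = 2, smooth_s = 0.05) {
  ci <- match(roi, tfr$channel_ids)
  fsel <- tfr$freqs >= band[1] & tfr$freqs <= band[2]
  tc <- apply(tfr$power[ci, fsel, , drop = FALSE], 3, mean)
  k <- max(1, round(smooth_s * tfr$sample_rate))
  tc <- stats::filter(tc, rep(1 / k, k), sides = 2)
  pause <- tfr$times >= noise_window[1] & tfr$times < noise_window[2] &
    tfr$valid & !is.na(tc)
  mu <- mean(tc[pause])
  sdv <- stats::sd(tc[pause])
  excess <- tc - mu
  post <- which(tfr$times > 0 & !is.na(excess))
  above <- excess[post] > threshold_sd * sdv
  if (!above[1]) return(NA_real_)
  first_below <- which(!above)[1]
  if (is.na(first_below)) return(max(tfr$times[post]))
  tfr$times[post[first_below]]
}

#' Analyze one simulated tapping session
#'
#' Band-limited TFR of the continuous tapping recording, tapping LI per
#' stimulation state, and tap rates per state.
#'
#' @param raw the session `raw_recording` (tap/cue events in its table).
#' @param schedule the session `stim_schedule`.
#' @param roi left ROI channel ids.
#' @param cfg a [run_config()].
#' @return list with `li` (data.frame state/li), `rates` (data.frame from
#'   [tap_rates()]).
#' @export
tapping_session_analysis <- function(raw, schedule, roi,
                                     cfg = run_config()) {
  green <- green_windows_from_events(raw$events)
  band <- cfg$tapping_band
  roi_right <- unname(raw$layout$mirror_map[roi])
  tfr <- morlet_tfr(as_continuous_epochs(raw),
                    freqs = seq(band[1], band[2]),
                    wavelet_length = cfg$wavelet_length_power,
                    channels = c(roi, roi_right), compute_itc = FALSE)
  li <- tapping_li(tfr, schedule, green, raw$layout, roi,
                   band = band, on_lag = cfg$tapping_on_lag)
  rates <- tap_rates(raw$events, schedule, green)
  list(li = li, rates = rates)
}

# --- orchestration ----------------------------------------------------------

write_csv_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run the complete simulated-cohort analysis
#'
#' Orchestrates simulate -> epoch -> spectral -> lateralization -> stats
#' end to end on a synthetic cohort: per-subject normalized after-effect
#' LI profiles, the per-frequency tmax group test, cluster-level
#' paired tests of the post-offset windows against the pause mean (with
#' BH-FDR over the window x condition family), the LME for normalized LI
#' by DBS frequency, tapping statistics (rates, Poisson mixed model,
#' tapping LI) and the cross-subject correlation between DBS-induced LI
#' shift and tap-rate change. Writes result tables as CSV, a markdown
#' report and a JSON manifest into `out_dir`; a rerun with an unchanged
#' configuration reuses the manifest and performs no recomputation.
#'
#' @param config a `simulation_config`.
#' @param cfg a [run_config()].
#' @param out_dir output directory.
#' @param conditions resting-state stimulation conditions to analyze.
#' @param tapping_conditions conditions with a tapping session (the
#'   condition matching `cfg$tapping_exclude_frequency` is dropped from
#'   the tapping LI analysis).
#' @param cluster_conditions conditions entering the cluster test (kept
#'   small by default: the test transforms every channel).
#' @return list of result tables (`li_table`, `tmax`, `clusters`, `lme`,
#'   `tap_table`, `glmm`, `correlation`, `manifest`), invisibly.
#' @export
run_all <- function(config, cfg = run_config(), out_dir = tempdir(),
                    conditions = config$stim_frequencies,
                    tapping_conditions = conditions,
                    cluster_conditions = conditions[1]) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_path <- file.path(out_dir, "config.json")
  write_run_config(c(unclass(config),
                     unclass(cfg),
                     list(.conditions = conditions,
                          .tapping_conditions = tapping_conditions,
                          .cluster_conditions = cluster_conditions)),
                   cfg_path)
  cfg_hash <- unname(tools::md5sum(cfg_path))
  man_path <- file.path(out_dir, "manifest.json")
  if (file.exists(man_path)) {
    man <- jsonlite::read_json(man_path, simplifyVector = TRUE)
    if (identical(man$config_hash, cfg_hash) &&
        all(file.exists(file.path(out_dir, unlist(man$outputs))))) {
      message("configuration unchanged; reusing cached outputs")
      tabs <- lapply(man$outputs, function(p)
        utils::read.csv(file.path(out_dir, p)))
      tabs$manifest <- man
      return(invisible(tabs))
    }
  }
  t0 <- Sys.time()

  co <- cohort_aftereffect_li(config, conditions, cfg)
  li_table <- do.call(rbind, lapply(seq_len(config$n_subjects), function(s)
    do.call(rbind, lapply(seq_along(conditions), function(ci)
      data.frame(subject = s, condition = conditions[ci],
                 freq_bin_hz = co$freqs,
                 normalized_li = co$per_condition[s, ci, ])))))
  tm <- tmax_perm_onesample(co$nli, cfg$max_exhaustive_perm, cfg$n_perm,
                            seed = derive_seed(cfg$seed, 11))
  tmax_table <- data.frame(freq_bin_hz = co$freqs, t = tm$t,
                           p_adjusted = tm$p_adjusted,
                           significant = tm$p_adjusted <= cfg$alpha)

  # cluster tests: per-subject sensor maps of window mean vs pause mean
  cl_rows <- list()
  for (f in cluster_conditions) {
    maps <- cluster_window_maps(config, f, cfg)
    for (w in names(cfg$cluster_windows)) {
      ct <- cluster_perm_paired(maps$window[[w]], maps$pause,
                                maps$adjacency,
                                alpha_cluster = cfg$cluster_alpha,
                                max_exhaustive = cfg$max_exhaustive_perm,
                                n_perm = cfg$n_perm,
                                seed = derive_seed(cfg$seed, 13, f))
      if (length(ct$clusters) > 0) {
        cl_rows[[length(cl_rows) + 1]] <- data.frame(
          condition = f, window = w,
          cluster = seq_along(ct$clusters),
          n_channels = lengths(ct$clusters),
          channels = vapply(ct$clusters, function(ix)
            paste(ct$channel_ids[ix], collapse = "|"), character(1)),
          mass = ct$mass, p = ct$p_value)
      } else {
        cl_rows[[length(cl_rows) + 1]] <- data.frame(
          condition = f, window = w, cluster = NA_integer_,
          n_channels = 0L, channels = "", mass = NA_real_, p = NA_real_)
      }
    }
  }
  cluster_table <- do.call(rbind, cl_rows)
  have_p <- !is.na(cluster_table$p)
  cluster_table$fdr_significant <- FALSE
  if (any(have_p))
    cluster_table$fdr_significant[have_p] <-
      fdr_bh(cluster_table$p[have_p], cfg$alpha)$reject

  lme_table <- data.frame(participant = li_table$subject,
                          dbs_frequency = li_table$condition,
                          normalized_li = li_table$normalized_li)
  beta_bins <- co$freqs >= 12 & co$freqs <= 26
  lme_in <- stats::aggregate(
    normalized_li ~ participant + dbs_frequency,
    data = lme_table[rep(beta_bins, length.out = nrow(lme_table)), ],
    FUN = mean)
  lme_res <- if (length(conditions) >= 2) lme_li_frequency(lme_in) else NULL

  # tapping
  tap_rows <- list()
  li_rows <- list()
  pars <- co$parameters
  for (s in seq_len(config$n_subjects)) {
    p <- pars[s, ]
    amp <- c(left = p$amp_left, right = p$amp_right)
    for (f in tapping_conditions) {
      tdur <- tapping_cue_windows(config)$duration
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
      ana <- tapping_session_analysis(raw, sched, co$rois[[s]], cfg)
      r <- ana$rates
      tap_rows[[length(tap_rows) + 1]] <- data.frame(
        participant = s, dbs_frequency = f, state = r$state,
        tap_count = r$tap_count, exposure_s = r$exposure_s, rate = r$rate)
      if (is.na(cfg$tapping_exclude_frequency) ||
          f != cfg$tapping_exclude_frequency)
        li_rows[[length(li_rows) + 1]] <- data.frame(
          participant = s, dbs_frequency = f, state = ana$li$state,
          li = ana$li$li)
    }
  }
  tap_table <- do.call(rbind, tap_rows)
  tli_table <- do.call(rbind, li_rows)
  glmm_res <- if (length(tapping_conditions) >= 1 &&
                  config$n_subjects >= 3) glmm_taprate(tap_table) else NULL

  # per-subject DBS-induced changes (session averages) and correlation
  delta <- merge(
    stats::aggregate(rate ~ participant,
                     data = tap_table[tap_table$state == "on", ], FUN = mean),
    stats::aggregate(rate ~ participant,
                     data = tap_table[tap_table$state == "off", ],
                     FUN = mean),
    by = "participant", suffixes = c("_on", "_off"))
  dli <- merge(
    stats::aggregate(li ~ participant,
                     data = tli_table[tli_table$state == "on", ],
                     FUN = mean),
    stats::aggregate(li ~ participant,
                     data = tli_table[tli_table$state == "off", ],
                     FUN = mean),
    by = "participant", suffixes = c("_on", "_off"))
  delta <- merge(delta, dli, by = "participant")
  delta$delta_rate <- delta$rate_on - delta$rate_off
  delta$delta_li <- delta$li_on - delta$li_off
  corr <- pearson_cor(delta$delta_li, delta$delta_rate)

  outputs <- list(li_table = "li_table.csv", tmax = "tmax.csv",
                  clusters = "clusters.csv", tap_table = "tap_table.csv",
                  delta = "delta.csv")
  write_csv_table(li_table, file.path(out_dir, outputs$li_table))
  write_csv_table(tmax_table, file.path(out_dir, outputs$tmax))
  write_csv_table(cluster_table, file.path(out_dir, outputs$clusters))
  write_csv_table(tap_table, file.path(out_dir, outputs$tap_table))
  write_csv_table(delta, file.path(out_dir, outputs$delta))

  manifest <- list(config_hash = cfg_hash, config_path = "config.json",
                   seed = config$seed,
                   outputs = outputs,
                   version = as.character(utils::packageVersion("cyclicdbs")),
                   started = format(t0), finished = format(Sys.time()))
  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, digits = NA)
  report <- c(
    "# Cyclic DBS after-effect analysis report", "",
    sprintf("- subjects: %d; conditions: %s", config$n_subjects,
            paste(conditions, collapse = ", ")),
    sprintf("- master seed: %d", config$seed), "",
    "## Normalized after-effect LI (tmax test)", "",
    paste(utils::capture.output(print(tmax_table)), collapse = "\n"), "",
    "## Cluster tests (window vs pause mean)", "",
    paste(utils::capture.output(print(cluster_table)), collapse = "\n"), "",
    if (!is.null(lme_res))
      sprintf("## LME: F(%g, %.2f) = %.3f, p = %.4f",
              lme_res$df1, lme_res$df2, lme_res$F, lme_res$p),
    if (!is.null(glmm_res))
      sprintf("## GLMM: ON/OFF rate ratio %.3f; DBS chisq(%d) = %.2f, p = %.4f",
              glmm_res$rate_ratio_on_off, glmm_res$tests$df[1],
              glmm_res$tests$chisq[1], glmm_res$tests$p[1]),
    sprintf("## Delta LI vs delta rate: r = %.3f, p = %.4f (n = %d)",
            corr$r, corr$p, corr$n))
  writeLines(report, file.path(out_dir, "report.md"))

  invisible(list(li_table = li_table, tmax = tmax_table,
                 clusters = cluster_table, lme = lme_res,
                 tap_table = tap_table, tapping_li = tli_table,
                 glmm = glmm_res, delta = delta, correlation = corr,
                 manifest = manifest))
}

#' Per-subject sensor maps for the cluster test
#'
#' Simulates one resting recording per subject for a condition and reduces
#' it to the paired sensor maps the cluster test compares: per channel,
#' the band-averaged power mean inside each post-offset window and inside
#' the stimulation pause.
#'
#' @param config a `simulation_config`.
#' @param stim_frequency condition in Hz.
#' @param cfg a [run_config()].
#' @return list with `window` (named list of subjects x channels
#'   matrices), `pause` (subjects x channels), `adjacency`.
#' @export
cluster_window_maps <- function(config, stim_frequency,
                                cfg = run_config()) {
  pars <- cohort_parameters(config)
  band <- cfg$cluster_band
  freqs <- seq(band[1], band[2], by = 1)
  win_maps <- lapply(cfg$cluster_windows, function(w) NULL)
  pause_map <- NULL
  adjacency <- NULL
  ch_ids <- NULL
  for (s in seq_len(config$n_subjects)) {
    p <- pars[s, ]
    raw <- simulate_subject(config, s, stim_frequency = stim_frequency,
                            gain = p$gain,
                            beta_amplitude = c(left = p$amp_left,
                                               right = p$amp_right))
    offs <- detect_train_offsets(raw, "events")
    ep <- reject_artifacts(make_offset_epochs(raw, offs,
                                              cfg$epoch_half_width),
                           cfg$reject_z)
    tfr <- morlet_tfr(ep, freqs = freqs,
                      wavelet_length = cfg$wavelet_length_aftereffect,
                      compute_itc = FALSE)
    bandpow <- apply(tfr$power, c(1, 3), mean)     # channels x time
    if (is.null(adjacency)) {
      adjacency <- raw$layout$adjacency
      ch_ids <- raw$layout$channel_ids
      win_maps <- lapply(cfg$cluster_windows, function(w)
        matrix(NA_real_, config$n_subjects, length(ch_ids),
               dimnames = list(NULL, ch_ids)))
      pause_map <- matrix(NA_real_, config$n_subjects, length(ch_ids),
                          dimnames = list(NULL, ch_ids))
    }
    psel <- tfr$times >= cfg$pause_window[1] &
      tfr$times < cfg$pause_window[2]
    pause_map[s, ] <- rowMeans(bandpow[, psel, drop = FALSE])
    for (w in names(cfg$cluster_windows)) {
      ws <- cfg$cluster_windows[[w]]
      sel <- tfr$times >= ws[1] & tfr$times < ws[2]
      win_maps[[w]][s, ] <- rowMeans(bandpow[, sel, drop = FALSE])
    }
  }
  list(window = win_maps, pause = pause_map, adjacency = adjacency)
}
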