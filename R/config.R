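#' Analysis run configuration
#'
#' Collects every tunable analysis parameter with defaults mirroring the
#' emulated study protocol: Morlet grid 5-60 Hz in 1 Hz steps with 500 ms
#' wavelets (300 ms for the after-effect spectra, shortened to keep
#' stimulation-period activity from leaking into the pause), +/-3.5 s
#' offset-aligned epochs, the 5-160 ms post-train segment window whose
#' 155 ms length fixes the 6.45 Hz after-effect frequency grid, the
#' T1-T3 cluster-test windows with the 0.155-2.845 s pause reference and
#' the 10-23 Hz cluster band, and the 14-18 Hz tapping band with the 16 Hz
#' condition excluded.
#'
#' @param freqs Morlet frequency grid in Hz.
#' @param wavelet_length_power wavelet length (s) for power/ITC spectra.
#' @param wavelet_length_aftereffect shorter wavelet length (s) for
#'   after-effect spectra.
#' @param epoch_half_width half-width (s) of offset-aligned epochs.
#' @param baseline_epoch_length length (s) of consecutive baseline epochs.
#' @param segment_window post-offset window (s) of the after-effect spectra.
#' @param pause_window stimulation-pause reference window (s).
#' @param cluster_windows named list of post-offset test windows (s).
#' @param cluster_band frequency band (Hz) for the cluster test.
#' @param tapping_band frequency band (Hz) for tapping lateralization.
#' @param tapping_exclude_frequency stimulation condition (Hz) excluded from
#'   tapping lateralization because its artifact falls inside the band.
#' @param tapping_on_lag seconds after train onset before ON-state samples
#'   enter the tapping analysis (skips filter/stimulator transients).
#' @param reject_z amplitude z-score threshold for trial rejection.
#' @param roi_z evoked-field z threshold of the ROI selection.
#' @param alpha significance level.
#' @param cluster_alpha cluster-forming (per-channel) alpha.
#' @param max_exhaustive_perm largest sign-flip count enumerated
#'   exhaustively; above it Monte Carlo permutations are used.
#' @param n_perm Monte Carlo permutation count.
#' @param seed master seed for every stochastic analysis step.
#' @return a named list with class `run_config`.
#' @export
run_config <- function(freqs = 5:60,
                       wavelet_length_power = 0.5,
                       wavelet_length_aftereffect = 0.3,
                       epoch_half_width = 3.5,
                       baseline_epoch_length = 7,
                       segment_window = c(0.005, 0.160),
                       pause_window = c(0.155, 2.845),
                       cluster_windows = list(T1 = c(0.155, 0.310),
                                              T2 = c(0.310, 0.465),
                                              T3 = c(0.465, 0.620)),
                       cluster_band = c(10, 23),
                       tapping_band = c(14, 18),
                       tapping_exclude_frequency = 16,
                       tapping_on_lag = 0.5,
                       reject_z = 6,
                       roi_z = 4,
                       alpha = 0.05,
                       cluster_alpha = 0.05,
                       max_exhaustive_perm = 16384,
                       n_perm = 4096,
                       seed = 1L) {
  cfg <- as.list(environment())
  for (w in c(list(cfg$segment_window, cfg$pause_window),
              cfg$cluster_windows)) {
    if (w[1] >= w[2]) stop("every window must satisfy start < end")
  }
  structure(cfg, class = c("run_config", "list"))
}
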