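# Shared fixtures: small, fast simulation configurations. Sample rate 200 Hz
# keeps the 155 ms after-effect segment at an integer 31 samples; durations
# are chosen per test (48 s = 6 stimulation trains).

quick_config <- function(duration = 48, n_ch = 4, seed = 1L, ...) {
  simulation_config(sample_rate = 200, n_channels_per_hemisphere = n_ch,
                    duration = duration, seed = seed, ...)
}

# single-trial (or replicated-trial) epoch set around a given signal
signal_epochs <- function(x, fs, times = NULL, n_trials = 1,
                          alignment = "consecutive") {
  times <- times %||% ((seq_along(x) - 1) / fs)
  data <- array(0, dim = c(n_trials, 1, length(x)))
  for (i in seq_len(n_trials)) data[i, 1, ] <- x
  epoch_set(data, times, fs, alignment = alignment)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# band power from a smoothed periodogram (independent Welch-style oracle)
welch_band_power <- function(x, fs, band) {
  sp <- stats::spec.pgram(stats::ts(x, frequency = fs), spans = c(11, 11),
                          plot = FALSE, taper = 0.1)
  sel <- sp$freq >= band[1] & sp$freq <= band[2]
  mean(sp$spec[sel])
}

expect_setequal_chr <- function(a, b) {
  expect_true(setequal(a, b),
              label = paste("setequal(", paste(a, collapse = ","), ";",
                            paste(b, collapse = ","), ")"))
}
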