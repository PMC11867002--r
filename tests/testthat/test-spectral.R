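test_that("Morlet power of a unit sinusoid matches the analytic response", {
  fs <- 1000
  tt <- seq(0, 3, 1 / fs)
  ep <- signal_epochs(sin(2 * pi * 20 * tt), fs)
  tfr <- morlet_tfr(ep, freqs = 5:60, wavelet_length = 0.5,
                    compute_itc = FALSE)
  interior <- which(tfr$valid)
  probe <- interior[round(seq(1, length(interior), length.out = 7))]
  for (k in probe) {
    expect_equal(tfr$freqs[which.max(tfr$power[1, , k])], 20)
  }
  # unit-energy Morlet response to a unit sinusoid: |W|^2 = sqrt(pi)/2 * sigma
  analytic <- sqrt(pi) / 2 * (0.5 / 6)
  mid <- which.min(abs(tfr$times - 1.5))
  expect_equal(tfr$power[1, tfr$freqs == 20, mid], analytic,
               tolerance = 0.01)
  # doubling the amplitude quadruples power everywhere
  ep2 <- signal_epochs(2 * sin(2 * pi * 20 * tt), fs)
  tfr2 <- morlet_tfr(ep2, freqs = 5:60, wavelet_length = 0.5,
                     compute_itc = FALSE)
  expect_equal(tfr2$power, 4 * tfr$power, tolerance = 1e-12)
  # a DC signal leaves no power anywhere on the grid
  tfr0 <- morlet_tfr(signal_epochs(rep(1, length(tt)), fs), freqs = 5:60,
                     wavelet_length = 0.5, compute_itc = FALSE)
  expect_lt(max(tfr0$power[1, , mid]) / tfr$power[1, tfr$freqs == 20, mid],
            1e-6)
})

test_that("the FFT convolution agrees with direct time-domain convolution", {
  fs <- 250
  set.seed(8)
  x <- rnorm(fs)                           # 1 s of noise
  ep <- signal_epochs(x, fs)
  freqs <- c(7, 20, 41)
  tfr <- morlet_tfr(ep, freqs = freqs, wavelet_length = 0.3,
                    compute_itc = FALSE)
  for (fi in seq_along(freqs)) {
    w <- morlet_wavelet(freqs[fi], 0.3, fs)
    half <- (length(w) - 1) / 2
    for (k in c(half + 1, 125, fs - half)) {
      direct <- sum(x[(k - half):(k + half)] * Conj(w)) / fs
      expect_equal(tfr$power[1, fi, k], Mod(direct)^2,
                   tolerance = 1e-6)
    }
  }
})

test_that("TFR guards reject invalid grids and wavelets", {
  ep <- signal_epochs(rnorm(400), 200)
  expect_error(morlet_tfr(ep, freqs = c(10, 120), wavelet_length = 0.3),
               "Nyquist")
  expect_error(morlet_tfr(ep, freqs = 10, wavelet_length = 3), "shorter")
  expect_error(morlet_tfr(ep, freqs = 10, wavelet_length = 0.3,
                          channels = "nope"), "unknown channel")
})

test_that("intertrial coherence calibrates against closed-form anchors", {
  fs <- 200
  tt <- seq(0, 1.5, 1 / fs)
  # identical trials: perfect phase alignment
  ep <- signal_epochs(sin(2 * pi * 12 * tt) + 0.1 * cos(2 * pi * 31 * tt),
                      fs, n_trials = 5)
  tfr <- morlet_tfr(ep, freqs = c(12, 31), wavelet_length = 0.4)
  sel <- tfr$valid
  expect_true(all(tfr$itc[1, , sel] > 0.999))
  # two trials in antiphase cancel exactly
  d2 <- array(0, dim = c(2, 1, length(tt)))
  d2[1, 1, ] <- sin(2 * pi * 12 * tt)
  d2[2, 1, ] <- -sin(2 * pi * 12 * tt)
  ep2 <- epoch_set(d2, tt, fs, "consecutive")
  tfr2 <- morlet_tfr(ep2, freqs = 12, wavelet_length = 0.4)
  expect_lt(max(tfr2$itc[1, 1, sel]), 1e-10)
  # 200 uniform random phases: E[resultant] = sqrt(pi) / (2 sqrt(200))
  set.seed(99)
  phases <- matrix(runif(200 * 400, 0, 2 * pi), 200, 400)
  coef <- array(exp(1i * phases), dim = c(200, 1, 1, 400))
  vals <- itc(coef)
  expect_equal(mean(vals), sqrt(pi) / (2 * sqrt(200)), tolerance = 0.01)
})

test_that("ITC ignores trial order and common phase rotations", {
  set.seed(4)
  coef <- array(complex(real = rnorm(40 * 6), imaginary = rnorm(40 * 6)),
                dim = c(40, 1, 2, 3))
  expect_equal(itc(coef[sample(40), , , , drop = FALSE]), itc(coef))
  expect_equal(itc(coef * exp(1.234i)), itc(coef), tolerance = 1e-12)
  # trial-averaged power is invariant to trial order
  cfg <- quick_config(duration = 48, n_ch = 2, seed = 41)
  raw <- simulate_subject(cfg, 1, stim_frequency = 20)
  ep <- suppressMessages(
    make_offset_epochs(raw, detect_train_offsets(raw, "events")))
  perm <- ep
  ord <- rev(seq_len(dim(ep$data)[1]))
  perm$data <- ep$data[ord, , , drop = FALSE]
  t1 <- morlet_tfr(ep, freqs = c(15, 20), wavelet_length = 0.3)
  t2 <- morlet_tfr(perm, freqs = c(15, 20), wavelet_length = 0.3)
  expect_equal(t2$power, t1$power, tolerance = 1e-12)
  expect_equal(t2$itc, t1$itc, tolerance = 1e-12)
})

test_that("baseline correction is frequency-specific, zero-mean and idempotent", {
  fs <- 200
  tt <- seq(-3, 3, 1 / fs)
  # amplitude steps from 1 to 2 at t = 0 -> power steps by 3x the unit level
  x <- sin(2 * pi * 15 * tt) * ifelse(tt < 0, 1, 2)
  tfr <- morlet_tfr(signal_epochs(x, fs, times = tt), freqs = c(10, 15),
                    wavelet_length = 0.4, compute_itc = FALSE)
  unit <- mean(tfr$power[1, 2, tfr$times > -2 & tfr$times < -0.5])
  bc <- baseline_correct(tfr, c(-2, -0.5))
  expect_lt(abs(mean(bc$power[1, 2, bc$times >= -2 & bc$times < -0.5])),
            1e-9 * unit)
  expect_equal(mean(bc$power[1, 2, bc$times > 0.5 & bc$times < 2]),
               3 * unit, tolerance = 0.02 * unit)
  bc2 <- baseline_correct(bc, c(-2, -0.5))
  expect_equal(bc2$power, bc$power, tolerance = 1e-9)
  expect_identical(bc$itc, tfr$itc)
  expect_error(baseline_correct(tfr, c(5, 6)), "no samples")
})

test_that("segment spectra live on the 6.45 Hz grid and obey Parseval", {
  fs <- 200
  times <- seq(-3.5, 3.5, 1 / fs)
  ss <- segment_spectrum(signal_epochs(sin(2 * pi * 12.9 * times), fs,
                                       times = times,
                                       alignment = "train_offset"))
  expect_equal(ss$freqs, (1:9) / 0.155, tolerance = 1e-7)
  expect_lt(max(abs(diff(ss$freqs) - 1 / 0.155)), 1e-6)
  expect_equal(which.max(ss$power[1, ]), 2)
  # zero input, zero spectrum
  ss0 <- segment_spectrum(signal_epochs(numeric(length(times)), fs,
                                        times = times,
                                        alignment = "train_offset"))
  expect_true(all(ss0$power == 0))
  # Parseval: one-sided bin powers sum to the tapered segment's variance
  set.seed(12)
  x <- rnorm(length(times))
  ep <- signal_epochs(x, fs, times = times, alignment = "train_offset")
  full <- segment_spectrum(ep, max_freq = fs / 2)
  i0 <- which(times >= 0.005 - 1e-9)[1]
  seg <- x[i0:(i0 + 30)]
  taper <- 0.5 - 0.5 * cos(2 * pi * (0:30) / 31)
  z <- (seg - sum(seg * taper) / sum(taper)) * taper
  expect_equal(sum(full$power[1, ]), mean(z^2) - mean(z)^2,
               tolerance = 1e-12)
  expect_error(segment_spectrum(ep, window = c(3.45, 3.605)), "extends")
})

test_that("short wavelets keep stimulation-period power out of the pause", {
  # DBS-band content confined to t < 0 must not contaminate t >= 0.155 s
  fs <- 200
  times <- seq(-3.5, 3.5, 1 / fs)
  x <- ifelse(times < 0, sin(2 * pi * 20 * times), 0)
  tfr <- morlet_tfr(signal_epochs(x, fs, times = times,
                                  alignment = "train_offset"),
                    freqs = 20, wavelet_length = 0.3, compute_itc = FALSE)
  on_level <- mean(tfr$power[1, 1, times > -2 & times < -0.5])
  post <- max(tfr$power[1, 1, times >= 0.155 & times < 1])
  expect_lt(post, 0.01 * on_level)
})
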