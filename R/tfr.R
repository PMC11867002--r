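#' Complex Morlet wavelet of fixed temporal support
#'
#' The wavelet has total length `wavelet_length` seconds at every frequency
#' (Gaussian envelope sigma = length/6, so the support covers ~ +/-3
#' sigma), is corrected to zero mean and normalized to unit energy in the
#' continuous sense (`sum(|psi|^2) / fs == 1`). A fixed length in seconds
#' -- rather than a fixed cycle count -- gives every frequency the same
#' temporal smearing, which is what bounds the leakage of
#' stimulation-period activity into the post-train pause.
#'
#' @param freq center frequency in Hz.
#' @param wavelet_length total support in seconds.
#' @param fs sampling rate in Hz.
#' @return complex vector of odd length (centered).
#' @export
morlet_wavelet <- function(freq, wavelet_length, fs) {
  half <- floor(wavelet_length * fs / 2)
  tt <- (-half:half) / fs
  sigma <- wavelet_length / 6
  env <- exp(-tt^2 / (2 * sigma^2))
  carrier <- exp(2i * pi * freq * tt)
  kappa <- sum(env * carrier) / sum(env)     # zero-mean correction
  psi <- env * (carrier - kappa)
  psi / sqrt(sum(Mod(psi)^2) / fs)
}

#' Morlet time-frequency transform
#'
#' Convolves every trial and channel with unit-energy complex Morlet
#' wavelets ([morlet_wavelet()]) on a frequency grid, via FFT. Returns
#' trial-averaged power (`|W|^2`, amplitude-squared units) and intertrial
#' coherence (the magnitude of the trial-mean unit phase vector), and
#' optionally the per-trial complex coefficients. Samples within half a
#' wavelet length of an epoch edge are convolution edge artifacts; they are
#' flagged by the `valid` element and should be excluded from statistics.
#'
#' @param epochs an `epoch_set` (or any trials x channels x time array
#'   wrapped in one).
#' @param freqs frequency grid in Hz (all < Nyquist).
#' @param wavelet_length wavelet support in seconds (< epoch duration).
#' @param channels channel ids (or indices) to transform; default all.
#' @param keep_trials retain per-trial complex coefficients (memory grows
#'   as trials x channels x freqs x times).
#' @param compute_itc accumulate intertrial coherence (needs >= 2 trials;
#'   otherwise flagged NA).
#' @return an object of class `tfr` with elements `power` (channels x
#'   freqs x times), `itc` (same shape, NA when undefined), `freqs`,
#'   `times`, `valid`, `wavelet_length`, `n_trials`, `sample_rate`,
#'   `channel_ids`, and `coef` when `keep_trials = TRUE`.
#' @export
morlet_tfr <- function(epochs, freqs = 5:60, wavelet_length = 0.5,
                       channels = NULL, keep_trials = FALSE,
                       compute_itc = TRUE) {
  data <- epochs$data
  fs <- epochs$sample_rate
  nt <- dim(data)[3]
  if (any(freqs >= fs / 2))
    stop("frequencies must lie below the Nyquist frequency (", fs / 2,
         " Hz)")
  if (wavelet_length >= nt / fs)
    stop("wavelet_length (", wavelet_length,
         " s) must be shorter than the epoch")
  ch_ids <- dimnames(data)[[2]] %||% as.character(seq_len(dim(data)[2]))
  channels <- channels %||% ch_ids
  ch_idx <- if (is.character(channels)) match(channels, ch_ids) else channels
  if (anyNA(ch_idx)) stop("unknown channel id")
  ntr <- dim(data)[1]
  nch <- length(ch_idx)
  nfr <- length(freqs)

  wavelets <- lapply(freqs, morlet_wavelet, wavelet_length = wavelet_length,
                     fs = fs)
  nw <- length(wavelets[[1]])
  cw <- (nw + 1L) %/% 2L
  nfft <- fast_fft_length(nt + nw - 1L)
  psi_f <- lapply(wavelets, function(w) Conj(stats::fft(c(w, rep(0, nfft - nw)))))
  # map epoch sample k to the circular correlation lag index
  lag_idx <- ((seq_len(nt) - cw) %% nfft) + 1L

  pow <- array(0, dim = c(nch, nfr, nt))
  itc_sum <- if (compute_itc) array(0i, dim = c(nch, nfr, nt))
  itc_n <- if (compute_itc) array(0L, dim = c(nch, nfr, nt))
  coef <- if (keep_trials) array(NA_complex_, dim = c(ntr, nch, nfr, nt))
  dt <- 1 / fs
  for (tr in seq_len(ntr)) {
    for (ci in seq_len(nch)) {
      x <- c(data[tr, ch_idx[ci], ], rep(0, nfft - nt))
      X <- stats::fft(x)
      for (fi in seq_len(nfr)) {
        w <- (stats::fft(X * psi_f[[fi]], inverse = TRUE) / nfft)[lag_idx] * dt
        pow[ci, fi, ] <- pow[ci, fi, ] + Mod(w)^2
        if (compute_itc) {
          m <- Mod(w)
          nz <- m > 0
          itc_sum[ci, fi, nz] <- itc_sum[ci, fi, nz] + w[nz] / m[nz]
          itc_n[ci, fi, nz] <- itc_n[ci, fi, nz] + 1L
        }
        if (keep_trials) coef[tr, ci, fi, ] <- w
      }
    }
  }
  pow <- pow / ntr
  itc <- if (compute_itc && ntr >= 2) {
    out <- Mod(itc_sum) / pmax(itc_n, 1L)
    out[itc_n < 2] <- NA_real_
    out
  } else NULL
  times <- epochs$times
  valid <- times >= times[1] + wavelet_length / 2 &
    times <= times[nt] - wavelet_length / 2
  structure(list(power = pow, itc = itc, freqs = freqs, times = times,
                 valid = valid, wavelet_length = wavelet_length,
                 n_trials = ntr, sample_rate = fs,
                 channel_ids = ch_ids[ch_idx],
                 baseline_window = NULL,
                 coef = coef),
            class = "tfr")
}

#' Intertrial coherence from per-trial coefficients
#'
#' `ITC = |mean over trials of W / |W||` per channel x frequency x time
#' bin; bins with zero-magnitude coefficients are excluded from the mean,
#' and bins with fewer than two contributing trials are flagged NA.
#'
#' @param coef complex array with trials as the first dimension (e.g. the
#'   `coef` element of a [morlet_tfr()] run with `keep_trials = TRUE`).
#' @return numeric array (the remaining dimensions) in [0, 1].
#' @export
itc <- function(coef) {
  if (is.list(coef)) coef <- coef$coef
  d <- dim(coef)
  if (d[1] < 2) stop("intertrial coherence needs at least 2 trials")
  m <- Mod(coef)
  ok <- m > 0
  unit <- coef
  unit[ok] <- coef[ok] / m[ok]
  unit[!ok] <- 0i
  n_ok <- colSums(array(ok, dim = d), dims = 1)
  s <- colSums(unit, dims = 1)
  out <- Mod(s) / pmax(n_ok, 1)
  out[n_ok < 2] <- NA_real_
  out
}

#' Frequency-specific baseline correction
#'
#' Subtracts, per channel and frequency, the mean power inside the
#' baseline window from every time-frequency bin. ITC is left untouched.
#'
#' @param tfr a `tfr` object.
#' @param baseline_window `c(start, end)` in seconds, inside `tfr$times`.
#' @return the corrected `tfr` (with `baseline_window` recorded).
#' @export
baseline_correct <- function(tfr, baseline_window) {
  sel <- tfr$times >= baseline_window[1] & tfr$times < baseline_window[2]
  if (!any(sel)) stop("baseline window contains no samples")
  base <- apply(tfr$power[, , sel, drop = FALSE], c(1, 2), mean)
  tfr$power <- sweep(tfr$power, c(1, 2), base)
  tfr$baseline_window <- baseline_window
  tfr
}

#' Short-segment after-effect spectrum
#'
#' Extracts the immediate post-train window (default 5-160 ms after the
#' last pulse, the 5 ms margin avoiding the pulse artifact), removes the
#' taper-weighted mean from and Hann-tapers the 155 ms segment per trial
#' and channel, and evaluates its
#' discrete Fourier power on the window's natural grid k / 0.155 s =
#' k x 6.45 Hz -- the grid on which the after-effect lateralization is
#' computed (beta corresponds to bins k = 2..4, i.e. 12.9-25.8 Hz).
#'
#' @param epochs an offset-aligned `epoch_set`.
#' @param window `c(start, end)` in seconds relative to the train offset.
#' @param max_freq highest bin frequency returned (Hz).
#' @return an object of class `segment_spectrum` with `power`
#'   (channels x bins, trial-averaged, amplitude-squared units),
#'   `per_trial` (trials x channels x bins), `freqs`, `window`.
#' @export
segment_spectrum <- function(epochs, window = c(0.005, 0.160),
                             max_freq = 60) {
  fs <- epochs$sample_rate
  len <- window[2] - window[1]
  nseg <- round(len * fs)
  i0 <- which(epochs$times >= window[1] - 1e-9)[1]
  if (is.na(i0) || i0 + nseg - 1 > length(epochs$times))
    stop("segment window extends past the epoch")
  ntr <- dim(epochs$data)[1]
  nch <- dim(epochs$data)[2]
  seg <- epochs$data[, , i0:(i0 + nseg - 1), drop = FALSE]
  # columns = trial x channel traces
  m <- matrix(aperm(seg, c(3, 1, 2)), nrow = nseg)
  taper <- hann_taper(nseg)
  # taper-weighted demean: removes the DC the taper would otherwise
  # reintroduce, and keeps zero-weight edge samples (e.g. the residual
  # pulse artifact at the window start) out of the estimate entirely
  m <- sweep(m, 2, colSums(m * taper) / sum(taper))
  m <- m * taper
  X <- stats::mvfft(m)
  kmax <- min(floor(max_freq * len + 1e-9), floor((nseg - 1) / 2))
  p <- 2 * Mod(X[1 + seq_len(kmax), , drop = FALSE])^2 / nseg^2
  per_trial <- array(t(p), dim = c(ntr, nch, kmax))
  ch_ids <- dimnames(epochs$data)[[2]]
  dimnames(per_trial) <- list(NULL, ch_ids, NULL)
  power <- apply(per_trial, c(2, 3), mean)
  rownames(power) <- ch_ids
  structure(list(power = power, per_trial = per_trial,
                 freqs = seq_len(kmax) / len, window = window,
                 n_trials = ntr, taper = "hann"),
            class = "segment_spectrum")
}
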