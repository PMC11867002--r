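#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the seed, runs the code, and restores the caller's RNG state, so
#' simulation routines are reproducible without clobbering the session RNG.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a deterministic child seed from a master seed
#'
#' Mixes the master seed with stream identifiers so every subject,
#' condition and replicate draws from an independent, reproducible stream.
#' The result stays below 2^31 - 1.
#'
#' @param master integer master seed.
#' @param ... integer stream identifiers.
#' @return integer seed.
#' @export
derive_seed <- function(master, ...) {
  ks <- c(as.numeric(master), as.numeric(c(...)))
  h <- 104729
  for (k in ks) h <- (h * 68111 + (k + 1) * 9739) %% 2147483629
  as.integer(h + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Intersect two sets of half-open time windows
#'
#' @param a,b two-column matrices of [start, end) windows in seconds.
#' @return two-column matrix of the pairwise non-empty intersections.
#' @keywords internal
intersect_windows <- function(a, b) {
  a <- matrix(as.numeric(a), ncol = 2)
  b <- matrix(as.numeric(b), ncol = 2)
  out <- vector("list", nrow(a))
  for (i in seq_len(nrow(a))) {
    lo <- pmax(a[i, 1], b[, 1])
    hi <- pmin(a[i, 2], b[, 2])
    keep <- hi > lo
    if (any(keep)) out[[i]] <- cbind(lo[keep], hi[keep])
  }
  res <- do.call(rbind, out)
  if (is.null(res)) matrix(numeric(0), ncol = 2) else res
}

# total length of a set of [start, end) windows, in seconds
window_length <- function(w) {
  if (length(w) == 0) return(0)
  sum(w[, 2] - w[, 1])
}

# periodic Hann taper of length n (as used for short-segment spectra)
hann_taper <- function(n) {
  0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / n)
}

# smallest highly-composite FFT length >= n
fast_fft_length <- function(n) {
  stats::nextn(n, factors = c(2, 3, 5))
}
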