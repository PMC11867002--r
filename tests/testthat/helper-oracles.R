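# Independent brute-force oracles used against the permutation machinery.
# They share nothing with the package implementation: plain loops, matrix
# t statistics from first principles, and a union-find clustering.

brute_t <- function(d) {
  n <- length(d)
  mean(d) / (stats::sd(d) / sqrt(n))
}

brute_clusters <- function(tvec, thr, adj) {
  # returns list of integer vectors (supra-threshold connected components,
  # positive and negative separately)
  out <- list()
  for (sgn in c(1, -1)) {
    supra <- unname(which(sgn * tvec > thr))
    lab <- seq_along(supra)
    repeat {
      changed <- FALSE
      for (i in seq_along(supra)) for (j in seq_along(supra)) {
        if (adj[supra[i], supra[j]] && lab[i] != lab[j]) {
          lab[lab == max(lab[i], lab[j])] <- min(lab[i], lab[j])
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    for (l in unique(lab)) out[[length(out) + 1]] <- sort(supra[lab == l])
  }
  out
}

brute_cluster_p <- function(x, y, adj, alpha = 0.05) {
  d <- x - y
  n <- nrow(d)
  thr <- stats::qt(1 - alpha / 2, n - 1)
  t_obs <- apply(d, 2, brute_t)
  obs <- brute_clusters(t_obs, thr, adj)
  masses <- vapply(obs, function(ix) sum(t_obs[ix]), numeric(1))
  flips <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
  null_max <- apply(flips, 1, function(s) {
    tv <- apply(d * s, 2, brute_t)
    cl <- brute_clusters(tv, thr, adj)
    if (length(cl) == 0) 0 else
      max(abs(vapply(cl, function(ix) sum(tv[ix]), numeric(1))))
  })
  list(clusters = obs, mass = masses,
       p = vapply(abs(masses), function(m) mean(null_max >= m - 1e-12),
                  numeric(1)))
}

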