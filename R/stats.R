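# --- sign-flip machinery ----------------------------------------------------

# All 2^n sign assignments when feasible, else Monte Carlo draws.
sign_flips <- function(n, max_exhaustive = 16384, n_perm = 4096,
                       seed = NULL) {
  if (2^n <= max_exhaustive) {
    S <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
    dimnames(S) <- NULL
    list(S = S, exhaustive = TRUE)
  } else {
    S <- with_seed(seed %||% 1L,
                   matrix(sample(c(1, -1), n_perm * n, replace = TRUE),
                          ncol = n))
    list(S = S, exhaustive = FALSE)
  }
}

# one-sample t statistics for every sign flip (rows of S) and every column
# of D (subjects x variables); vectorized over flips.
flip_t_matrix <- function(S, D) {
  n <- nrow(D)
  M <- S %*% D / n
  ssq <- colSums(D^2)                      # invariant under sign flips
  V <- sweep(-M^2, 2, ssq / n, "+") * n / (n - 1)
  V[V < 1e-300] <- 0
  Tm <- M / sqrt(V / n)
  Tm[V == 0 & M == 0] <- 0                 # identical conditions: t = 0
  Tm[V == 0 & M > 0] <- Inf
  Tm[V == 0 & M < 0] <- -Inf
  Tm
}

# connected components of `nodes` under the adjacency matrix
connected_components <- function(nodes, adjacency) {
  comps <- list()
  remaining <- unname(nodes)
  while (length(remaining) > 0) {
    queue <- remaining[1]
    comp <- integer(0)
    while (length(queue) > 0) {
      v <- queue[1]
      queue <- queue[-1]
      if (v %in% comp) next
      comp <- c(comp, v)
      nb <- which(adjacency[v, ])
      queue <- c(queue, intersect(nb, setdiff(remaining, comp)))
    }
    comps[[length(comps) + 1]] <- sort(comp)
    remaining <- setdiff(remaining, comp)
  }
  comps
}

# maximum |cluster mass| of a t-map given a forming threshold
max_cluster_mass <- function(tvec, threshold, adjacency) {
  mm <- 0
  for (sgn in c(1, -1)) {
    supra <- which(sgn * tvec > threshold)
    if (length(supra) == 0) next
    for (comp in connected_components(supra, adjacency))
      mm <- max(mm, abs(sum(tvec[comp])))
  }
  mm
}

#' Cluster-level paired permutation test over sensor maps
#'
#' Nonparametric paired test for spatial data: per-channel paired t
#' statistics between two conditions, channels exceeding the two-sided
#' cluster-forming threshold grouped into clusters via the sensor
#' adjacency graph (positive and negative deflections separately), cluster
#' mass = sum of member t values, and a permutation null built from the
#' maximum |cluster mass| under subject-wise sign flips of the paired
#' differences. All 2^n flips are enumerated when feasible
#' (2^n <= `max_exhaustive`, giving exact p values in multiples of 1/2^n);
#' otherwise `n_perm` random flips are drawn and p = (b + 1) / (m + 1).
#'
#' @param x,y subjects x channels matrices of paired condition maps (e.g.
#'   a post-offset window mean and the stimulation-pause mean).
#' @param adjacency logical channel adjacency matrix (symmetric,
#'   irreflexive).
#' @param alpha_cluster two-sided alpha of the cluster-forming paired-t
#'   threshold.
#' @param max_exhaustive,n_perm,seed permutation controls.
#' @return an object of class `cluster_test`: `t_map`, `threshold`,
#'   `clusters` (list of channel index vectors), `channel_ids`, `mass`,
#'   `p_value` per cluster, `n_perm`, `exhaustive`.
#' @export
cluster_perm_paired <- function(x, y, adjacency, alpha_cluster = 0.05,
                                max_exhaustive = 16384, n_perm = 4096,
                                seed = NULL) {
  x <- as.matrix(x)
  y <- as.matrix(y)
  stopifnot(all(dim(x) == dim(y)))
  n <- nrow(x)
  if (n < 3) stop("need at least 3 subjects")
  D <- x - y
  nch <- ncol(D)
  stopifnot(nrow(adjacency) == nch)
  ncomp <- length(connected_components(seq_len(nch), adjacency))
  if (ncomp > 1)
    message("adjacency graph has ", ncomp, " disconnected components")
  thr <- stats::qt(1 - alpha_cluster / 2, df = n - 1)
  t_obs <- flip_t_matrix(matrix(1, 1, n), D)[1, ]
  clusters <- list()
  masses <- numeric(0)
  for (sgn in c(1, -1)) {
    supra <- which(sgn * t_obs > thr)
    if (length(supra) == 0) next
    for (comp in connected_components(supra, adjacency)) {
      clusters[[length(clusters) + 1]] <- comp
      masses <- c(masses, sum(t_obs[comp]))
    }
  }
  fl <- sign_flips(n, max_exhaustive, n_perm, seed)
  Tm <- flip_t_matrix(fl$S, D)
  null_max <- vapply(seq_len(nrow(Tm)), function(i)
    max_cluster_mass(Tm[i, ], thr, adjacency), numeric(1))
  p <- if (length(masses) > 0) {
    vapply(abs(masses), function(m0) {
      if (fl$exhaustive) mean(null_max >= m0 - 1e-12)
      else (sum(null_max >= m0 - 1e-12) + 1) / (nrow(fl$S) + 1)
    }, numeric(1))
  } else numeric(0)
  structure(list(t_map = t_obs, threshold = thr, clusters = clusters,
                 channel_ids = colnames(x) %||% rownames(adjacency),
                 mass = masses, p_value = p,
                 n_perm = nrow(fl$S), exhaustive = fl$exhaustive),
            class = "cluster_test")
}

#' @export
print.cluster_test <- function(x, ...) {
  cat(sprintf("<cluster_test> %d cluster(s), %s%d permutations\n",
              length(x$clusters),
              if (x$exhaustive) "exhaustive " else "", x$n_perm))
  for (i in seq_along(x$clusters))
    cat(sprintf("  cluster %d: %d channel(s), mass %.2f, p = %.4g\n",
                i, length(x$clusters[[i]]), x$mass[i], x$p_value[i]))
  invisible(x)
}

#' One-sample permutation t test with tmax correction
#'
#' Per-bin one-sample t statistics (e.g. the normalized LI per frequency
#' bin against zero) with family-wise error controlled by the permutation
#' distribution of the maximum |t| across bins under subject sign flips.
#' The adjusted p value of a bin is the proportion of the max-|t| null at
#' or above its observed |t|.
#'
#' @param values subjects x bins matrix.
#' @param max_exhaustive,n_perm,seed permutation controls.
#' @return list with `t` (per bin), `p_adjusted`, `n_perm`, `exhaustive`.
#' @export
tmax_perm_onesample <- function(values, max_exhaustive = 16384,
                                n_perm = 4096, seed = NULL) {
  values <- as.matrix(values)
  n <- nrow(values)
  if (n < 3) stop("need at least 3 subjects")
  t_obs <- flip_t_matrix(matrix(1, 1, n), values)[1, ]
  fl <- sign_flips(n, max_exhaustive, n_perm, seed)
  Tm <- abs(flip_t_matrix(fl$S, values))
  null_max <- apply(Tm, 1, max)
  p <- vapply(abs(t_obs), function(t0) {
    if (fl$exhaustive) mean(null_max >= t0 - 1e-12)
    else (sum(null_max >= t0 - 1e-12) + 1) / (nrow(fl$S) + 1)
  }, numeric(1))
  list(t = t_obs, p_adjusted = p, n_perm = nrow(fl$S),
       exhaustive = fl$exhaustive)
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Standard step-up procedure via [stats::p.adjust()]; the
#' Benjamini-Yekutieli variant is available for dependence structures
#' where BH's assumptions are in doubt.
#'
#' @param p raw p values in [0, 1].
#' @param alpha FDR level.
#' @param method `"BH"` (default) or `"BY"`.
#' @return list with `reject` (logical), `p_adjusted`, `alpha`, `method`.
#' @export
fdr_bh <- function(p, alpha = 0.05, method = c("BH", "BY")) {
  method <- match.arg(method)
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p values must lie in [0, 1]")
  adj <- stats::p.adjust(p, method = method)
  list(reject = !is.na(adj) & adj <= alpha, p_adjusted = adj,
       alpha = alpha, method = method)
}

#' Pearson correlation with two-sided t-based p value
#'
#' @param x,y finite numeric vectors, n >= 3.
#' @return list with `r`, `p`, `n`.
#' @export
pearson_cor <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3,
            all(is.finite(x)), all(is.finite(y)))
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Linear mixed model: normalized LI ~ DBS frequency
#'
#' REML fit of `normalized_li ~ dbs_frequency + (1 | participant)` with a
#' Satterthwaite F test for the categorical frequency factor
#' (via lmerTest). A singular fit (zero participant variance) is flagged
#' and the model falls back to the fixed-effects one-way ANOVA, whose F
#' statistic is the closed-form limit of the mixed model at zero random
#' variance.
#'
#' @param table data.frame with columns `participant`, `dbs_frequency`,
#'   `normalized_li` (>= 2 frequency levels, >= 3 participants).
#' @return list with `estimates` (fixed effects), `F`, `df1`, `df2`, `p`,
#'   `formula`, `method`, `singular`.
#' @export
lme_li_frequency <- function(table) {
  table$participant <- factor(table$participant)
  table$dbs_frequency <- factor(table$dbs_frequency)
  if (nlevels(table$dbs_frequency) < 2) stop("need >= 2 frequency levels")
  if (nlevels(table$participant) < 3) stop("need >= 3 participants")
  fit <- lmerTest::lmer(normalized_li ~ dbs_frequency + (1 | participant),
                        data = table, REML = TRUE)
  singular <- lme4::isSingular(fit, tol = 1e-5)
  if (singular) {
    message("singular mixed-model fit (zero participant variance); ",
            "falling back to fixed-effects ANOVA")
    av <- stats::anova(stats::lm(normalized_li ~ dbs_frequency,
                                 data = table))
    return(list(estimates = stats::coef(stats::lm(
      normalized_li ~ dbs_frequency, data = table)),
      F = av$`F value`[1], df1 = av$Df[1], df2 = av$Df[2],
      p = av$`Pr(>F)`[1],
      formula = "normalized_li ~ dbs_frequency", method = "anova-fallback",
      singular = TRUE))
  }
  av <- stats::anova(fit)           # Satterthwaite by default in lmerTest
  list(estimates = lme4::fixef(fit),
       F = av$`F value`[1], df1 = av$NumDF[1], df2 = av$DenDF[1],
       p = av$`Pr(>F)`[1],
       formula = "normalized_li ~ dbs_frequency + (1 | participant)",
       method = "lmer-reml-satterthwaite", singular = FALSE)
}

#' Poisson mixed model for tap counts
#'
#' Generalized linear mixed model of finger-tap counts with a
#' log(exposure) offset (rates expressed in taps/min), fixed effects
#' DBS state (ON = +0.5, OFF = -0.5), DBS frequency (sum-coded
#' categorical) and their interaction, and a random intercept per
#' participant. Each effect is tested by a type-III likelihood-ratio
#' chi-square: the full model against the model with that term's design
#' columns removed (all other terms, including the interaction, kept).
#'
#' @param table data.frame with columns `participant`, `dbs_frequency`,
#'   `state` ("on"/"off"), `tap_count`, `exposure_s`. Zero-exposure rows
#'   are dropped with a warning.
#' @param tests compute the likelihood-ratio tests (set FALSE to return
#'   only the full-model estimates, e.g. in recovery simulations).
#' @return list with `estimates` (fixed effects on the log taps/min
#'   scale), `rate_ratio_on_off`, `tests` (data.frame term/chisq/df/p),
#'   `formula`, `method`.
#' @export
glmm_taprate <- function(table, tests = TRUE) {
  bad <- table$exposure_s <= 0
  if (any(bad)) {
    warning(sum(bad), " zero-exposure row(s) dropped")
    table <- table[!bad, , drop = FALSE]
  }
  table$participant <- factor(table$participant)
  ff <- factor(table$dbs_frequency)
  d <- ifelse(table$state == "on", 0.5, -0.5)
  dat <- data.frame(y = table$tap_count, participant = table$participant,
                    off = log(table$exposure_s / 60), d = d)
  fcols <- icols <- character(0)
  if (nlevels(ff) > 1) {
    Cf <- stats::contr.sum(nlevels(ff))[as.integer(ff), , drop = FALSE]
    fcols <- paste0("f", seq_len(ncol(Cf)))
    icols <- paste0("df", seq_len(ncol(Cf)))
    dat[fcols] <- Cf
    dat[icols] <- Cf * d
  }
  fit_with <- function(cols) {
    rhs <- paste(c(cols, "offset(off)", "(1 | participant)"),
                 collapse = " + ")
    lme4::glmer(stats::as.formula(paste("y ~", rhs)), data = dat,
                family = stats::poisson(),
                control = lme4::glmerControl(optimizer = "bobyqa",
                                             calc.derivs = FALSE))
  }
  full_cols <- c("d", fcols, icols)
  full <- fit_with(full_cols)
  drop_sets <- if (!tests) list() else
    c(list(dbs = "d"),
      if (length(fcols)) list(dbs_frequency = fcols,
                              interaction = icols))
  lrt <- lapply(names(drop_sets), function(term) {
    red <- fit_with(setdiff(full_cols, drop_sets[[term]]))
    chisq <- max(0, 2 * (as.numeric(stats::logLik(full)) -
                           as.numeric(stats::logLik(red))))
    df <- length(drop_sets[[term]])
    data.frame(term = term, chisq = chisq, df = df,
               p = stats::pchisq(chisq, df, lower.tail = FALSE))
  })
  est <- lme4::fixef(full)
  list(estimates = est,
       rate_ratio_on_off = unname(exp(est["d"])),
       tests = if (length(lrt)) do.call(rbind, lrt) else NULL,
       formula = paste("tap_count ~ dbs * dbs_frequency +",
                       "(1 | participant) + offset(log(exposure_s / 60))"),
       method = "glmer-poisson-lrt-type3")
}

#' Tap counts, exposures and rates by stimulation state
#'
#' Accumulates tap counts and exposure over the intersections of the
#' green-cue (tapping) windows with the ON trains and OFF pauses of a
#' session, and converts to rates in taps/min.
#'
#' @param events an `event_table` containing `tap` events.
#' @param schedule the session `stim_schedule` (NULL: everything is OFF).
#' @param green_windows `[start, end)` matrix of tapping windows.
#' @return data.frame with columns `state`, `tap_count`, `exposure_s`,
#'   `rate` (taps/min).
#' @export
tap_rates <- function(events, schedule, green_windows) {
  taps <- events$onset[events$event_type == "tap"]
  end <- max(green_windows[, 2])
  on_w <- if (is.null(schedule)) matrix(numeric(0), ncol = 2) else
    cbind(schedule$train_onsets, schedule$train_offsets)
  off_w <- if (is.null(schedule)) matrix(c(0, end), ncol = 2) else {
    brk <- sort(unique(c(0, t(on_w), end)))
    cand <- cbind(utils::head(brk, -1), utils::tail(brk, -1))
    keep <- vapply(seq_len(nrow(cand)), function(i)
      nrow(intersect_windows(cand[i, , drop = FALSE], on_w)) == 0,
      logical(1))
    cand[keep & cand[, 2] > cand[, 1], , drop = FALSE]
  }
  one_state <- function(w, state) {
    wg <- intersect_windows(w, green_windows)
    cnt <- if (nrow(wg) == 0) 0L else
      sum(vapply(seq_len(nrow(wg)), function(i)
        sum(taps >= wg[i, 1] & taps < wg[i, 2]), numeric(1)))
    expo <- window_length(wg)
    data.frame(state = state, tap_count = cnt, exposure_s = expo,
               rate = if (expo > 0) cnt / expo * 60 else NA_real_)
  }
  rbind(one_state(on_w, "on"), one_state(off_w, "off"))
}

#' One-sample Cohen's d
#'
#' Effect size of paired differences: `mean(x) / sd(x)`.
#'
#' @param x numeric vector of (paired) differences.
#' @return Cohen's d.
#' @export
cohen_d <- function(x) mean(x) / stats::sd(x)
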