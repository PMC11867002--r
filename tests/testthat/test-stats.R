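test_that("cluster permutation p-values equal exhaustive enumeration (n = 5)", {
  lay <- make_grid_layout(4)           # 8 channels
  set.seed(31)
  x <- matrix(rnorm(5 * 8), 5, 8, dimnames = list(NULL, lay$channel_ids))
  y <- matrix(rnorm(5 * 8), 5, 8, dimnames = list(NULL, lay$channel_ids))
  x[, lay$channel_ids[lay$hemisphere == "left"]] <-
    x[, lay$channel_ids[lay$hemisphere == "left"]] + 1.6
  res <- cluster_perm_paired(x, y, lay$adjacency)
  expect_true(res$exhaustive)
  expect_equal(res$n_perm, 32)
  oracle <- brute_cluster_p(x, y, lay$adjacency)
  expect_equal(length(res$clusters), length(oracle$clusters))
  o <- order(vapply(res$clusters, min, numeric(1)))
  oo <- order(vapply(oracle$clusters, min, numeric(1)))
  for (i in seq_along(o)) {
    expect_equal(res$clusters[[o[i]]], oracle$clusters[[oo[i]]])
    expect_equal(res$mass[o[i]], oracle$mass[oo[i]], tolerance = 1e-12)
    expect_equal(res$p_value[o[i]], oracle$p[oo[i]], tolerance = 1e-12)
  }
  # exhaustive p values are exact multiples of 1 / 2^n
  expect_true(all(abs(res$p_value * 32 - round(res$p_value * 32)) < 1e-9))
})

test_that("identical conditions never produce a significant cluster", {
  lay <- make_grid_layout(4)
  for (s in 1:50) {
    set.seed(s)
    x <- matrix(rnorm(10 * 8), 10, 8)
    res <- cluster_perm_paired(x, x, lay$adjacency)
    expect_length(res$clusters, 0)
  }
})

test_that("a coherent injected shift is detected over the right channels", {
  lay <- make_grid_layout(8)           # 16 channels; left block connected
  block <- lay$channel_ids[lay$hemisphere == "left"]
  set.seed(77)
  x <- matrix(rnorm(10 * 16), 10, 16, dimnames = list(NULL, lay$channel_ids))
  y <- matrix(rnorm(10 * 16), 10, 16, dimnames = list(NULL, lay$channel_ids))
  x[, block] <- x[, block] + 3
  res <- cluster_perm_paired(x, y, lay$adjacency, n_perm = 1024)
  sig <- which(res$p_value <= 0.05)
  expect_gte(length(sig), 1)
  best <- res$clusters[[sig[which.max(abs(res$mass[sig]))]]]
  expect_gte(length(intersect(lay$channel_ids[best], block)), 6)
})

test_that("the cluster test is invariant to channel order and map sign", {
  lay <- make_grid_layout(4)
  set.seed(13)
  x <- matrix(rnorm(6 * 8), 6, 8, dimnames = list(NULL, lay$channel_ids))
  y <- matrix(rnorm(6 * 8), 6, 8, dimnames = list(NULL, lay$channel_ids))
  x[, 1:4] <- x[, 1:4] + 2
  res <- cluster_perm_paired(x, y, lay$adjacency)
  perm <- sample(8)
  res_p <- cluster_perm_paired(x[, perm], y[, perm],
                               lay$adjacency[perm, perm])
  expect_setequal(res_p$p_value, res$p_value)
  expect_setequal(round(abs(res_p$mass), 10), round(abs(res$mass), 10))
  res_s <- cluster_perm_paired(y, x, lay$adjacency)
  expect_equal(sort(res_s$p_value), sort(res$p_value), tolerance = 1e-12)
  expect_equal(sort(res_s$mass), sort(-res$mass), tolerance = 1e-12)
})

test_that("tmax adjusted p-values equal exhaustive enumeration (n = 5)", {
  set.seed(41)
  v <- matrix(rnorm(5 * 8), 5, 8)
  v[, 3] <- v[, 3] + 2
  res <- tmax_perm_onesample(v)
  expect_true(res$exhaustive)
  flips <- as.matrix(expand.grid(rep(list(c(1, -1)), 5)))
  null_max <- apply(flips, 1, function(s)
    max(abs(apply(v * s, 2, brute_t))))
  t_obs <- apply(v, 2, brute_t)
  p_oracle <- vapply(abs(t_obs), function(t0)
    mean(null_max >= t0 - 1e-12), numeric(1))
  expect_equal(res$t, t_obs, tolerance = 1e-12)
  expect_equal(res$p_adjusted, p_oracle, tolerance = 1e-12)
})

test_that("a near-constant positive bin attains the minimal two-sided p", {
  set.seed(42)
  v <- cbind(1 + rnorm(5, sd = 1e-4), rnorm(5, sd = 1e-4))
  res <- tmax_perm_onesample(v)
  # sign flips come in +/- pairs with equal |t|: the minimum attainable
  # two-sided adjusted p is 2 / 2^n
  expect_equal(res$p_adjusted[1], 2 / 32)
})

test_that("Monte-Carlo permutation p-values approach the exhaustive values", {
  set.seed(43)
  v <- matrix(rnorm(10 * 4), 10, 4)
  v[, 2] <- v[, 2] + 0.9
  exact <- tmax_perm_onesample(v)                       # 1024 flips
  mc <- tmax_perm_onesample(v, max_exhaustive = 512, n_perm = 10000,
                            seed = 7)
  expect_false(mc$exhaustive)
  expect_lt(max(abs(mc$p_adjusted - exact$p_adjusted)), 0.02)
})

test_that("BH step-up matches hand-computed decisions", {
  r <- fdr_bh(c(0.01, 0.02, 0.03, 0.04), alpha = 0.05)
  expect_true(all(r$reject))             # p(4) = 0.04 <= 4 * 0.05 / 4
  expect_false(fdr_bh(0.06)$reject)
  r1 <- fdr_bh(rep(1, 5))
  expect_false(any(r1$reject))
  expect_true(all(r1$p_adjusted == 1))
  # adjusted p monotone in raw p rank
  set.seed(2)
  p <- runif(20)
  adj <- fdr_bh(p)$p_adjusted
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
  # BY is more conservative
  expect_true(all(fdr_bh(p, method = "BY")$p_adjusted >= adj - 1e-12))
  expect_error(fdr_bh(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Pearson correlation matches anchors and calibrates", {
  x <- rnorm(14)
  expect_equal(pearson_cor(x, 2 * x + 1)$r, 1, tolerance = 1e-12)
  expect_equal(pearson_cor(x, -x)$r, -1, tolerance = 1e-12)
  set.seed(6)
  sims <- t(vapply(1:500, function(i) {
    a <- rnorm(14)
    b <- rnorm(14)
    ct <- pearson_cor(a, b)
    c(ct$r, ct$p)
  }, numeric(2)))
  expect_lt(abs(mean(sims[, 1])), 0.04)
  expect_gt(mean(sims[, 2] < 0.05), 0.02)
  expect_lt(mean(sims[, 2] < 0.05), 0.09)
})

test_that("the LI mixed model reduces to one-way ANOVA at zero subject variance", {
  set.seed(61)
  nsub <- 6
  lev <- c(10, 16, 20, 26, 30)
  tab <- expand.grid(participant = seq_len(nsub), dbs_frequency = lev)
  tab$normalized_li <- 0.1 * (tab$dbs_frequency == 20) + rnorm(30, sd = 0.3)
  # force identical participant means (boundary fit, zero random variance)
  pm <- tapply(tab$normalized_li, tab$participant, mean)
  tab$normalized_li <- tab$normalized_li - pm[tab$participant] + mean(pm)
  res <- suppressMessages(lme_li_frequency(tab))
  # closed-form one-way ANOVA F computed from sums of squares
  gm <- mean(tab$normalized_li)
  lm_means <- tapply(tab$normalized_li, tab$dbs_frequency, mean)
  ssb <- nsub * sum((lm_means - gm)^2)
  ssw <- sum((tab$normalized_li -
                lm_means[as.character(tab$dbs_frequency)])^2)
  f_oracle <- (ssb / 4) / (ssw / (30 - 5))
  expect_equal(res$F, f_oracle, tolerance = 1e-6)
})

test_that("the LI mixed model has correct size and power", {
  run_lme <- function(shift, seed) {
    set.seed(seed)
    tab <- expand.grid(participant = 1:8, dbs_frequency = c(10, 16, 20, 26, 30))
    b <- rnorm(8, sd = 0.2)
    tab$normalized_li <- b[tab$participant] + rnorm(40, sd = 0.1) +
      shift * 0.2 * (tab$dbs_frequency == 20)
    suppressMessages(lme_li_frequency(tab))$p
  }
  p_null <- vapply(1:120, function(s) run_lme(0, s), numeric(1))
  expect_gt(mean(p_null < 0.05), 0.01)
  expect_lt(mean(p_null < 0.05), 0.11)
  # one level shifted by 5 between-subject-residual SDs (0.5 / 0.1)
  p_alt <- vapply(1:40, function(s) run_lme(5, 1000 + s), numeric(1))
  expect_gte(mean(p_alt < 0.05), 0.95)
})

test_that("the Poisson mixed model is offset-invariant and recovers ratios", {
  set.seed(71)
  tab <- expand.grid(participant = 1:6, dbs_frequency = c(10, 20, 30),
                     state = c("on", "off"))
  lam <- 2 * exp(rnorm(6, sd = 0.1))[tab$participant] *
    ifelse(tab$state == "on", 0.9, 1)
  tab$exposure_s <- 60
  tab$tap_count <- rpois(nrow(tab), lam * tab$exposure_s)
  f1 <- glmm_taprate(tab, tests = FALSE)
  tab2 <- tab
  tab2$exposure_s <- 2 * tab$exposure_s
  tab2$tap_count <- 2 * tab$tap_count
  f2 <- glmm_taprate(tab2, tests = FALSE)
  expect_equal(f2$estimates, f1$estimates, tolerance = 1e-3)
  expect_equal(f2$rate_ratio_on_off, f1$rate_ratio_on_off,
               tolerance = 1e-3)
  # quick recovery sanity on generator output (full check in acceptance)
  cfg <- quick_config(seed = 72)
  rows <- list()
  for (s in 1:10) for (f in c(10, 20, 30)) {
    sched <- make_schedule(175, f)
    li_on <- 0.1 * 120 / cfg$li_tap_coupling
    ev <- simulate_tapping(sched, cfg, list(on = li_on, off = 0),
                           base_rate = 120,
                           seed = 72000 + s * 37 + f)
    r <- tap_rates(ev, sched, green_windows_from_events(ev))
    rows[[length(rows) + 1]] <- data.frame(participant = s,
                                           dbs_frequency = f,
                                           state = r$state,
                                           tap_count = r$tap_count,
                                           exposure_s = r$exposure_s)
  }
  fit <- glmm_taprate(do.call(rbind, rows), tests = FALSE)
  expect_equal(fit$rate_ratio_on_off, 0.9, tolerance = 0.05)
  # zero exposure rows are dropped with a warning
  tab3 <- tab
  tab3$exposure_s[1] <- 0
  expect_warning(glmm_taprate(tab3, tests = FALSE), "zero-exposure")
})

test_that("tap rates accumulate counts over green ON/OFF intersections", {
  sched <- make_schedule(175, 20)
  green <- cbind(10 + 25 * (0:6), 25 + 25 * (0:6))
  taps <- seq(0.25, 174.75, by = 0.5)          # constant 2 taps/s
  ev <- event_table(taps, 0, rep("tap", length(taps)), "20")
  r <- tap_rates(ev, sched, green)
  expect_equal(r$rate, c(120, 120))
  expect_equal(sum(r$exposure_s), 105)
  # taps only during OFF intervals: ON rate 0
  on_w <- cbind(sched$train_onsets, sched$train_offsets)
  off_taps <- taps[!vapply(taps, function(tp)
    any(tp >= on_w[, 1] & tp < on_w[, 2]), logical(1))]
  ev2 <- event_table(off_taps, 0, rep("tap", length(off_taps)), "20")
  r2 <- tap_rates(ev2, sched, green)
  expect_equal(r2$rate[r2$state == "on"], 0)
  expect_gt(r2$rate[r2$state == "off"], 100)
  # generator with ON 110 / OFF 120 is recovered within sampling error
  cfg <- quick_config(li_tap_coupling = 20)
  recov <- t(vapply(1:20, function(s) {
    ev <- simulate_tapping(sched, cfg, list(on = 0.5, off = 0),
                           base_rate = 120, seed = 1200 + s)
    tap_rates(ev, sched, green_windows_from_events(ev))$rate
  }, numeric(2)))
  expect_equal(mean(recov[, 1]), 110, tolerance = 3)
  expect_equal(mean(recov[, 2]), 120, tolerance = 3)
})

test_that("effect-size helpers behave on canonical inputs", {
  x <- c(2, 2, 2, 4, 4, 4)
  expect_equal(cohen_d(x), mean(x) / sd(x))
  expect_error(pearson_cor(1:2, 2:3), "length")
})
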