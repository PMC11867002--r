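test_that("identical seeds give bit-identical recordings", {
  cfg <- quick_config(seed = 11)
  a <- simulate_subject(cfg, 2, stim_frequency = 20)
  b <- simulate_subject(cfg, 2, stim_frequency = 20)
  expect_identical(a$data, b$data)
  c <- simulate_subject(cfg, 3, stim_frequency = 20)
  expect_false(identical(a$data, c$data))
})

test_that("the artifact term vanishes identically outside ON windows", {
  cfg <- quick_config(noise_amplitude = 0, beta_amplitude = c(left = 0,
                                                              right = 0),
                      evoked_amplitude = 0)
  raw <- simulate_subject(cfg, 1, stim_frequency = 20)
  sched <- schedule_from_events(raw$events)
  fs <- raw$sample_rate
  outside <- rep(TRUE, ncol(raw$data))
  for (i in seq_along(sched$train_onsets)) {
    # ON window plus the trailing sample of the final biphasic impulse
    i0 <- floor(sched$train_onsets[i] * fs) + 1
    i1 <- round(sched$train_offsets[i] * fs) + 2
    outside[i0:i1] <- FALSE
  }
  expect_true(all(raw$data[, outside] == 0))
  expect_true(any(raw$data[, !outside] != 0))
  # artifact projects onto the wire-path channels only
  quiet <- setdiff(rownames(raw$data),
                   c(raw$layout$groups$wire_right,
                     raw$layout$groups$roi_left))
  expect_true(all(raw$data[quiet, ] == 0))
})

test_that("the response term vanishes before the first train offset", {
  base <- list(quick_config(seed = 5, response_mode = "none"),
               quick_config(seed = 5, response_mode = "induced"),
               quick_config(seed = 5, response_mode = "entrainment"))
  raws <- lapply(base, simulate_subject, subject_index = 1,
                 stim_frequency = 20)
  pre <- seq_len(round(5 * 200))        # samples before the first offset
  expect_identical(raws[[1]]$data[, pre], raws[[2]]$data[, pre])
  expect_identical(raws[[1]]$data[, pre], raws[[3]]$data[, pre])
  expect_false(identical(raws[[1]]$data, raws[[2]]$data))
  expect_error(simulate_subject(base[[3]], 1, stim_frequency = NA),
               "entrainment")
})

test_that("a symmetric no-DBS cohort has near-zero beta lateralization", {
  # Welch-spectrum oracle over 20 independent seeds, 480 s each
  lis <- vapply(1:20, function(s) {
    cfg <- quick_config(duration = 480, n_ch = 2, seed = 100 + s,
                        response_mode = "none", aftereffect_gain = 0)
    raw <- simulate_subject(cfg, 1, stim_frequency = NA)
    L <- welch_band_power(raw$data["L01", ], 200, c(13, 26))
    R <- welch_band_power(raw$data["R01", ], 200, c(13, 26))
    (L - R) / (L + R)
  }, numeric(1))
  expect_lt(max(abs(lis)), 0.05)
})

test_that("doubling one hemisphere's beta amplitude gives LI near 0.6", {
  # power scales with amplitude squared: (4 - 1) / (4 + 1) = 0.6; the
  # aperiodic background is kept small so it does not dilute the index
  lis <- vapply(1:4, function(s) {
    cfg <- quick_config(duration = 240, n_ch = 2, seed = 200 + s,
                        beta_amplitude = c(left = 2, right = 1),
                        noise_amplitude = 0.3, response_mode = "none")
    raw <- simulate_subject(cfg, 1, stim_frequency = NA)
    L <- welch_band_power(raw$data["L01", ], 200, c(12, 18))
    R <- welch_band_power(raw$data["R01", ], 200, c(12, 18))
    (L - R) / (L + R)
  }, numeric(1))
  expect_equal(mean(lis), 0.6, tolerance = 0.05)
})

test_that("the beta oscillator peaks at its configured frequency", {
  cfg <- quick_config(duration = 240, n_ch = 2, seed = 9,
                      noise_amplitude = 0, response_mode = "none")
  raw <- simulate_subject(cfg, 1, stim_frequency = NA)
  sp <- stats::spec.pgram(stats::ts(raw$data["L01", ], frequency = 200),
                          spans = c(11, 11), plot = FALSE)
  peak <- sp$freq[which.max(sp$spec)]
  expect_lt(abs(peak - cfg$beta_center_freq), 1)
  # with the 1/f background the spectrum still shows a beta-band local
  # maximum, tilted at most a couple of Hz toward lower frequencies
  cfg2 <- quick_config(duration = 480, n_ch = 2, seed = 9,
                       response_mode = "none")
  raw2 <- simulate_subject(cfg2, 1, stim_frequency = NA)
  sp2 <- stats::spec.pgram(stats::ts(raw2$data["L01", ], frequency = 200),
                           spans = c(25, 25), plot = FALSE)
  sel <- sp2$freq > 8 & sp2$freq < 30
  peak2 <- sp2$freq[sel][which.max(sp2$spec[sel])]
  expect_lt(abs(peak2 - cfg$beta_center_freq), 2.5)
})

test_that("post-offset phase is locked in entrainment mode, uniform in induced mode", {
  # matched-filter phase at the stimulation frequency per train, high SNR
  train_phases <- function(mode, seed) {
    cfg <- quick_config(duration = 240, seed = seed, response_mode = mode,
                        beta_amplitude = c(left = 2, right = 2),
                        noise_amplitude = 0.5)
    # gain = 3: a strong response, so the phase estimate is SNR-limited by
    # the beta background as little as possible
    raw <- simulate_subject(cfg, 1, stim_frequency = 26, gain = 3)
    sched <- schedule_from_events(raw$events)
    fs <- raw$sample_rate
    x <- colMeans(raw$data[raw$layout$groups$roi_left, , drop = FALSE])
    vapply(sched$train_offsets, function(off) {
      idx <- round(off * fs) + round(0.02 * fs):round(0.08 * fs)
      tt <- (idx - 1) / fs - off
      Arg(sum(x[idx] * exp(-2i * pi * 26 * tt)))
    }, numeric(1))
  }
  ph_e <- train_phases("entrainment", 31)
  rbar_e <- Mod(mean(exp(1i * ph_e)))
  expect_lt(1 - rbar_e, 0.1)            # circular variance < 0.1
  ph_i <- train_phases("induced", 31)
  rbar_i <- Mod(mean(exp(1i * ph_i)))
  n <- length(ph_i)
  rayleigh_p <- exp(-n * rbar_i^2)
  expect_gt(rayleigh_p, 0.01)           # no phase alignment
})

test_that("tap events respect cues, rates and coupling sign", {
  cfg <- quick_config(li_tap_coupling = 0)
  sched <- make_schedule(175, 20)
  ev <- simulate_tapping(sched, cfg, list(on = 0.5, off = 0), seed = 2)
  taps <- ev$onset[ev$event_type == "tap"]
  green <- green_windows_from_events(ev)
  in_green <- vapply(taps, function(tp)
    any(tp >= green[, 1] & tp < green[, 2]), logical(1))
  expect_true(all(in_green))
  # coupling 0: ON and OFF rates both near the 120/min base
  rates <- do.call(rbind, lapply(1:5, function(s) {
    ev <- simulate_tapping(sched, cfg, list(on = 0.5, off = 0), seed = s)
    tap_rates(ev, sched, green_windows_from_events(ev))$rate
  }))
  expect_equal(mean(rates[, 1]), 120, tolerance = 5)   # ON
  expect_equal(mean(rates[, 2]), 120, tolerance = 5)   # OFF
  # positive coupling with positive ON lateralization slows ON tapping
  cfg2 <- quick_config(li_tap_coupling = 30)
  gt <- attr(simulate_tapping(sched, cfg2, list(on = 0.5, off = 0),
                              seed = 3), "ground_truth")
  expect_lt(max(gt$true_rate[gt$state == "on"]),
            min(gt$true_rate[gt$state == "off"]))
  # negative implied rate is clipped and flagged
  ev3 <- simulate_tapping(sched, quick_config(li_tap_coupling = 500),
                          list(on = 1, off = 0), base_rate = 100, seed = 4)
  expect_true(attr(ev3, "clipped"))
})

test_that("expected tap count over the green time matches rate x exposure", {
  # 7 blocks x 15 s green = 105 s at 120/min -> about 210 taps; the gamma
  # renewal restarts at segment boundaries, costing a fraction of a tap
  # per segment, so the Monte-Carlo mean sits within a few taps of 210
  cfg <- quick_config(li_tap_coupling = 0)
  counts <- vapply(1:100, function(s) {
    ev <- simulate_tapping(NULL, cfg, 0, base_rate = 120, seed = 400 + s)
    sum(ev$event_type == "tap")
  }, numeric(1))
  expect_lt(abs(mean(counts) - 210), 5)
})

test_that("cohorts are reproducible and couple tap slowing to lateralization", {
  cfg <- quick_config(n_subjects = 4, duration = 24, seed = 77)
  p1 <- cohort_parameters(cfg)
  p2 <- cohort_parameters(cfg)
  expect_identical(p1, p2)
  co <- simulate_cohort(cfg, conditions = 20, rest = TRUE, tapping = TRUE)
  co2 <- simulate_cohort(cfg, conditions = 20, rest = TRUE, tapping = TRUE)
  expect_identical(co$subjects[[2]][["20"]]$rest$data,
                   co2$subjects[[2]][["20"]]$rest$data)
  expect_identical(
    co$subjects[[3]][["20"]]$tapping$raw$events$onset,
    co2$subjects[[3]][["20"]]$tapping$raw$events$onset)
  # across cohort draws, true delta-LI and realized delta-rate correlate
  # negatively when coupling is on, not when it is off
  draw_r <- function(coupling, seed) {
    cfg <- quick_config(n_subjects = 14, seed = seed,
                        li_tap_coupling = coupling)
    pars <- cohort_parameters(cfg)
    # three sessions per subject, as in a multi-condition protocol
    drate <- vapply(seq_len(14), function(s) {
      mean(vapply(c(10, 20, 26), function(f) {
        sched <- make_schedule(175, f)
        ev <- simulate_tapping(sched, cfg,
                               list(on = pars$li_on[s],
                                    off = pars$li_off[s]),
                               base_rate = pars$base_rate[s],
                               seed = seed * 1000 + s * 37 + f)
        r <- tap_rates(ev, sched, green_windows_from_events(ev))
        r$rate[r$state == "on"] - r$rate[r$state == "off"]
      }, numeric(1)))
    }, numeric(1))
    stats::cor(pars$li_on - pars$li_off, drate)
  }
  r_on <- vapply(1:20, function(s) draw_r(20, 500 + s), numeric(1))
  expect_gte(mean(r_on < 0), 0.9)
  r_off <- vapply(1:20, function(s) draw_r(0, 600 + s), numeric(1))
  expect_lt(abs(mean(r_off)), 0.2)
})
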