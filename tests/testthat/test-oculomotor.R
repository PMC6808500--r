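test_that("REOG is the mean of the EOG channels minus Pz", {
  ses <- stub_session(dur = 10)
  lay <- channel_layout()
  # all EOG equal to Pz -> zero
  ses$signals["Pz", ] <- sin(seq_len(ncol(ses$signals)) / 50)
  for (ch in lay$eog) ses$signals[ch, ] <- ses$signals["Pz", ]
  expect_lt(max(abs(compute_reog(ses))), 1e-12)

  # EOG = Pz + c -> constant c
  for (ch in lay$eog) ses$signals[ch, ] <- ses$signals["Pz", ] + 3
  expect_equal(unname(range(compute_reog(ses))), c(3, 3))

  # a spike on one EOG channel appears at 1/6 amplitude
  ses$signals[lay$eog[1], 500] <- ses$signals[lay$eog[1], 500] + 6
  expect_equal(compute_reog(ses)[500], 3 + 1, tolerance = 1e-12)

  ses2 <- ses
  rownames(ses2$signals)[rownames(ses2$signals) == "Pz"] <- "PzX"
  expect_error(compute_reog(ses2), "Pz")
})

test_that("blink detector finds injected templates and applies its rules", {
  fs <- 500
  ses <- stub_session(dur = 60)
  set.seed(5)
  ses$signals["EOG_LA", ] <- rnorm(60 * fs, sd = 2)
  ses$signals["EOG_LB", ] <- rnorm(60 * fs, sd = 2)
  tpl <- 75 * (1 + cos(2 * pi * seq(-100, 100) / 200))  # 150 uV, 400 ms
  times <- c(10, 25, 40)
  for (t0 in times) {
    idx <- round(t0 * fs) + seq(-100, 100)
    ses$signals["EOG_LA", idx] <- ses$signals["EOG_LA", idx] + tpl / 2
    ses$signals["EOG_LB", idx] <- ses$signals["EOG_LB", idx] - tpl / 2
  }
  bl <- detect_blinks(ses)
  expect_equal(nrow(bl), 3)
  expect_true(all(abs(bl$t_peak - times) <= 0.02))
  expect_true(all(bl$peak_amp > 100))

  # flat signal: nothing detected
  expect_equal(nrow(detect_blinks(stub_session(dur = 30))), 0)

  # two threshold crossings 50 ms apart merge into one blink
  ses2 <- stub_session(dur = 30)
  idx1 <- round(10 * fs) + seq(-100, 100)
  ses2$signals["EOG_LA", idx1] <- tpl / 2
  ses2$signals["EOG_LB", idx1] <- -tpl / 2
  # carve a 30 ms sub-threshold notch so the 20 uV level is crossed twice
  notch <- round(10 * fs) + seq(-8, 8)
  ses2$signals["EOG_LA", notch] <- 5
  ses2$signals["EOG_LB", notch] <- -5
  expect_equal(nrow(detect_blinks(ses2)), 1)

  ses3 <- stub_session(dur = 10)
  rownames(ses3$signals)[rownames(ses3$signals) == "EOG_LA"] <- "X"
  expect_error(detect_blinks(ses3), "EOG")
})

test_that("saccade detector finds spike potentials and groups nearby points", {
  fs <- 500
  ses <- stub_session(dur = 120)
  set.seed(6)
  lay <- channel_layout()
  for (ch in c(lay$eog, "Pz"))
    ses$signals[ch, ] <- rnorm(120 * fs, sd = 1)
  tpl <- walkvep:::spike_template(fs)
  half <- (length(tpl) - 1) / 2
  times <- seq(8, 112, length.out = 10)
  for (t0 in times) {
    idx <- round(t0 * fs) + seq(-half, half)
    for (ch in lay$eog)
      ses$signals[ch, idx] <- ses$signals[ch, idx] + 30 * tpl
  }
  sa <- detect_saccades(ses)
  expect_equal(nrow(sa), 10)
  expect_true(all(vapply(times, function(t) any(abs(sa$t - t) < 0.03),
                         logical(1))))

  # pure 10 Hz signal is outside the 20-90 Hz band: no detections
  ses10 <- stub_session(dur = 60)
  tt <- seq_len(60 * fs) / fs
  for (ch in lay$eog) ses10$signals[ch, ] <- 50 * sin(2 * pi * 10 * tt)
  expect_equal(nrow(detect_saccades(ses10)), 0)
})

test_that("supra-threshold points closer than the merge gaps form one event", {
  # brute-force interval-union oracle for the grouping rule
  oracle_groups <- function(times, gap) {
    times <- sort(times)
    groups <- list()
    for (t in times) {
      placed <- FALSE
      for (i in seq_along(groups)) {
        if (min(abs(groups[[i]] - t)) <= gap + 1e-12) {
          groups[[i]] <- c(groups[[i]], t)
          placed <- TRUE
          break
        }
      }
      if (!placed) groups[[length(groups) + 1]] <- t
    }
    length(groups)
  }
  set.seed(11)
  for (i in 1:30) {
    times <- sort(runif(sample(2:25, 1), 0, 10))
    gap <- sample(c(0.02, 0.1, 0.5, 2), 1)
    grp <- walkvep:::group_time_points(times, gap)
    expect_equal(nrow(grp), oracle_groups(times, gap))
  }
  # two points 10 ms apart with a 20 ms rule: one saccade group
  expect_equal(nrow(walkvep:::group_time_points(c(1.00, 1.01), 0.02)), 1)
  # two head-movement bursts 1 s apart with a 2 s rule: one event
  expect_equal(nrow(walkvep:::group_time_points(c(5, 6), 2)), 1)
})

test_that("spike-potential extraction averages normalised 80 ms windows", {
  fs <- 500
  ses <- stub_session(dur = 100)
  lay <- channel_layout()
  set.seed(8)
  for (ch in c(lay$eog, "Pz"))
    ses$signals[ch, ] <- rnorm(100 * fs, sd = 0.8)
  tpl <- walkvep:::spike_template(fs)
  half_t <- (length(tpl) - 1) / 2
  times <- seq(6, 94, by = 8)
  for (t0 in times) {
    idx <- round(t0 * fs) + seq(-half_t, half_t)
    for (ch in lay$eog)
      ses$signals[ch, idx] <- ses$signals[ch, idx] + 25 * tpl
  }
  sa <- detect_saccades(ses)
  sp <- extract_spike_potential(ses, sa)
  w <- sp$mean_waveform
  expect_equal(nrow(w), 0.08 * fs + 1)
  # trough at the window centre (time 0); amplitude read there
  expect_equal(w$time[which.min(w$amplitude)], 0)
  expect_equal(sp$saccades$spike_amp,
               abs(w$amplitude[w$time == 0]) + 0 * sp$saccades$spike_amp,
               tolerance = 0.35)
  # the mean converges toward template / normaliser: strong negative
  # correlation with the (inverted) template shape at the centre
  centre <- abs(w$time) <= half_t / fs
  tpl_interp <- 25 * tpl
  expect_gt(cor(w$amplitude[centre], tpl_interp), 0.95)
})

test_that("size calibration recovers exact quadratics and round-trips noisy data", {
  # points on an exact quadratic: coefficients recovered to machine precision
  amp <- c(10, 20, 35, 50, 80)
  truth <- c(0.5, -0.02, 0.001)
  size <- truth[1] + truth[2] * amp + truth[3] * amp^2
  cal <- fit_size_calibration(tibble::tibble(size = size, amplitude = amp))
  expect_equal(unname(cal$coef), truth, tolerance = 1e-10)

  expect_error(fit_size_calibration(tibble::tibble(size = c(1, 1, 2),
                                                   amplitude = 1:3)),
               "3 distinct")

  # out-of-range amplitude: clamped estimate with flag
  est <- estimate_saccade_size(cal, c(5, 50, 200))
  expect_equal(attr(est, "clamped"), c(TRUE, FALSE, TRUE))
  expect_equal(est[1], estimate_saccade_size(cal, 10)[1])

  # generator round trip: sizes recovered within 10% for 0.2-5 degrees
  set.seed(12)
  coefs <- sim_config(seed = 1)$saccade_amp_coef
  sizes <- c(0.1, 0.2, 0.5, 1, 5)
  pts <- purrr::map_dfr(sizes, function(s) tibble::tibble(
    size = s,
    amplitude = mean(coefs[1] + coefs[2] * s + coefs[3] * s^2 +
                       rnorm(20, 0, 1.5))))
  cal2 <- fit_size_calibration(pts)
  test_s <- c(0.2, 0.5, 1, 2, 5)
  amp_true <- coefs[1] + coefs[2] * test_s + coefs[3] * test_s^2
  est2 <- estimate_saccade_size(cal2, amp_true)
  expect_true(all(abs(est2 - test_s) / test_s < 0.10))
})

test_that("head-movement detector flags bursts and honours the 2 s window", {
  fs <- 500
  # constant rotational velocity: no events
  ses <- stub_session(dur = 60)
  ses$gyro[] <- 5
  expect_equal(nrow(detect_head_movements(ses)), 0)

  # one injected burst against smooth noise: one event
  mk_gyro_session <- function(burst_times) {
    s <- stub_session(dur = 120)
    set.seed(13)
    for (i in 1:3)
      s$gyro[i, ] <- stats::filter(rnorm(120 * fs, sd = 4), rep(1, 25) / 25,
                                   circular = TRUE)
    bt <- seq(-0.45, 0.45, by = 1 / fs)
    burst <- 160 * exp(-bt^2 / (2 * 0.12^2)) * sin(2 * pi * 2 * bt)
    for (t0 in burst_times) {
      idx <- round(t0 * fs) + seq_along(bt) - round(0.45 * fs)
      s$gyro[1, idx] <- s$gyro[1, idx] + burst
    }
    s
  }
  one <- detect_head_movements(mk_gyro_session(60))
  expect_equal(nrow(one), 1)
  expect_true(one$t_start[1] < 60 & one$t_end[1] > 59)

  # two bursts 1 s apart fall into the same 2 s window: one event
  two_close <- detect_head_movements(mk_gyro_session(c(60, 61)))
  expect_equal(nrow(two_close), 1)
  # well-separated bursts stay distinct
  two_far <- detect_head_movements(mk_gyro_session(c(40, 80)))
  expect_equal(nrow(two_far), 2)
})

test_that("detectors reach recall and precision >= 0.9 at generator-default SNR", {
  ses <- cached_session(seed = 7, n_blocks = 2)
  gt <- ses$ground_truth

  bl <- detect_blinks(ses)
  m_bl <- match_events(bl$t_peak, gt$blinks$time, tol = 0.05)
  expect_gte(m_bl["recall"], 0.9)
  expect_gte(m_bl["precision"], 0.9)

  sa <- detect_saccades(ses)
  m_sa <- match_events(sa$t, gt$saccades$time, tol = 0.05)
  expect_gte(m_sa["recall"], 0.9)
  expect_gte(m_sa["precision"], 0.9)

  hm <- detect_head_movements(ses)
  m_hm <- match_events((hm$t_start + hm$t_end) / 2, gt$head_moves$time, tol = 1)
  expect_gte(m_hm["recall"], 0.9)
  expect_gte(m_hm["precision"], 0.9)
})

test_that("per-trial event counts follow the half-open window convention", {
  trials <- tibble::tibble(trial_id = 1:3,
                           t_start = c(0, 10, 20), t_end = c(2, 12, 22))
  blinks <- tibble::tibble(t_peak = c(0, 1.999, 2.0, 11, 25))
  out <- count_events_per_trial(trials, blinks = blinks)
  # event exactly at t_start counts; event at t_end does not
  expect_equal(out$n_blinks, c(2L, 1L, 0L))
  # no events -> zeros
  out0 <- count_events_per_trial(trials,
                                 saccades = tibble::tibble(t = numeric(0)))
  expect_equal(out0$n_saccades, c(0L, 0L, 0L))
  # conservation: counts never exceed the total number of events
  expect_lte(sum(out$n_blinks), nrow(blinks))
})
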