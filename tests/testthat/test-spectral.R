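test_that("welch_psd equals a direct-FFT oracle on single-window inputs", {
  fs <- 500
  set.seed(2)
  x <- rnorm(fs)  # exactly one 1-s window: Welch = single tapered periodogram
  ps <- welch_psd(x, fs)
  # independent oracle: direct periodogram with Hamming taper, density scaling
  n <- length(x)
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1))
  seg <- (x - mean(x)) * w
  X <- fft(seg)[1:(n / 2 + 1)]
  p <- Mod(X)^2 / (fs * sum(w^2))
  p[2:(n / 2)] <- 2 * p[2:(n / 2)]
  expect_equal(ps$power, p, tolerance = 1e-12)
})

test_that("welch_psd localises sinusoids and conserves noise power", {
  fs <- 500
  t <- seq(0, 2 - 1 / fs, by = 1 / fs)
  ps <- welch_psd(sin(2 * pi * 15 * t), fs)
  expect_equal(ps$freq[which.max(ps$power)], 15)
  expect_equal(diff(ps$freq)[1], 1)           # exact 1 Hz grid
  expect_equal(max(ps$freq), 250)

  # zero in, zero out
  expect_true(all(welch_psd(numeric(1000), fs)$power == 0))

  # Parseval: total power of white noise ~ its variance (10 averages)
  set.seed(3)
  tot <- mean(replicate(10, sum(welch_psd(rnorm(5500, sd = 1.5), fs)$power)))
  expect_equal(tot, 1.5^2, tolerance = 0.05)

  # too-short input errors
  expect_error(welch_psd(numeric(100), fs), "shorter")
})

test_that("channel selection finds the SSVEP-bearing channels", {
  # synthetic spectra: channels O1, Oz, O2 carry strong 15 Hz power
  chans <- channel_layout()$occipital_pool
  spectra <- tidyr::expand_grid(trial_id = 1:6, channel = chans,
                                freq = 0:50) |>
    dplyr::mutate(power = 1 + (freq == 15) *
                    ifelse(channel %in% c("O1", "Oz", "O2"), 5, 0.5))
  expect_setequal(select_channels(spectra, 3), c("O1", "Oz", "O2"))

  # equal power everywhere: first n pool labels (deterministic tie rule)
  flat <- dplyr::mutate(spectra, power = 1)
  expect_equal(select_channels(flat, 2), chans[1:2])
  # n = 1 is the argmax channel
  one <- dplyr::mutate(spectra,
                       power = 1 + (freq == 15) * (channel == "POz") * 9)
  expect_equal(select_channels(one, 1), "POz")
  expect_error(select_channels(spectra, 10), "pool")
})

test_that("referenced power is target minus mean of references", {
  sp <- tibble::tibble(freq = 10:20,
                       power = c(1, 1, 1, 1, 1, 5, 1, 1, 1, 1, 1))
  expect_equal(referenced_power(sp, 15, c(13, 14, 16, 17)), 4)
  flat <- tibble::tibble(freq = 0:30, power = rep(2, 31))
  expect_equal(referenced_power(flat, 15, c(13, 14, 16, 17)), 0)
  expect_error(referenced_power(sp, 15.5, c(13, 14)), "off the spectral grid")

  # 17 Hz referenced to {15,16,18,19} turns negative on SSVEP-bearing data
  # (the 15 Hz peak inflates the reference mean)
  fs <- 500
  t <- seq(0, 35 - 1 / fs, by = 1 / fs)
  set.seed(8)
  x <- 2 * sin(2 * pi * 15 * t) + rnorm(length(t), sd = 1)
  ps <- welch_psd(x, fs)
  expect_lt(referenced_power(ps, 17, c(15, 16, 18, 19)), 0)
})

test_that("peak alpha frequency is estimated from still trials inside the band", {
  trials <- tibble::tibble(trial_id = 1:4,
                           condition = c("still", "still", "slow", "slow"))
  mk <- function(peak_freq, ids) {
    tidyr::expand_grid(trial_id = ids, channel = "Oz", freq = 0:30) |>
      dplyr::mutate(power = 1 + 3 * (freq == peak_freq))
  }
  # synthetic alpha at 10 Hz in still trials, 9 Hz in walking trials
  spectra <- dplyr::bind_rows(mk(10, 1:2), mk(9, 3:4))
  expect_equal(peak_alpha(spectra, trials), 10)

  # two equal peaks: the lower frequency wins
  sp2 <- tidyr::expand_grid(trial_id = 1:2, channel = "Oz", freq = 0:30) |>
    dplyr::mutate(power = 1 + 3 * (freq %in% c(9, 11)))
  expect_equal(peak_alpha(sp2, trials[1:2, ]), 9)

  # a larger out-of-band peak is ignored: the in-band maximum is returned
  sp3 <- tidyr::expand_grid(trial_id = 1:2, channel = "Oz", freq = 0:30) |>
    dplyr::mutate(power = 1 + 10 * (freq == 13) + 3 * (freq == 11))
  expect_equal(peak_alpha(sp3, trials[1:2, ]), 11)
  expect_error(peak_alpha(sp3, trials[3:4, ]), "no trials")
})

test_that("Hilbert envelope recovers amplitude and tracks amplitude steps", {
  fs <- 500
  t <- seq(0, 35 - 1 / fs, by = 1 / fs)
  A <- 2.4
  env <- hilbert_envelope(A * sin(2 * pi * 15 * t), fs)
  core <- env$amplitude[!env$edge]
  expect_lt(max(abs(core - A)) / A, 0.02)

  # zero signal -> zero envelope
  env0 <- hilbert_envelope(numeric(10 * fs), fs)
  expect_lt(max(env0$amplitude), 1e-8)

  # amplitude step A -> A/2 at mid-epoch is tracked within the filter rise time
  x <- ifelse(t < 17.5, A, A / 2) * sin(2 * pi * 15 * t)
  envs <- hilbert_envelope(x, fs)
  before <- envs$amplitude[t > 15 & t < 16.5]
  after <- envs$amplitude[t > 18.5 & t < 20]
  expect_equal(mean(before), A, tolerance = 0.03)
  expect_equal(mean(after), A / 2, tolerance = 0.03)
  expect_error(hilbert_envelope(x, fs, band = c(240, 260)), "Nyquist")
})

test_that("target-evoked perturbation recovers an injected amplitude dip", {
  fs <- 500
  t <- seq(0, 35 - 1 / fs, by = 1 / fs)
  targets <- c(8, 14, 20, 26)
  A <- 2
  # 30% dip covering the post-target analysis window plus the rise time of
  # the (short) envelope filter used here, so the window sees the full dip
  amp <- rep(A, length(t))
  for (tt in targets) amp[t >= tt & t <= tt + 1.0] <- 0.7 * A
  env <- hilbert_envelope(amp * sin(2 * pi * 15 * t), fs,
                          fir_s = 0.2, edge_s = 0.1)

  pert <- evoked_perturbation(env, targets, mode = "mean_200_600")
  expect_equal(pert$value / pert$baseline, 0.7, tolerance = 0.04)

  # no modulation: statistic matches baseline
  env_flat <- hilbert_envelope(A * sin(2 * pi * 15 * t), fs,
                               fir_s = 0.2, edge_s = 0.1)
  pert_flat <- evoked_perturbation(env_flat, targets, mode = "mean_200_600")
  expect_equal(pert_flat$value, pert_flat$baseline, tolerance = 0.02)

  # min over [0.2, 1] never exceeds the mean over [0.2, 0.6]
  pmin_ <- evoked_perturbation(env, targets, mode = "min_200_1000")
  expect_lte(pmin_$value, pert$value)
  expect_equal(pmin_$value_signed, -pmin_$value)

  expect_error(evoked_perturbation(env, 34.9), "full post-target")
})

test_that("referenced SSVEP power increases with injected amplitude through the full path", {
  # rank correlation 1 across an amplitude grid (single-period sessions)
  amps <- c(0.5, 1.5, 3)
  refp <- vapply(amps, function(a) {
    mean(vapply(1:5, function(s) {
      cfg <- tiny_config(seed = 300 + s, amp = a)
      ses <- synthesize_signals(cfg, make_event_schedule(cfg))
      onset <- ses$events$time[ses$events$kind == "contrast_onset"][1]
      i0 <- round(onset * 500) + 1
      ps <- welch_psd(ses$signals["Oz", i0:(i0 + 35 * 500 - 1)], 500)
      referenced_power(ps, 15, c(13, 14, 16, 17))
    }, numeric(1)))
  }, numeric(1))
  expect_equal(cor(refp, amps, method = "spearman"), 1)
})

test_that("step-frequency spectrum peaks at the configured gait frequencies", {
  ses <- cached_session(seed = 7, n_blocks = 1)
  sp <- step_frequency_spectrum(ses)
  pk <- sp |>
    dplyr::filter(freq > 0.3, freq < 5) |>
    dplyr::group_by(condition) |>
    dplyr::slice_max(power, n = 1)
  expect_equal(pk$freq[pk$condition == "slow"], 1, tolerance = 0.06)
  expect_equal(pk$freq[pk$condition == "normal"], 1.75, tolerance = 0.06)
})
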