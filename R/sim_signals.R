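#' Channel layout of the synthetic recording system
#'
#' 16 EEG channels, 6 EOG channels (above/below eye and outer canthus for each
#' eye), and 2 earlobe channels, matching a 24-channel mobile amplifier.
#' @return Named list with elements `eeg`, `eog`, `earlobe`, `occipital_pool`.
#' @export
channel_layout <- function() {
  list(
    eeg = c("Fp1", "Fp2", "Fz", "F3", "F4", "Cz", "C3", "C4",
            "P3", "Pz", "P4", "P7", "POz", "O1", "Oz", "O2"),
    eog = c("EOG_LA", "EOG_LB", "EOG_LC", "EOG_RA", "EOG_RB", "EOG_RC"),
    earlobe = c("A1", "A2"),
    occipital_pool = c("POz", "O1", "Oz", "O2")
  )
}

# Scalp weighting of the occipitally generated SSVEP/alpha components.
occipital_weights <- function(labels) {
  w <- setNames(rep(0.05, length(labels)), labels)
  w[c("O1", "Oz", "O2")] <- 1
  w["POz"] <- 0.5
  w[c("P3", "Pz", "P4", "P7")] <- 0.2
  w
}

#' Synthesize the multi-stream signals of a session
#'
#' Generates EEG, EOG, gyroscope and body-motion traces consistent with an
#' event schedule. The EEG is a sum of 1/f background noise, an ongoing alpha
#' oscillation at the participant's peak alpha frequency, a 15 Hz SSVEP whose
#' amplitude follows the condition x contrast amplitude map during each
#' contrast period, a gait-locked component during walking, and high-frequency
#' noise whose level grows with walking speed. Vertical EOG carries raised-
#' cosine blink templates; all EOG channels carry brief biphasic spike
#' potentials at saccade times with amplitude growing quadratically with
#' saccade size; the gyroscope carries head-movement velocity bursts.
#' Ground-truth event lists are returned inside the session.
#'
#' @param cfg A [sim_config()].
#' @param schedule Event table from [make_event_schedule()].
#' @param participant Participant index (selects the random substream).
#' @return A `walk_session` object: list with `signals` (24 x samples matrix,
#'   microvolts, 500 Hz), `gyro` (3 x samples, deg/s), `motion` (3 x samples,
#'   m/s, 120 Hz), `events`, `fs`, `channel_labels`, `ground_truth`,
#'   `alpha_peak`, `participant`.
#' @export
synthesize_signals <- function(cfg, schedule, participant = 1L) {
  validate_sim_config(cfg)
  set.seed(participant_seed(cfg, participant, stream = 2L))
  fs <- cfg$fs_eeg
  dur <- attr(schedule, "recording_s") %||% (max(schedule$time) + 40)
  n <- round(dur * fs)
  tt <- (seq_len(n) - 1) / fs
  lay <- channel_layout()
  labels <- c(lay$eeg, lay$eog, lay$earlobe)
  alpha_peak <- sample(cfg$alpha_peak_choices, 1)

  sig <- matrix(0, nrow = length(labels), ncol = n,
                dimnames = list(labels, NULL))

  blocks <- schedule |>
    dplyr::filter(.data$kind == "block_start") |>
    dplyr::select("time", "condition", "block")
  block_len <- cfg$block_lead_s + cfg$n_periods_per_block * cfg$period_s +
    cfg$block_gap_s
  periods <- schedule |> dplyr::filter(.data$kind == "contrast_onset")

  # per-period correlated log-normal amplitude fluctuation (alpha, ssvep)
  sdj <- cfg$amp_jitter_sd
  z1 <- rnorm(nrow(periods))
  z2 <- cfg$coupling_rho * z1 + sqrt(1 - cfg$coupling_rho^2) * rnorm(nrow(periods))
  mult_alpha <- exp(sdj * z1 - sdj^2 / 2)
  mult_ssvep <- exp(sdj * z2 - sdj^2 / 2)

  w_occ <- occipital_weights(labels)
  alpha_phase <- runif(1, 0, 2 * pi)

  # EEG: per-channel background + shared oscillatory components
  for (b in seq_len(nrow(blocks))) {
    cond <- blocks$condition[b]
    i0 <- t_to_sample(blocks$time[b], fs) + 1L
    i1 <- min(i0 + round(block_len * fs) - 1L, n)
    nb <- i1 - i0 + 1L
    tb <- tt[i0:i1]
    hf_rms <- cfg$hf_noise_map[[cond]]
    gait_f <- if (cond %in% names(cfg$gait_freq_map)) cfg$gait_freq_map[[cond]] else NA
    for (ch in lay$eeg) {
      x <- shaped_noise(nb, fs, cfg$noise_exponent, cfg$noise_rms)
      if (hf_rms > 0) x <- x + band_noise(nb, fs, 20, 99, hf_rms)
      if (!is.na(gait_f)) {
        ph <- runif(2, 0, 2 * pi)
        x <- x + cfg$gait_amp * sin(2 * pi * gait_f * tb + ph[1]) +
          0.5 * cfg$gait_amp * sin(2 * pi * 2 * gait_f * tb + ph[2])
      }
      sig[ch, i0:i1] <- sig[ch, i0:i1] + x
    }
    # ongoing alpha across the whole block at the condition's base amplitude
    alpha_base <- cfg$alpha_amplitude_map[[cond]]
    osc <- sin(2 * pi * alpha_peak * tb + alpha_phase)
    for (ch in lay$eeg)
      sig[ch, i0:i1] <- sig[ch, i0:i1] + w_occ[[ch]] * alpha_base * osc
  }

  # period-locked components: SSVEP plus the per-period alpha fluctuation
  for (p in seq_len(nrow(periods))) {
    i0 <- t_to_sample(periods$time[p], fs) + 1L
    i1 <- min(i0 + round(cfg$period_s * fs) - 1L, n)
    tb <- tt[i0:i1]
    cond <- periods$condition[p]
    amp <- cfg$ssvep_amplitude_map[cond, as.character(periods$contrast[p])] *
      mult_ssvep[p]
    ssvep <- amp * sin(2 * pi * cfg$ssvep_freq * tb)
    alpha_extra <- cfg$alpha_amplitude_map[[cond]] * (mult_alpha[p] - 1) *
      sin(2 * pi * alpha_peak * tb + alpha_phase)
    for (ch in lay$eeg)
      sig[ch, i0:i1] <- sig[ch, i0:i1] + w_occ[[ch]] * (ssvep + alpha_extra)
  }

  # EOG background: steeper spectral slope than EEG (ocular potentials are
  # dominated by slow components)
  for (ch in lay$eog)
    sig[ch, ] <- shaped_noise(n, fs, cfg$eog_noise_exponent, cfg$eog_noise_rms)
  for (ch in lay$earlobe)
    sig[ch, ] <- shaped_noise(n, fs, cfg$noise_exponent, 1)

  # blinks: raised-cosine templates on above/below-eye channels (binocular)
  blink_times <- draw_event_times(dur, cfg$blink_rate, min_gap = 0.6)
  tpl_b <- blink_template(fs)
  half_b <- (length(tpl_b) - 1) / 2
  for (t0 in blink_times) {
    idx <- t_to_sample(t0, fs) + 1L + seq(-half_b, half_b)
    keep <- idx >= 1 & idx <= n
    for (ch in c("EOG_LA", "EOG_RA"))
      sig[ch, idx[keep]] <- sig[ch, idx[keep]] + cfg$blink_amp / 2 * tpl_b[keep]
    for (ch in c("EOG_LB", "EOG_RB"))
      sig[ch, idx[keep]] <- sig[ch, idx[keep]] - cfg$blink_amp / 2 * tpl_b[keep]
  }

  # saccadic spike potentials on all six EOG channels
  sac_times <- draw_event_times(dur, cfg$saccade_rate, min_gap = 0.25)
  sizes <- exp(runif(length(sac_times), log(cfg$saccade_size_range[1]),
                     log(cfg$saccade_size_range[2])))
  amps <- spike_amplitude(sizes, cfg$saccade_amp_coef)
  tpl_s <- spike_template(fs)
  half_s <- (length(tpl_s) - 1) / 2
  for (k in seq_along(sac_times)) {
    idx <- t_to_sample(sac_times[k], fs) + 1L + seq(-half_s, half_s)
    keep <- idx >= 1 & idx <= n
    for (ch in lay$eog)
      sig[ch, idx[keep]] <- sig[ch, idx[keep]] + amps[k] * tpl_s[keep]
  }

  # gyroscope: smooth (band-limited) baseline noise, gait rotation,
  # head-movement bursts; head angular velocity has no white component
  gyro <- do.call(rbind, lapply(1:3, function(i)
    band_noise(n, fs, 0, 10, rms = cfg$gyro_noise_rms)))
  dimnames(gyro) <- list(c("gyro_x", "gyro_y", "gyro_z"), NULL)
  for (b in seq_len(nrow(blocks))) {
    cond <- blocks$condition[b]
    if (!cond %in% names(cfg$gait_freq_map)) next
    i0 <- t_to_sample(blocks$time[b], fs) + 1L
    i1 <- min(i0 + round(block_len * fs) - 1L, n)
    gait_f <- cfg$gait_freq_map[[cond]]
    gyro[1, i0:i1] <- gyro[1, i0:i1] +
      10 * sin(2 * pi * gait_f * tt[i0:i1] + runif(1, 0, 2 * pi))
  }
  head_times <- draw_event_times(dur, cfg$head_move_rate, min_gap = 5)
  burst_t <- seq(-0.45, 0.45, by = 1 / fs)
  burst <- exp(-burst_t^2 / (2 * 0.12^2)) * sin(2 * pi * 2 * burst_t)
  half_h <- (length(burst) - 1) / 2
  for (t0 in head_times) {
    idx <- t_to_sample(t0, fs) + 1L + seq(-half_h, half_h)
    keep <- idx >= 1 & idx <= n
    ax <- sample(1:3, 1)
    gyro[ax, idx[keep]] <- gyro[ax, idx[keep]] + cfg$head_move_amp * burst[keep]
  }

  motion <- synth_motion(cfg, blocks, block_len, dur)

  structure(list(
    signals = sig, gyro = gyro, motion = motion,
    events = schedule, fs = list(eeg = fs, motion = cfg$fs_motion),
    channel_labels = lay,
    ground_truth = list(
      blinks = tibble::tibble(time = blink_times, amp = cfg$blink_amp),
      saccades = tibble::tibble(time = sac_times, size = sizes, amp = amps),
      head_moves = tibble::tibble(time = head_times),
      period_multipliers = tibble::tibble(
        period = seq_len(nrow(periods)), alpha = mult_alpha, ssvep = mult_ssvep)
    ),
    alpha_peak = alpha_peak, participant = participant,
    recording_s = dur
  ), class = "walk_session")
}

# Poisson event stream thinned to a minimum inter-event gap.
draw_event_times <- function(dur, rate_per_min, min_gap) {
  k <- rpois(1, rate_per_min / 60 * dur)
  if (k == 0) return(numeric(0))
  t <- sort(runif(k, 1, dur - 1))
  keep <- c(TRUE, diff(t) > min_gap)
  while (!all(keep)) {
    t <- t[keep]
    keep <- c(TRUE, diff(t) > min_gap)
  }
  t
}

# 400 ms raised-cosine blink on the vertical EOG difference, unit peak.
blink_template <- function(fs, width_s = 0.4) {
  half <- round(width_s / 2 * fs)
  t <- seq(-half, half) / fs
  0.5 * (1 + cos(2 * pi * t / width_s))
}

# Brief biphasic spike-potential wavelet (Ricker), trough of -1 at its
# centre; sigma 4 ms puts its spectral peak near 56 Hz, inside the 20-90 Hz
# detection band.
spike_template <- function(fs, sigma_s = 0.004) {
  half <- round(3 * sigma_s * fs)
  t <- seq(-half, half) / fs
  -(1 - (t / sigma_s)^2) * exp(-t^2 / (2 * sigma_s^2))
}

# Quadratic size -> amplitude mapping of the spike potential (uV).
spike_amplitude <- function(size, coef) {
  coef[1] + coef[2] * size + coef[3] * size^2
}

# Body/ankle speed traces at the motion sampling rate.
synth_motion <- function(cfg, blocks, block_len, dur) {
  fsm <- cfg$fs_motion
  nm <- round(dur * fsm)
  tm <- (seq_len(nm) - 1) / fsm
  speed_map <- c(still = 0.02, slow = 0.8, normal = 1.4)
  m <- matrix(rnorm(3 * nm, sd = 0.05), nrow = 3,
              dimnames = list(c("back", "ankle_l", "ankle_r"), NULL))
  for (b in seq_len(nrow(blocks))) {
    cond <- blocks$condition[b]
    i0 <- t_to_sample(blocks$time[b], fsm) + 1L
    i1 <- min(i0 + round(block_len * fsm) - 1L, nm)
    base <- speed_map[[cond]] %||% 0.02
    m[, i0:i1] <- m[, i0:i1] + base
    if (cond %in% names(cfg$gait_freq_map)) {
      gf <- cfg$gait_freq_map[[cond]]
      tb <- tm[i0:i1]
      m["back", i0:i1] <- m["back", i0:i1] + 0.1 * sin(2 * pi * gf * tb)
      # alternating feet: each ankle swings at half the step frequency, the
      # summed speed of both ankles then peaks at the step frequency gf
      m["ankle_l", i0:i1] <- m["ankle_l", i0:i1] +
        0.5 * base * abs(sin(pi * gf / 2 * tb))
      m["ankle_r", i0:i1] <- m["ankle_r", i0:i1] +
        0.5 * base * abs(sin(pi * gf / 2 * tb + pi / 2))
    }
  }
  m
}

#' @export
print.walk_session <- function(x, ...) {
  cat("<walk_session>\n")
  cat("  participant:", x$participant, " duration:",
      round(x$recording_s), "s @", x$fs$eeg, "Hz\n")
  cat("  channels:", nrow(x$signals), "(EEG/EOG/earlobe) + 3 gyro + 3 motion\n")
  cat("  events:", nrow(x$events), "rows;",
      sum(x$events$kind == "target_onset"), "targets\n")
  invisible(x)
}
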