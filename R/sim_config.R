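#' Simulation configuration for synthetic free-walking SSVEP sessions
#'
#' Builds the configuration object that fully determines a synthetic session
#' (together with its seed). Defaults encode the experimental design the
#' package analyses: three walking conditions (standing still, slow walking, normal
#' walking), four surround-contrast levels (0, 33, 67, 100%), seven testing
#' blocks per condition, 35-second contrast periods each containing six
#' targets, and a 15 Hz flickering central grating driving the SSVEP.
#'
#' Amplitude maps are free parameters in microvolts (no ground-truth source
#' amplitudes exist to calibrate them against); the defaults encode the qualitative structure
#' the analysis is designed to detect: surround-contrast suppression of the
#' SSVEP that is present during walking but not during standing, alpha power
#' decreasing with walking speed, and broadband/high-frequency noise increasing
#' with walking speed.
#'
#' @param seed Integer seed; the same configuration (including seed) yields a
#'   bit-identical session.
#' @param n_participants Number of participants to simulate.
#' @param n_blocks Testing blocks per walking condition (default 7).
#' @param walking_conditions Character vector of condition labels, ordered.
#' @param contrast_levels Surround contrast levels as fractions in `[0, 1]`.
#' @param ssvep_freq Flicker frequency in Hz.
#' @param ssvep_amplitude_map Matrix (condition x contrast) of SSVEP source
#'   amplitudes, microvolts.
#' @param alpha_amplitude_map Named numeric vector (per condition) of alpha
#'   amplitudes, microvolts.
#' @param alpha_peak_choices Integer Hz values from which each participant's
#'   peak alpha frequency is drawn.
#' @param noise_exponent Spectral slope a of the 1/f^a background noise.
#' @param noise_rms RMS of the broadband background noise, microvolts.
#' @param hf_noise_map Named numeric vector (per condition): RMS of additional
#'   flat 20-99 Hz noise, microvolts.
#' @param gait_freq_map Named numeric vector of step frequencies in Hz for the
#'   walking conditions.
#' @param gait_amp Amplitude of the gait-locked EEG component, microvolts.
#' @param coupling_rho Correlation between per-period alpha and SSVEP amplitude
#'   fluctuations (emulating the positive alpha-SSVEP association).
#' @param amp_jitter_sd Log-scale SD of per-period amplitude fluctuations.
#' @param blink_rate Blinks per minute on vertical EOG.
#' @param blink_amp Peak amplitude of the blink template on the vertical EOG
#'   difference signal, microvolts.
#' @param saccade_rate Saccades per minute.
#' @param saccade_amp_coef Quadratic coefficients `c(a0, a1, a2)` mapping
#'   saccade size s (degrees) to spike-potential amplitude a0 + a1 s + a2 s^2
#'   (microvolts on each EOG channel).
#' @param saccade_size_range Range (degrees) from which saccade sizes are drawn
#'   (log-uniform).
#' @param head_move_rate Strong head movements per minute during walking.
#' @param head_move_amp Peak rotational velocity of a head-movement burst,
#'   deg/s.
#' @param eog_noise_rms RMS of EOG background noise, microvolts.
#' @param eog_noise_exponent Spectral slope of the EOG background noise.
#' @param gyro_noise_rms RMS of gyroscope background noise, deg/s.
#' @param stimulus_level Target contrast used in the main task (titrated level).
#' @param observer_threshold_map Matrix (condition x contrast) of psychometric
#'   thresholds in contrast units.
#' @param observer_slope Psychometric slope (SD of the cumulative Gaussian).
#' @param lapse_rate Lapse rate of the simulated observer.
#' @param false_alarm_rate_map Named numeric vector: spontaneous button presses
#'   per minute per condition.
#' @param rt_shift,rt_meanlog,rt_sdlog Shifted log-normal reaction-time model:
#'   RT = rt_shift + lognormal(rt_meanlog, rt_sdlog), seconds.
#' @param fs_eeg,fs_motion Sampling rates (Hz) of the EEG/EOG/gyro stream and
#'   the body-motion stream.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, n_blocks = 1)
#' cfg$ssvep_freq
sim_config <- function(seed = 1L,
                       n_participants = 1L,
                       n_blocks = 7L,
                       walking_conditions = c("still", "slow", "normal"),
                       contrast_levels = c(0, 0.33, 0.67, 1),
                       ssvep_freq = 15,
                       ssvep_amplitude_map = default_ssvep_map(walking_conditions, contrast_levels),
                       alpha_amplitude_map = c(still = 4.0, slow = 2.8, normal = 2.0),
                       alpha_peak_choices = 9:11,
                       noise_exponent = 1,
                       noise_rms = 4,
                       hf_noise_map = c(still = 1.0, slow = 1.6, normal = 2.2),
                       gait_freq_map = c(slow = 1.0, normal = 1.75),
                       gait_amp = 3,
                       coupling_rho = 0.5,
                       amp_jitter_sd = 0.3,
                       blink_rate = 12,
                       blink_amp = 150,
                       saccade_rate = 24,
                       saccade_amp_coef = c(22, 12, 0.6),
                       saccade_size_range = c(0.1, 5),
                       head_move_rate = 3,
                       head_move_amp = 160,
                       eog_noise_rms = 5,
                       eog_noise_exponent = 1.5,
                       gyro_noise_rms = 4,
                       stimulus_level = 0.5,
                       observer_threshold_map = default_threshold_map(
                         walking_conditions, contrast_levels,
                         stimulus_level, observer_slope = 0.1, lapse_rate = 0.02),
                       observer_slope = 0.1,
                       lapse_rate = 0.02,
                       false_alarm_rate_map = c(still = 0.5, slow = 1.0, normal = 1.5),
                       rt_shift = 0.2,
                       rt_meanlog = log(0.28),
                       rt_sdlog = 0.35,
                       fs_eeg = 500,
                       fs_motion = 120) {
  cfg <- list(
    seed = as.integer(seed), n_participants = as.integer(n_participants),
    n_blocks = as.integer(n_blocks),
    walking_conditions = walking_conditions,
    contrast_levels = contrast_levels,
    ssvep_freq = ssvep_freq,
    ssvep_amplitude_map = ssvep_amplitude_map,
    alpha_amplitude_map = alpha_amplitude_map,
    alpha_peak_choices = alpha_peak_choices,
    noise_exponent = noise_exponent, noise_rms = noise_rms,
    hf_noise_map = hf_noise_map,
    gait_freq_map = gait_freq_map, gait_amp = gait_amp,
    coupling_rho = coupling_rho, amp_jitter_sd = amp_jitter_sd,
    blink_rate = blink_rate, blink_amp = blink_amp,
    saccade_rate = saccade_rate, saccade_amp_coef = saccade_amp_coef,
    saccade_size_range = saccade_size_range,
    head_move_rate = head_move_rate, head_move_amp = head_move_amp,
    eog_noise_rms = eog_noise_rms, eog_noise_exponent = eog_noise_exponent,
    gyro_noise_rms = gyro_noise_rms,
    stimulus_level = stimulus_level,
    observer_threshold_map = observer_threshold_map,
    observer_slope = observer_slope, lapse_rate = lapse_rate,
    false_alarm_rate_map = false_alarm_rate_map,
    rt_shift = rt_shift, rt_meanlog = rt_meanlog, rt_sdlog = rt_sdlog,
    fs_eeg = fs_eeg, fs_motion = fs_motion,
    # experiment design constants
    period_s = 35, n_periods_per_block = length(contrast_levels),
    n_targets_per_period = 6L, target_window = c(5, 31.5),
    soa_range = c(3.5, 6.5), block_lead_s = 2, block_gap_s = 4
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (any(cfg$contrast_levels < 0 | cfg$contrast_levels > 1))
    stop("contrast_levels must lie in [0, 1]", call. = FALSE)
  if (any(cfg$ssvep_amplitude_map < 0) || any(cfg$alpha_amplitude_map < 0) ||
      any(cfg$hf_noise_map < 0))
    stop("amplitude maps must be non-negative", call. = FALSE)
  if (!all(cfg$walking_conditions %in% rownames(cfg$ssvep_amplitude_map)))
    stop("ssvep_amplitude_map must have one row per walking condition",
         call. = FALSE)
  if (cfg$lapse_rate < 0 || cfg$lapse_rate > 1)
    stop("lapse_rate must lie in [0, 1]", call. = FALSE)
  # 6 targets with minimum SOA must fit inside the target window
  min_span <- (cfg$n_targets_per_period - 1) * cfg$soa_range[1]
  if (min_span > diff(cfg$target_window))
    stop("infeasible schedule: SOA range cannot fit ",
         cfg$n_targets_per_period, " targets in the target window",
         call. = FALSE)
  cfg
}

# Default SSVEP amplitude map (uV): surround-contrast suppression present
# during walking, essentially absent while standing still; overall amplitude
# decreasing with walking speed.
default_ssvep_map <- function(conditions, contrasts) {
  base <- rbind(
    still  = c(2.00, 1.97, 1.93, 1.92),
    slow   = c(1.80, 1.60, 1.45, 1.35),
    normal = c(1.70, 1.45, 1.30, 1.20)
  )
  m <- base[conditions, seq_along(contrasts), drop = FALSE]
  dimnames(m) <- list(conditions, as.character(contrasts))
  m
}

# Thresholds chosen so that at the titrated stimulus level the simulated
# observer's per-cell hit probabilities follow the qualitative behavioural
# pattern: high flat rates while standing, strong contrast-dependent decline
# while walking, overall decline with walking speed.
default_hit_rate_map <- function(conditions, contrasts) {
  base <- rbind(
    still  = c(0.82, 0.81, 0.79, 0.77),
    slow   = c(0.62, 0.58, 0.48, 0.40),
    normal = c(0.50, 0.42, 0.32, 0.24)
  )
  m <- base[conditions, seq_along(contrasts), drop = FALSE]
  dimnames(m) <- list(conditions, as.character(contrasts))
  m
}

default_threshold_map <- function(conditions, contrasts, stimulus_level,
                                  observer_slope, lapse_rate) {
  p <- default_hit_rate_map(conditions, contrasts)
  thr <- stimulus_level - observer_slope * qnorm(p / (1 - lapse_rate))
  dimnames(thr) <- dimnames(p)
  thr
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  seed:", x$seed, " participants:", x$n_participants, "\n")
  cat("  design:", length(x$walking_conditions), "conditions x",
      x$n_blocks, "blocks x", length(x$contrast_levels),
      "contrast periods of", x$period_s, "s\n")
  cat("  ssvep:", x$ssvep_freq, "Hz;",
      x$n_targets_per_period, "targets/period\n")
  invisible(x)
}
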