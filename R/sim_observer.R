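#' Psychometric hit probability of the simulated observer
#'
#' Cumulative-Gaussian detection function with a lapse rate:
#' `Psi(x) = (1 - lapse) * pnorm((x - threshold) / slope)`.
#'
#' @param level Stimulus level (contrast units).
#' @param threshold Psychometric threshold (level of 50% detection before
#'   lapses).
#' @param slope SD of the cumulative Gaussian (smaller = steeper).
#' @param lapse Lapse rate in `[0, 1]`.
#' @return Detection probability.
#' @export
psi_detect <- function(level, threshold, slope, lapse = 0) {
  (1 - lapse) * pnorm((level - threshold) / slope)
}

#' Simulate the observer's button presses for a schedule
#'
#' For every target in the schedule the observer detects with probability
#' `Psi(level; threshold(condition, contrast), slope, lapse)`; detections
#' produce a button press after a shifted log-normal reaction time.
#' Spontaneous false-alarm presses are added at a per-condition Poisson rate.
#'
#' @param cfg A [sim_config()].
#' @param schedule Event table from [make_event_schedule()].
#' @param stimulus_level Target contrast presented (defaults to the titrated
#'   level in `cfg`).
#' @param participant Participant index (random substream).
#' @return Tibble of button-press events (`time`, `kind = "button_press"`,
#'   `condition`, `contrast`, `block`), plus a `ground_truth` attribute with
#'   the per-target hit/RT table.
#' @export
simulate_observer <- function(cfg, schedule, stimulus_level = cfg$stimulus_level,
                              participant = 1L) {
  stopifnot(stimulus_level >= 0)
  validate_sim_config(cfg)
  set.seed(participant_seed(cfg, participant, stream = 3L))

  targets <- schedule |> dplyr::filter(.data$kind == "target_onset")
  thr <- cfg$observer_threshold_map[cbind(targets$condition,
                                          as.character(targets$contrast))]
  p_hit <- psi_detect(stimulus_level, thr, cfg$observer_slope, cfg$lapse_rate)
  hit <- runif(nrow(targets)) < p_hit
  rt <- cfg$rt_shift + rlnorm(nrow(targets), cfg$rt_meanlog, cfg$rt_sdlog)

  presses <- tibble::tibble(
    time = targets$time[hit] + rt[hit],
    kind = "button_press",
    condition = targets$condition[hit],
    contrast = targets$contrast[hit],
    block = targets$block[hit],
    target_location = NA_character_)

  # spontaneous presses during each block at the condition's false-alarm rate
  blocks <- schedule |> dplyr::filter(.data$kind == "block_start")
  block_len <- cfg$block_lead_s + cfg$n_periods_per_block * cfg$period_s
  fa <- purrr::map_dfr(seq_len(nrow(blocks)), function(b) {
    rate <- cfg$false_alarm_rate_map[[blocks$condition[b]]]
    k <- rpois(1, rate / 60 * block_len)
    if (k == 0) return(NULL)
    tibble::tibble(
      time = blocks$time[b] + runif(k, 0, block_len),
      kind = "button_press", condition = blocks$condition[b],
      contrast = NA_real_, block = blocks$block[b],
      target_location = NA_character_)
  })

  out <- dplyr::bind_rows(presses, fa) |> dplyr::arrange(.data$time)
  attr(out, "ground_truth") <- tibble::tibble(
    time = targets$time, condition = targets$condition,
    contrast = targets$contrast, location = targets$target_location,
    p_hit = p_hit, hit = hit, rt = ifelse(hit, rt, NA_real_))
  out
}

#' Simulate a complete synthetic session
#'
#' Convenience wrapper: builds the event schedule, synthesizes all signal
#' streams, simulates the observer, and merges button presses into the event
#' table.
#'
#' @param cfg A [sim_config()].
#' @param participant Participant index.
#' @return A `walk_session` with observer responses included in `$events` and
#'   the per-target ground truth under `$ground_truth$responses`.
#' @export
#' @examples
#' \donttest{
#' cfg <- sim_config(seed = 1, n_blocks = 1)
#' ses <- simulate_session(cfg)
#' ses
#' }
simulate_session <- function(cfg, participant = 1L) {
  schedule <- make_event_schedule(cfg, participant)
  ses <- synthesize_signals(cfg, schedule, participant)
  presses <- simulate_observer(cfg, schedule, participant = participant)
  ses$events <- dplyr::bind_rows(schedule, presses) |>
    dplyr::arrange(.data$time)
  attr(ses$events, "recording_s") <- attr(schedule, "recording_s")
  ses$ground_truth$responses <- attr(presses, "ground_truth")
  ses
}

#' Fast trial-level spectral simulation (no signal synthesis)
#'
#' Draws per-trial referenced SSVEP power directly from the generative model
#' used by [synthesize_signals()]: the expected referenced power of a sinusoid
#' of amplitude `A` under the package's Welch estimator is `kappa * A^2 / 2`
#' (with `kappa` the Hamming-window leakage retention after neighbour
#' referencing), scaled by a participant gain and per-trial log-normal
#' fluctuation, plus additive spectral estimation noise. Intended for
#' statistical power/recovery studies over many simulated experiments where
#' full signal synthesis is not needed; the small-session equivalence of the
#' two paths is part of the package's test suite.
#'
#' @param cfg A [sim_config()].
#' @param participant Participant index.
#' @param n_trials_per_cell Trials per condition x contrast cell (default 42 =
#'   7 blocks x 6 targets).
#' @param subject_gain_sd Log-scale SD of the participant's multiplicative
#'   gain.
#' @param spec_noise_sd SD of additive spectral estimation noise (uV^2).
#' @return Tibble with `participant`, `condition`, `contrast`, `block`,
#'   `trial`, `ref_ssvep`.
#' @export
simulate_trial_power <- function(cfg, participant = 1L,
                                 n_trials_per_cell = cfg$n_blocks * cfg$n_targets_per_period,
                                 subject_gain_sd = 0.25,
                                 spec_noise_sd = 1.5) {
  validate_sim_config(cfg)
  set.seed(participant_seed(cfg, participant, stream = 4L))
  # referenced-power retention of a sinusoid of amplitude A under the Welch
  # estimator: Hamming coherent/incoherent gain (sum(w)^2 / (N sum(w^2)) =
  # 0.7337) times the neighbour-referencing correction for +-1-bin leakage
  # (1 - 2 (0.46/2/0.54)^2 / 4 = 0.9076); product 0.666
  kappa <- 0.666
  gain <- rlnorm(1, -subject_gain_sd^2 / 2, subject_gain_sd)
  grid <- tidyr::expand_grid(condition = cfg$walking_conditions,
                             contrast = cfg$contrast_levels)
  purrr::pmap_dfr(grid, function(condition, contrast) {
    A <- cfg$ssvep_amplitude_map[condition, as.character(contrast)]
    mult <- exp(cfg$amp_jitter_sd * rnorm(n_trials_per_cell) -
                  cfg$amp_jitter_sd^2 / 2)
    tibble::tibble(
      participant = participant, condition = condition, contrast = contrast,
      block = rep(seq_len(cfg$n_blocks), length.out = n_trials_per_cell),
      trial = seq_len(n_trials_per_cell),
      ref_ssvep = gain * kappa * (A * mult)^2 / 2 +
        rnorm(n_trials_per_cell, 0, spec_noise_sd))
  })
}
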