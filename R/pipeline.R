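#' Run the full spectral analysis on one session
#'
#' Filters the EEG (1-100 Hz zero-phase FIR), epochs contrast periods, cuts
#' 2-second pre-target trials, excludes press-contaminated trials, computes
#' Welch spectra over the occipital pool, selects the 3 strongest SSVEP
#' channels, derives referenced SSVEP (15 Hz vs 13/14/16/17 Hz) and alpha
#' power (individual peak vs 10/11/12 Hz), applies the MAD-median
#' high-frequency exclusion within each walking condition, and aggregates to
#' the condition x contrast cell table.
#'
#' @param session A `walk_session`.
#' @param cfg A [pipeline_config()].
#' @param prefiltered Set `TRUE` if the session is already band-pass filtered.
#' @return List of class `walk_analysis`: `trials` (per-trial table with
#'   powers and exclusion flags), `cells` (condition x contrast means),
#'   `channels` (selected labels), `peak_alpha_freq`, `n_trials_used`.
#' @export
analyze_session <- function(session, cfg = pipeline_config(),
                            prefiltered = FALSE) {
  if (!prefiltered) session <- filter_session(session, cfg)
  periods <- epoch_periods(session, cfg)
  trials <- extract_pretarget_trials(periods, session$events, cfg)
  trials <- trials |>
    dplyr::filter(!.data$excluded_press, !.data$short_trial, !is.na(.data$period_id))

  pool <- session$channel_labels$occipital_pool
  spectra <- compute_spectra(session, trials, cfg, channels = pool)
  channels <- select_channels(spectra, cfg$n_select_channels, pool,
                              cfg$ssvep_freq)

  ssvep <- trial_referenced_power(spectra, channels, cfg$ssvep_freq,
                                  cfg$ssvep_reference_freqs)
  hf <- trial_hf_power(spectra, cfg, channels)
  trials <- mad_exclude_hf(trials, hf, cfg)

  pa <- peak_alpha(spectra, trials, cfg$alpha_band, "still", channels)
  alpha <- trial_referenced_power(spectra, channels, pa,
                                  cfg$alpha_reference_freqs) |>
    dplyr::rename(raw_alpha = "raw_power", ref_alpha = "ref_power")

  trials <- trials |>
    dplyr::left_join(ssvep, by = "trial_id") |>
    dplyr::rename(raw_ssvep = "raw_power", ref_ssvep = "ref_power") |>
    dplyr::left_join(alpha, by = "trial_id")

  used <- trials |> dplyr::filter(!.data$excluded_mad)
  cells <- used |>
    dplyr::group_by(.data$condition, .data$contrast) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      ref_ssvep = mean(.data$ref_ssvep),
      raw_ssvep = mean(.data$raw_ssvep),
      ref_alpha = mean(.data$ref_alpha),
      hf_power = mean(.data$hf_power),
      .groups = "drop")

  structure(list(trials = trials, cells = cells, channels = channels,
                 peak_alpha_freq = pa, n_trials_used = nrow(used),
                 participant = session$participant),
            class = "walk_analysis")
}

#' @export
print.walk_analysis <- function(x, ...) {
  cat("<walk_analysis> participant", x$participant, "\n")
  cat("  channels:", paste(x$channels, collapse = ", "),
      "; peak alpha", x$peak_alpha_freq, "Hz\n")
  cat("  trials used:", x$n_trials_used, "of", nrow(x$trials), "\n")
  print(x$cells, n = 5)
  invisible(x)
}

#' Simulate a multi-participant experiment at the trial-power level
#'
#' Runs the fast generative path ([simulate_trial_power()]) for
#' `n_participants`, aggregates per-cell means, and fits the walking x
#' contrast within-subjects ANOVA on referenced SSVEP power. Used for
#' statistical power and recovery studies over many simulated experiments.
#'
#' @param cfg A [sim_config()].
#' @param n_participants Number of simulated participants.
#' @param ... Passed to [simulate_trial_power()].
#' @return List with `cells` (participant x condition x contrast means) and
#'   `anova` (an [rm_anova()] fit).
#' @export
simulate_experiment <- function(cfg, n_participants = 25, ...) {
  cells <- purrr::map_dfr(seq_len(n_participants), function(p) {
    simulate_trial_power(cfg, participant = p, ...) |>
      dplyr::group_by(.data$participant, .data$condition, .data$contrast) |>
      dplyr::summarise(ref_ssvep = mean(.data$ref_ssvep), .groups = "drop")
  })
  fit <- rm_anova(cells, "ref_ssvep", c("condition", "contrast"), "participant")
  list(cells = cells, anova = fit)
}
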