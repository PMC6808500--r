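#' Generate the event schedule for one synthetic participant
#'
#' Lays out the block/period/target structure of a session: for each walking
#' condition, `n_blocks` testing blocks, each presenting every surround
#' contrast level for one 35-second period (random order within block). Six
#' targets are presented in each period between 5 and 31.5 s after period
#' onset, with stimulus-onset asynchronies drawn uniformly from 3.5-6.5 s.
#' Block order is randomised across the session.
#'
#' @param cfg A [sim_config()] object.
#' @param participant Participant index (1-based); selects the participant's
#'   deterministic random substream.
#' @return A tibble (the event table) with columns `time` (s from recording
#'   start), `kind` (`block_start`, `contrast_onset`, `target_onset`),
#'   `condition`, `contrast`, `block` (session-wide block index), and
#'   `target_location` (`up`/`down`/`left`/`right`, `NA` for non-targets).
#' @export
#' @examples
#' sched <- make_event_schedule(sim_config(seed = 1))
#' sum(sched$kind == "contrast_onset")  # 84 = 3 conditions x 7 blocks x 4 levels
make_event_schedule <- function(cfg, participant = 1L) {
  validate_sim_config(cfg)
  set.seed(participant_seed(cfg, participant, stream = 1L))

  conditions <- rep(cfg$walking_conditions, each = cfg$n_blocks)
  conditions <- sample(conditions)  # random block order
  period_s <- cfg$period_s
  n_per <- cfg$n_periods_per_block
  block_len <- cfg$block_lead_s + n_per * period_s + cfg$block_gap_s

  rows <- vector("list", length(conditions))
  for (b in seq_along(conditions)) {
    t0 <- (b - 1) * block_len
    cond <- conditions[b]
    contrasts <- sample(cfg$contrast_levels)
    block_rows <- list(tibble::tibble(
      time = t0, kind = "block_start", condition = cond,
      contrast = NA_real_, block = b, target_location = NA_character_))
    for (p in seq_len(n_per)) {
      p0 <- t0 + cfg$block_lead_s + (p - 1) * period_s
      block_rows[[p + 1]] <- tibble::tibble(
        time = c(p0, p0 + draw_target_times(cfg)),
        kind = c("contrast_onset", rep("target_onset", cfg$n_targets_per_period)),
        condition = cond, contrast = contrasts[p], block = b,
        target_location = c(NA_character_,
                            sample(c("up", "down", "left", "right"),
                                   cfg$n_targets_per_period, replace = TRUE)))
    }
    rows[[b]] <- dplyr::bind_rows(block_rows)
  }
  out <- dplyr::bind_rows(rows) |> dplyr::arrange(.data$time)
  attr(out, "recording_s") <- length(conditions) * block_len
  attr(out, "fs_eeg") <- cfg$fs_eeg
  out
}

# Six target onsets inside [5, 31.5] s of a period, SOAs uniform in [3.5, 6.5],
# by rejection sampling of the SOA vector (keeps the SOA distribution uniform).
draw_target_times <- function(cfg) {
  k <- cfg$n_targets_per_period
  lo <- cfg$target_window[1]
  hi <- cfg$target_window[2]
  repeat {
    soa <- runif(k - 1, cfg$soa_range[1], cfg$soa_range[2])
    span <- sum(soa)
    if (span <= hi - lo) {
      t1 <- runif(1, lo, hi - span)
      return(t1 + c(0, cumsum(soa)))
    }
  }
}

# Deterministic per-participant, per-stream sub-seed below 2^31.
participant_seed <- function(cfg, participant, stream = 1L) {
  (cfg$seed %% 100000L) * 10007L + participant * 131L + stream
}
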