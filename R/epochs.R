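#' Cut a session into 35-second contrast-period epochs
#'
#' One epoch per contrast period, labelled with its walking condition,
#' surround contrast and block. Periods extending past the end of the
#' recording are flagged `truncated`, not dropped.
#'
#' @param session A `walk_session`.
#' @param cfg A [pipeline_config()].
#' @param period_s Period duration in seconds.
#' @return Tibble with `period_id`, `block`, `condition`, `contrast`,
#'   `t_start`, `t_end`, `truncated`.
#' @export
#' @examples
#' \donttest{
#' ses <- simulate_session(sim_config(seed = 1, n_blocks = 1))
#' epoch_periods(ses)  # 12 epochs: 1 block x 4 contrasts x 3 conditions
#' }
epoch_periods <- function(session, cfg = pipeline_config(), period_s = 35) {
  onsets <- session$events |> dplyr::filter(.data$kind == "contrast_onset")
  if (nrow(onsets) == 0)
    stop("no contrast_onset events in session", call. = FALSE)
  dur <- session$recording_s
  onsets |>
    dplyr::transmute(
      period_id = dplyr::row_number(),
      block = .data$block, condition = .data$condition,
      contrast = .data$contrast,
      t_start = .data$time, t_end = .data$time + period_s,
      truncated = .data$time + period_s > dur + 1e-9)
}

#' Extract 2-second pre-target trials
#'
#' Each trial is the half-open window `[t_target - 2, t_target)` ending at a
#' target onset. Trials with a button press inside the 2.5-second window
#' before target onset are flagged `excluded_press`; targets closer than 2 s
#' to the period start are flagged `short_trial`. Nothing is silently
#' dropped — downstream code filters on the flags.
#'
#' @param periods Period table from [epoch_periods()].
#' @param events Event table (needs `target_onset` and `button_press` rows).
#' @param cfg A [pipeline_config()] (uses `behavior$pre_press_exclusion_s`).
#' @param trial_s Trial length in seconds.
#' @return Tibble with one row per target: `trial_id`, `period_id`, `block`,
#'   `condition`, `contrast`, `location`, `t_target`, `t_start`, `t_end`,
#'   `excluded_press`, `short_trial`.
#' @export
extract_pretarget_trials <- function(periods, events,
                                     cfg = pipeline_config(), trial_s = 2) {
  targets <- events |> dplyr::filter(.data$kind == "target_onset")
  presses <- events |> dplyr::filter(.data$kind == "button_press")
  excl_s <- cfg$behavior$pre_press_exclusion_s

  # locate each target's parent period (half-open membership)
  pid <- vapply(targets$time, function(t) {
    i <- which(periods$t_start <= t + 1e-9 & t < periods$t_end - 1e-9)
    if (length(i) == 0) NA_integer_ else periods$period_id[i[1]]
  }, integer(1))

  has_press <- vapply(targets$time, function(t)
    any(presses$time >= t - excl_s & presses$time < t), logical(1))

  tibble::tibble(
    trial_id = seq_len(nrow(targets)),
    period_id = pid,
    block = targets$block,
    condition = targets$condition,
    contrast = targets$contrast,
    location = targets$target_location,
    t_target = targets$time,
    t_start = targets$time - trial_s,
    t_end = targets$time,
    excluded_press = has_press,
    short_trial = !is.na(pid) &
      targets$time - periods$t_start[match(pid, periods$period_id)] < trial_s)
}

#' Flag trials as high-frequency power outliers (MAD-median rule)
#'
#' Within each walking condition, a trial with high-frequency power `p` is an
#' outlier iff `|p - median(P)| * scale > cutoff * MAD`, where `P` are all
#' trial powers of that condition and `MAD = median(|P - median(P)|)`
#' (unscaled). Defaults: scale 0.6745, cutoff 2.24. The rule is invariant to
#' a common rescaling of `P`. Groups with fewer than 3 trials are left
#' unflagged with a warning.
#'
#' @param trials Trial table (needs `trial_id`, `condition`).
#' @param hf Tibble with `trial_id` and `hf_power` (see [trial_band_power()]).
#' @param cfg A [pipeline_config()].
#' @return `trials` with columns `hf_power` and `excluded_mad` added.
#' @export
mad_exclude_hf <- function(trials, hf, cfg = pipeline_config()) {
  out <- trials |>
    dplyr::left_join(hf, by = "trial_id") |>
    dplyr::group_by(.data$condition) |>
    dplyr::mutate(excluded_mad = {
      p <- .data$hf_power
      if (sum(!is.na(p)) < 3) {
        warning("condition group with < 3 trials: no MAD exclusion applied",
                call. = FALSE)
        rep(FALSE, length(p))
      } else {
        mad_outlier(p, cfg$mad$scale, cfg$mad$cutoff)
      }
    }) |>
    dplyr::ungroup()
  out
}

#' Vector form of the MAD-median outlier rule
#'
#' @param p Numeric vector of trial statistics.
#' @param scale Scale constant applied to the deviation (0.6745).
#' @param cutoff MAD multiple above which a point is an outlier (2.24).
#' @return Logical vector (`NA` in, `FALSE` out).
#' @export
mad_outlier <- function(p, scale = 0.6745, cutoff = 2.24) {
  med <- median(p, na.rm = TRUE)
  mad_raw <- median(abs(p - med), na.rm = TRUE)
  flag <- abs(p - med) * scale > cutoff * mad_raw
  flag[is.na(flag)] <- FALSE
  flag
}

#' Repair noisy epoch channels by neighbour interpolation
#'
#' Replaces a flagged (period, channel) segment by the average of the
#' channel's spatial neighbours over the same samples, mirroring interpolation
#' of channels identified as noisy. The mask is an explicit input (an
#' inspection result), keeping the step reproducible.
#'
#' @param session A `walk_session`.
#' @param periods Period table from [epoch_periods()].
#' @param mask Tibble with columns `period_id` and `channel`.
#' @param neighbours Named list mapping each EEG channel to its neighbour
#'   labels; defaults to a nearest-neighbour map of the montage.
#' @return List with the repaired `session` and `periods` gaining a
#'   `repaired` flag column.
#' @export
repair_epochs <- function(session, periods, mask,
                          neighbours = default_neighbours()) {
  periods$repaired <- periods$period_id %in% mask$period_id
  if (nrow(mask) == 0) return(list(session = session, periods = periods))
  fs <- session$fs$eeg
  n_eeg <- length(session$channel_labels$eeg)
  for (pid in unique(mask$period_id)) {
    chans <- mask$channel[mask$period_id == pid]
    if (length(chans) >= n_eeg)
      stop("repair error: all channels masked in period ", pid, call. = FALSE)
    pr <- periods[periods$period_id == pid, ]
    idx <- (t_to_sample(pr$t_start, fs) + 1L):
      min(t_to_sample(pr$t_end, fs), ncol(session$signals))
    for (ch in chans) {
      nb <- setdiff(neighbours[[ch]], chans)
      if (length(nb) == 0)
        stop("repair error: no unmasked neighbours for ", ch, call. = FALSE)
      session$signals[ch, idx] <- colMeans(session$signals[nb, idx, drop = FALSE])
    }
  }
  list(session = session, periods = periods)
}

#' Default spatial neighbour map for the 16-channel montage
#' @return Named list of character vectors.
#' @export
default_neighbours <- function() {
  list(
    Fp1 = c("Fz", "F3"), Fp2 = c("Fz", "F4"),
    Fz = c("Fp1", "Fp2", "Cz"), F3 = c("Fp1", "Fz", "C3"),
    F4 = c("Fp2", "Fz", "C4"),
    Cz = c("Fz", "C3", "C4", "Pz"), C3 = c("F3", "Cz", "P3"),
    C4 = c("F4", "Cz", "P4"),
    P3 = c("C3", "Pz", "O1"), Pz = c("Cz", "P3", "P4", "POz"),
    P4 = c("C4", "Pz", "O2"), P7 = c("P3", "O1"),
    POz = c("Pz", "O1", "Oz", "O2"),
    O1 = c("P3", "POz", "Oz"), Oz = c("O1", "POz", "O2"),
    O2 = c("P4", "POz", "Oz")
  )
}
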