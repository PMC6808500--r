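#' Select the channels with the strongest SSVEP response
#'
#' Picks the `n` channels from the occipital pool with the highest mean power
#' at the SSVEP frequency across all trials. Ties are broken deterministically
#' by the order of the `pool` argument.
#'
#' @param spectra Spectrum table from [compute_spectra()].
#' @param n Number of channels to select.
#' @param pool Candidate channel labels (occipital area).
#' @param target_freq SSVEP frequency, Hz.
#' @return Character vector of `n` channel labels.
#' @export
select_channels <- function(spectra, n = 3,
                            pool = channel_layout()$occipital_pool,
                            target_freq = 15) {
  if (length(pool) == 0) stop("channel pool is empty", call. = FALSE)
  if (n > length(pool))
    stop("cannot select ", n, " channels from a pool of ", length(pool),
         call. = FALSE)
  means <- spectra |>
    dplyr::filter(.data$channel %in% pool, .data$freq == target_freq) |>
    dplyr::group_by(.data$channel) |>
    dplyr::summarise(mp = mean(.data$power), .groups = "drop")
  if (nrow(means) == 0)
    stop("no spectra available for the channel pool", call. = FALSE)
  # stable ordering: by pool position first, then stable sort on -power
  means <- means[order(match(means$channel, pool)), ]
  means$channel[order(-means$mp)[seq_len(n)]]
}

#' Neighbour-referenced power at a target frequency
#'
#' Power at the target frequency minus the mean power at the reference
#' frequencies, correcting broadband power shifts. The result may be negative.
#'
#' @param spectrum Tibble with `freq` and `power` (a single spectrum).
#' @param target Target frequency, Hz.
#' @param refs Reference frequencies, Hz.
#' @return Referenced power (same units as `power`).
#' @export
#' @examples
#' sp <- tibble::tibble(freq = 10:20, power = c(1,1,1,1,1,5,1,1,1,1,1))
#' referenced_power(sp, 15, c(13, 14, 16, 17))  # 4
referenced_power <- function(spectrum, target, refs) {
  all_f <- c(target, refs)
  idx <- match(all_f, spectrum$freq)
  if (anyNA(idx))
    stop("frequency off the spectral grid: ",
         paste(all_f[is.na(idx)], collapse = ", "), call. = FALSE)
  spectrum$power[idx[1]] - mean(spectrum$power[idx[-1]])
}

#' Per-trial referenced power over selected channels
#'
#' Averages the spectrum over the selected channels and applies
#' [referenced_power()] per trial.
#'
#' @param spectra Spectrum table.
#' @param channels Channel labels to average over.
#' @param target Target frequency, Hz.
#' @param refs Reference frequencies, Hz.
#' @return Tibble `trial_id`, `raw_power` (at target), `ref_power`.
#' @export
trial_referenced_power <- function(spectra, channels, target, refs) {
  sub <- spectra |>
    dplyr::filter(.data$channel %in% channels,
                  .data$freq %in% c(target, refs)) |>
    dplyr::group_by(.data$trial_id, .data$freq) |>
    dplyr::summarise(power = mean(.data$power), .groups = "drop")
  sub |>
    dplyr::group_by(.data$trial_id) |>
    dplyr::summarise(
      raw_power = .data$power[.data$freq == target],
      ref_power = .data$power[.data$freq == target] -
        mean(.data$power[.data$freq != target]),
      .groups = "drop")
}

#' Individual peak alpha frequency
#'
#' The grid frequency inside the alpha band maximizing mean power over the
#' still-condition trials and the given channels; ties resolve to the lower
#' frequency.
#'
#' @param spectra Spectrum table.
#' @param trials Trial table (needs `trial_id`, `condition`).
#' @param band Alpha band, Hz.
#' @param condition Condition whose trials define the estimate.
#' @param channels Channel labels to average over (default: all present).
#' @return Peak frequency in Hz.
#' @export
peak_alpha <- function(spectra, trials, band = c(8, 12), condition = "still",
                       channels = NULL) {
  if (band[1] > band[2]) stop("empty alpha band", call. = FALSE)
  ids <- trials$trial_id[trials$condition == condition]
  if (length(ids) == 0)
    stop("no trials in condition '", condition, "'", call. = FALSE)
  sub <- spectra |> dplyr::filter(.data$trial_id %in% ids,
                                  .data$freq >= band[1],
                                  .data$freq <= band[2])
  if (!is.null(channels))
    sub <- sub |> dplyr::filter(.data$channel %in% channels)
  prof <- sub |>
    dplyr::group_by(.data$freq) |>
    dplyr::summarise(power = mean(.data$power), .groups = "drop") |>
    dplyr::arrange(.data$freq)
  prof$freq[which.max(prof$power)]
}

#' Step-frequency spectrum from ankle speed traces
#'
#' Welch spectrum of the summed ankle speeds, per walking condition. Long
#' windows give sub-Hz resolution so the 1 Hz (slow) and 1.75 Hz (normal)
#' step frequencies separate.
#'
#' @param session A `walk_session`.
#' @param window_s Welch window, seconds.
#' @return Tibble `condition`, `freq`, `power`.
#' @export
step_frequency_spectrum <- function(session, window_s = 20) {
  fsm <- session$fs$motion
  x <- session$motion["ankle_l", ] + session$motion["ankle_r", ]
  blocks <- session$events |> dplyr::filter(.data$kind == "block_start")
  conds <- unique(blocks$condition)
  block_len <- diff(sort(unique(blocks$time)))[1] %||% (session$recording_s)
  purrr::map_dfr(conds, function(cond) {
    rows <- blocks[blocks$condition == cond, ]
    seg <- unlist(lapply(rows$time, function(t0) {
      i0 <- t_to_sample(t0, fsm) + 1L
      i1 <- min(i0 + round(block_len * fsm) - 1L, length(x))
      x[i0:i1]
    }))
    ps <- welch_psd(seg, fsm, window_s = window_s, overlap = 0.5)
    ps$condition <- cond
    ps
  }) |> dplyr::select("condition", "freq", "power")
}
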