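#' Instantaneous SSVEP amplitude via band-pass + Hilbert transform
#'
#' Band-passes the signal around the SSVEP frequency with a zero-phase
#' Hamming-window FIR filter and returns the magnitude of the analytic signal
#' (instantaneous amplitude, microvolts). The first and last `edge_s` seconds
#' are filter-contaminated and should be excluded from statistics; they are
#' returned but marked by the `edge` column.
#'
#' @param x Signal vector (typically one 35-second epoch).
#' @param fs Sampling rate, Hz.
#' @param band Pass band, Hz (default 14.5-15.5).
#' @param fir_s FIR kernel duration, seconds.
#' @param edge_s Edge duration flagged as contaminated.
#' @return Tibble `time` (s from epoch start), `amplitude`, `edge` (logical).
#' @export
#' @examples
#' x <- 2 * sin(2 * pi * 15 * seq(0, 5, by = 1 / 500))
#' env <- hilbert_envelope(x, 500)
#' mean(env$amplitude[!env$edge])  # close to 2
hilbert_envelope <- function(x, fs, band = c(14.5, 15.5), fir_s = 1.0,
                             edge_s = 0.5) {
  xf <- bandpass_hamming(x, fs, band, fir_s)
  amp <- Mod(analytic_signal(xf))
  t <- (seq_along(x) - 1) / fs
  tibble::tibble(time = t, amplitude = amp,
                 edge = t < edge_s | t > t[length(t)] - edge_s)
}

#' Target-evoked SSVEP perturbation
#'
#' Averages the SSVEP amplitude envelope across targets, aligned to target
#' onset, and summarises the post-target window: `mean_200_600` takes the mean
#' amplitude 200-600 ms after onset; `min_200_1000` takes the lowest amplitude
#' point in 200-1000 ms (the reported variant negates this minimum so that
#' stronger dips give larger values; `value_signed` carries that convention).
#' The pre-target baseline is the mean envelope in the second before onset.
#'
#' @param envelope Envelope tibble from [hilbert_envelope()] for one epoch
#'   (`time` relative to epoch start).
#' @param target_times Target onset times, seconds from epoch start.
#' @param mode `"mean_200_600"` or `"min_200_1000"`.
#' @param cfg A [pipeline_config()] (windows under `perturbation`).
#' @return One-row tibble: `mode`, `value`, `value_signed`, `baseline`,
#'   `n_targets`, plus the average target-locked curve as attribute `curve`.
#' @export
evoked_perturbation <- function(envelope, target_times,
                                mode = c("mean_200_600", "min_200_1000"),
                                cfg = pipeline_config()) {
  mode <- match.arg(mode)
  win <- if (mode == "mean_200_600") cfg$perturbation$window else
    cfg$perturbation$alt_window
  base_win <- cfg$perturbation$baseline
  fs <- 1 / diff(envelope$time[1:2])
  lo <- base_win[1]
  hi <- max(win[2], 0)
  rel <- seq(round(lo * fs), round(hi * fs)) / fs

  ok <- target_times + lo >= envelope$time[1] &
    target_times + hi <= envelope$time[nrow(envelope)]
  if (!any(ok)) stop("no target with a full post-target window", call. = FALSE)
  segs <- vapply(target_times[ok], function(t0) {
    idx <- round((t0 - envelope$time[1]) * fs) + 1 + round(rel * fs)
    envelope$amplitude[idx]
  }, numeric(length(rel)))
  curve <- tibble::tibble(time = rel, amplitude = rowMeans(segs))

  in_win <- curve$time >= win[1] & curve$time <= win[2]
  value <- if (mode == "mean_200_600") mean(curve$amplitude[in_win]) else
    min(curve$amplitude[in_win])
  baseline <- mean(curve$amplitude[curve$time >= base_win[1] &
                                     curve$time < base_win[2]])
  out <- tibble::tibble(
    mode = mode, value = value,
    value_signed = if (mode == "min_200_1000") -value else value,
    baseline = baseline, n_targets = sum(ok))
  attr(out, "curve") <- curve
  out
}
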