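#' Welch power spectral density
#'
#' Mean of tapered periodograms over `window_s`-second segments with the given
#' overlap. With 1-second windows the frequency grid has exactly 1 Hz spacing.
#' One-sided density scaling: for white noise of variance `s^2` the powers sum
#' to `s^2` (times the grid spacing); a sinusoid concentrates its power at its
#' frequency bin (with the taper's leakage into adjacent bins).
#'
#' @param x Numeric signal vector.
#' @param fs Sampling rate, Hz.
#' @param window_s Segment length, seconds.
#' @param overlap Fractional overlap between segments (0.5 = 50%).
#' @param taper `"hamming"` (default) or `"rect"`.
#' @param demean Subtract each segment's mean before tapering.
#' @return Tibble with `freq` (0..Nyquist) and `power` (uV^2/Hz).
#' @export
#' @examples
#' x <- sin(2 * pi * 15 * seq(0, 2 - 1 / 500, by = 1 / 500))
#' ps <- welch_psd(x, 500)
#' ps$freq[which.max(ps$power)]  # 15
welch_psd <- function(x, fs, window_s = 1, overlap = 0.5,
                      taper = "hamming", demean = TRUE) {
  nwin <- round(window_s * fs)
  if (length(x) < nwin)
    stop("signal shorter than one Welch window", call. = FALSE)
  step <- max(1, round(nwin * (1 - overlap)))
  starts <- seq(1, length(x) - nwin + 1, by = step)
  w <- switch(taper,
              hamming = 0.54 - 0.46 * cos(2 * pi * seq(0, nwin - 1) / (nwin - 1)),
              rect = rep(1, nwin),
              stop("unknown taper: ", taper, call. = FALSE))
  u <- sum(w^2)
  nf <- floor(nwin / 2) + 1
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nwin - 1)]
    if (demean) seg <- seg - mean(seg)
    X <- fft(seg * w)[seq_len(nf)]
    acc <- acc + (Mod(X)^2) / (fs * u)
  }
  p <- acc / length(starts)
  # one-sided: double everything except DC (and Nyquist for even windows)
  dbl <- rep(2, nf)
  dbl[1] <- 1
  if (nwin %% 2 == 0) dbl[nf] <- 1
  tibble::tibble(freq = seq(0, by = fs / nwin, length.out = nf),
                 power = p * dbl)
}

#' Per-trial, per-channel Welch spectra of a session
#'
#' @param session A `walk_session`.
#' @param trials Trial (or period) table with `t_start`, `t_end` and an id
#'   column (`trial_id` or `period_id`).
#' @param cfg A [pipeline_config()].
#' @param channels Channel labels to include (default: all EEG channels).
#' @return Long tibble: `trial_id`, `channel`, `freq`, `power` — the spectrum
#'   table consumed by the SSVEP/alpha statistics.
#' @export
compute_spectra <- function(session, trials, cfg = pipeline_config(),
                            channels = session$channel_labels$eeg) {
  fs <- session$fs$eeg
  id_col <- if ("trial_id" %in% names(trials)) "trial_id" else "period_id"
  purrr::map_dfr(seq_len(nrow(trials)), function(i) {
    i0 <- t_to_sample(trials$t_start[i], fs) + 1L
    i1 <- t_to_sample(trials$t_end[i], fs)
    i1 <- min(i1, ncol(session$signals))
    purrr::map_dfr(channels, function(ch) {
      ps <- welch_psd(session$signals[ch, i0:i1], fs,
                      cfg$welch$window_s, cfg$welch$overlap, cfg$welch$taper)
      ps$trial_id <- trials[[id_col]][i]
      ps$channel <- ch
      ps
    })
  }) |>
    dplyr::select("trial_id", "channel", "freq", "power")
}

#' Per-trial band power (summed over an inclusive 1 Hz bin range)
#'
#' Averages the spectrum over channels, then sums the bins inside `band`
#' (inclusive at both edges).
#'
#' @param spectra Spectrum table from [compute_spectra()].
#' @param band Length-2 numeric band in Hz.
#' @param channels Optional channel subset.
#' @return Tibble `trial_id`, `power`.
#' @export
trial_band_power <- function(spectra, band, channels = NULL) {
  if (!is.null(channels))
    spectra <- spectra |> dplyr::filter(.data$channel %in% channels)
  spectra |>
    dplyr::filter(.data$freq >= band[1], .data$freq <= band[2]) |>
    dplyr::group_by(.data$trial_id, .data$freq) |>
    dplyr::summarise(power = mean(.data$power), .groups = "drop") |>
    dplyr::group_by(.data$trial_id) |>
    dplyr::summarise(power = sum(.data$power), .groups = "drop")
}

#' Per-trial high-frequency (20-99 Hz) power
#'
#' @inheritParams trial_band_power
#' @param cfg A [pipeline_config()] (uses `hf_band`).
#' @return Tibble `trial_id`, `hf_power`.
#' @export
trial_hf_power <- function(spectra, cfg = pipeline_config(), channels = NULL) {
  trial_band_power(spectra, cfg$hf_band, channels) |>
    dplyr::rename(hf_power = "power")
}
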