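#' Zero-phase windowed-sinc FIR filtering (Kaiser window)
#'
#' Designs a linear-phase FIR filter with a Kaiser window (stopband
#' attenuation `ripple_db`, transition bandwidth a fixed fraction of the lower
#' band edge with a floor of `min_transition` Hz) and applies it without phase
#' distortion by compensating the integer group delay after symmetric edge
#' padding. Pass `low = NULL` for a low-pass, `high = NULL` for a high-pass.
#'
#' @param x Numeric signal vector.
#' @param fs Sampling rate, Hz.
#' @param low,high Band edges in Hz (either may be `NULL` for one-sided).
#' @param ripple_db Stopband attenuation in dB.
#' @param transition_frac Transition bandwidth as fraction of the lower edge.
#' @param min_transition Minimum transition bandwidth, Hz.
#' @return Filtered signal, same length as `x`.
#' @export
#' @examples
#' x <- sin(2 * pi * 15 * seq(0, 2, by = 1 / 500))
#' y <- bandpass_fir(x, 500, 1, 100)
#' max(abs(y - x)) < 0.05
bandpass_fir <- function(x, fs, low = NULL, high = NULL, ripple_db = 60,
                         transition_frac = 0.25, min_transition = 1) {
  nyq <- fs / 2
  if (is.null(low) && is.null(high))
    stop("parameter error: at least one band edge required", call. = FALSE)
  for (edge in c(low, high))
    if (edge <= 0 || edge >= nyq)
      stop("parameter error: band edges must lie strictly inside (0, Nyquist)",
           call. = FALSE)
  if (!is.null(low) && !is.null(high) && low >= high)
    stop("parameter error: low must be below high", call. = FALSE)

  edge_for_width <- if (!is.null(low)) low else high
  trans <- max(min_transition, transition_frac * edge_for_width)
  b <- kaiser_fir(fs, low, high, trans, ripple_db)
  fir_zerophase(x, b)
}

# Kaiser-window FIR design (standard Kaiser order/beta formulas).
kaiser_fir <- function(fs, low, high, trans, ripple_db) {
  A <- ripple_db
  beta <- if (A > 50) {
    0.1102 * (A - 8.7)
  } else if (A >= 21) {
    0.5842 * (A - 21)^0.4 + 0.07886 * (A - 21)
  } else 0
  d_omega <- 2 * pi * trans / fs
  n <- ceiling((A - 8) / (2.285 * d_omega))
  if (n %% 2 == 1) n <- n + 1  # even order -> odd length, integer delay
  w <- signal::kaiser(n + 1, beta)
  nyq <- fs / 2
  if (is.null(low)) {
    signal::fir1(n, high / nyq, type = "low", window = w)
  } else if (is.null(high)) {
    signal::fir1(n, low / nyq, type = "high", window = w)
  } else {
    signal::fir1(n, c(low, high) / nyq, type = "pass", window = w)
  }
}

#' Zero-phase Hamming-window FIR band-pass (fixed length)
#'
#' Used for the narrow-band SSVEP envelope extraction, where the kernel length
#' (hence the temporal edge) is fixed rather than derived from a transition
#' width.
#'
#' @param x Signal vector.
#' @param fs Sampling rate, Hz.
#' @param band Length-2 band in Hz.
#' @param fir_s Kernel duration in seconds (rounded to an odd sample count).
#' @return Filtered signal.
#' @export
bandpass_hamming <- function(x, fs, band, fir_s = 1.0) {
  nyq <- fs / 2
  if (band[1] <= 0 || band[2] >= nyq)
    stop("parameter error: band must lie strictly inside (0, Nyquist)",
         call. = FALSE)
  n <- round(fir_s * fs)
  if (n %% 2 == 1) n <- n + 1
  b <- signal::fir1(n, band / nyq, type = "pass",
                    window = signal::hamming(n + 1))
  fir_zerophase(x, b)
}

#' Filter all EEG/EOG channels of a session in place
#'
#' Applies the pipeline's 1-100 Hz zero-phase FIR band-pass to every
#' EEG/EOG/earlobe channel.
#'
#' @param session A `walk_session`.
#' @param cfg A [pipeline_config()].
#' @return The session with filtered `signals`.
#' @export
filter_session <- function(session, cfg = pipeline_config()) {
  b <- kaiser_fir(session$fs$eeg, cfg$filter$low, cfg$filter$high,
                  max(cfg$filter$min_transition,
                      cfg$filter$transition_frac * cfg$filter$low),
                  cfg$filter$ripple_db)
  for (i in seq_len(nrow(session$signals)))
    session$signals[i, ] <- fir_zerophase(session$signals[i, ], b)
  session$filtered <- TRUE
  session
}
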