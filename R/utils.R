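# Internal numerical helpers shared across modules.

#' Analytic signal via frequency-domain construction
#'
#' Returns the complex analytic signal of a real vector: positive frequencies
#' doubled, negative frequencies zeroed, DC/Nyquist untouched.
#' @noRd
analytic_signal <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

#' Gaussian noise with a power-law (1/f^a) spectrum plus optional flat bands
#'
#' Spectral-shaping synthesis: white Gaussian noise is transformed to the
#' frequency domain, each bin scaled by the target amplitude spectrum, and
#' transformed back. `rms` fixes the standard deviation of the result.
#' @noRd
shaped_noise <- function(n, fs, exponent = 1, rms = 1) {
  freqs <- seq(0, fs / 2, by = fs / n)
  x <- rnorm(n)
  X <- fft(x)
  nf <- length(freqs)
  gain <- c(0, freqs[-1]^(-exponent / 2))
  full_gain <- numeric(n)
  full_gain[seq_len(nf)] <- gain
  if (n %% 2 == 0) {
    full_gain[(nf + 1):n] <- rev(gain[2:(nf - 1)])
  } else {
    full_gain[(nf + 1):n] <- rev(gain[2:nf])
  }
  y <- Re(fft(X * full_gain, inverse = TRUE) / n)
  s <- stats::sd(y)
  if (s == 0) return(y)
  y / s * rms
}

#' Band-limited Gaussian noise with flat spectrum inside [lo, hi] Hz
#' @noRd
band_noise <- function(n, fs, lo, hi, rms = 1) {
  freqs <- seq(0, fs / 2, by = fs / n)
  x <- rnorm(n)
  X <- fft(x)
  nf <- length(freqs)
  gain <- as.numeric(freqs >= lo & freqs <= hi)
  full_gain <- numeric(n)
  full_gain[seq_len(nf)] <- gain
  if (n %% 2 == 0) {
    full_gain[(nf + 1):n] <- rev(gain[2:(nf - 1)])
  } else {
    full_gain[(nf + 1):n] <- rev(gain[2:nf])
  }
  y <- Re(fft(X * full_gain, inverse = TRUE) / n)
  s <- stats::sd(y)
  if (s == 0) return(y)
  y / s * rms
}

#' Apply a linear-phase FIR filter with group-delay compensation (zero phase)
#'
#' The filter is applied forward once; the output is shifted back by the
#' integer group delay (length - 1)/2 after symmetric edge padding, so the
#' result is zero phase for odd-length symmetric kernels.
#' @noRd
fir_zerophase <- function(x, b) {
  nb <- length(b)
  stopifnot(nb %% 2 == 1)
  d <- (nb - 1) / 2
  nx <- length(x)
  npad <- min(d, nx - 1)
  # reflect edges to limit transient contamination
  xp <- c(rev(x[2:(npad + 1)]), x, rev(x[(nx - npad):(nx - 1)]))
  # linear convolution via FFT
  nfull <- length(xp) + nb - 1
  nfft <- stats::nextn(nfull, 2)
  y <- Re(fft(fft(c(xp, numeric(nfft - length(xp)))) *
                fft(c(b, numeric(nfft - nb))), inverse = TRUE) / nfft)
  # centre of the kernel aligned with the input: drop delay d and edge pad
  y[(d + npad + 1):(d + npad + nx)]
}

#' Group sorted time points closer than `gap` seconds into events
#'
#' Returns a tibble with one row per group: t_start, t_end, n_points.
#' @noRd
group_time_points <- function(times, gap) {
  if (length(times) == 0) {
    return(tibble::tibble(t_start = numeric(0), t_end = numeric(0),
                          n_points = integer(0)))
  }
  times <- sort(times)
  brk <- c(0, cumsum(diff(times) > gap))
  tibble::tibble(t = times, g = brk) |>
    dplyr::group_by(.data$g) |>
    dplyr::summarise(t_start = min(.data$t), t_end = max(.data$t),
                     n_points = dplyr::n(), .groups = "drop") |>
    dplyr::select(-dplyr::any_of("g"))
}

#' Seconds to 0-based sample index (floor convention, half-open windows)
#' @noRd
t_to_sample <- function(t, fs) as.integer(floor(t * fs + 1e-9))

`%||%` <- function(a, b) if (is.null(a)) b else a
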