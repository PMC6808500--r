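#' Detect blinks from the vertical EOG
#'
#' The vertical component (above-eye minus below-eye channel, left eye by
#' default) is band-limited to 0.2-20 Hz, candidate points are threshold
#' crossings at `cross` (20 uV), candidates within 100 ms are merged, and a
#' merged candidate is kept only if its peak amplitude reaches `min_peak`
#' (40 uV) and the local amplitude SD (400 ms window centred on the peak)
#' reaches `min_sd` (15 uV).
#'
#' @param session A `walk_session`.
#' @param cfg A [pipeline_config()].
#' @param eye `"left"` or `"right"`.
#' @return Tibble `t_peak` (s), `peak_amp` (uV).
#' @export
detect_blinks <- function(session, cfg = pipeline_config(), eye = "left") {
  chans <- if (eye == "left") c("EOG_LA", "EOG_LB") else c("EOG_RA", "EOG_RB")
  if (!all(chans %in% rownames(session$signals)))
    stop("missing EOG channel(s): ",
         paste(setdiff(chans, rownames(session$signals)), collapse = ", "),
         call. = FALSE)
  fs <- session$fs$eeg
  v <- session$signals[chans[1], ] - session$signals[chans[2], ]
  # drift removal with a zero-phase 2nd-order Butterworth (a windowed-sinc at
  # 0.2 Hz would need a multi-second kernel), then 20 Hz windowed-sinc low-pass
  bf <- signal::butter(2, cfg$blink$hp / (fs / 2), type = "high")
  v <- as.numeric(signal::filtfilt(bf, v))
  v <- bandpass_fir(v, fs, low = NULL, high = cfg$blink$lp,
                    min_transition = 5)

  above <- which(v > cfg$blink$cross)
  if (length(above) == 0)
    return(tibble::tibble(t_peak = numeric(0), peak_amp = numeric(0)))
  groups <- group_time_points((above - 1) / fs, cfg$blink$merge_s)

  half_sd <- round(cfg$blink$sd_window_s / 2 * fs)
  res <- purrr::map_dfr(seq_len(nrow(groups)), function(g) {
    i0 <- t_to_sample(groups$t_start[g], fs) + 1L
    i1 <- t_to_sample(groups$t_end[g], fs) + 1L
    ipk <- i0 + which.max(v[i0:i1]) - 1L
    peak <- v[ipk]
    w0 <- max(1, ipk - half_sd)
    w1 <- min(length(v), ipk + half_sd)
    tibble::tibble(t_peak = (ipk - 1) / fs, peak_amp = peak,
                   local_sd = stats::sd(v[w0:w1]))
  })
  res |>
    dplyr::filter(.data$peak_amp >= cfg$blink$min_peak,
                  .data$local_sd >= cfg$blink$min_sd) |>
    dplyr::select("t_peak", "peak_amp")
}

#' Radial EOG (REOG) signal
#'
#' Mean of all six EOG channels minus the Pz channel; emphasises the saccadic
#' spike potential.
#'
#' @param session A `walk_session`.
#' @return Numeric vector, microvolts.
#' @export
compute_reog <- function(session) {
  eog <- session$channel_labels$eog
  need <- c(eog, "Pz")
  missing <- setdiff(need, rownames(session$signals))
  if (length(missing) > 0)
    stop("missing channel(s) for REOG: ", paste(missing, collapse = ", "),
         call. = FALSE)
  colMeans(session$signals[eog, , drop = FALSE]) - session$signals["Pz", ]
}

# Block windows (start, end) from the event table; last block runs to the end.
block_windows <- function(session) {
  starts <- session$events |>
    dplyr::filter(.data$kind == "block_start") |>
    dplyr::arrange(.data$time)
  tibble::tibble(
    block = starts$block,
    t_start = starts$time,
    t_end = c(starts$time[-1], session$recording_s))
}

#' Detect saccades from the REOG spike potential
#'
#' The REOG is band-pass-filtered 20-90 Hz (6th-order Butterworth, zero
#' phase), its Hilbert amplitude envelope computed, and points exceeding the
#' block mean by `sd_mult` (2.5) block SDs are marked; marked points less than
#' 20 ms apart are grouped into one saccade. Thresholds are computed per
#' recording block; detections within the filter warm-up of block edges are
#' discarded.
#'
#' @param session A `walk_session`.
#' @param cfg A [pipeline_config()].
#' @return Tibble `t` (time of the envelope peak, s), `block`, `env_peak`.
#' @export
detect_saccades <- function(session, cfg = pipeline_config()) {
  fs <- session$fs$eeg
  reog <- compute_reog(session)
  bf <- signal::butter(cfg$saccade$order / 2,
                       cfg$saccade$band / (fs / 2), type = "pass")
  rf <- as.numeric(signal::filtfilt(bf, reog))
  env <- Mod(analytic_signal(rf))
  blocks <- block_windows(session)
  warm <- cfg$saccade$warmup_s

  purrr::map_dfr(seq_len(nrow(blocks)), function(b) {
    i0 <- t_to_sample(blocks$t_start[b], fs) + 1L
    i1 <- min(t_to_sample(blocks$t_end[b], fs), length(env))
    if ((i1 - i0) / fs < 2 * warm + 1) {
      warning("block ", blocks$block[b], " shorter than filter warm-up; skipped",
              call. = FALSE)
      return(NULL)
    }
    e <- env[i0:i1]
    thr <- mean(e) + cfg$saccade$sd_mult * stats::sd(e)
    sup <- which(e > thr)
    if (length(sup) == 0) return(NULL)
    t_sup <- (i0 - 1 + sup - 1) / fs
    inside <- t_sup >= blocks$t_start[b] + warm & t_sup <= blocks$t_end[b] - warm
    if (!any(inside)) return(NULL)
    grp <- group_time_points(t_sup[inside], cfg$saccade$group_s)
    purrr::map_dfr(seq_len(nrow(grp)), function(g) {
      j0 <- t_to_sample(grp$t_start[g], fs) + 1L
      j1 <- t_to_sample(grp$t_end[g], fs) + 1L
      jp <- j0 + which.max(env[j0:j1]) - 1L
      tibble::tibble(t = (jp - 1) / fs, block = blocks$block[b],
                     env_peak = env[jp])
    })
  })
}

#' Extract and average the saccadic spike potential
#'
#' For each detected saccade an 80 ms window of the 20-90 Hz-filtered REOG is
#' extracted, centred on the lowest point of the filtered signal near the
#' detection; each window is divided by the block-mean Hilbert amplitude of
#' the filtered REOG (correcting broadband power differences between blocks)
#' and the windows are averaged. The normalised amplitude at window centre
#' (time 0, the trough) is the per-saccade spike amplitude used for size
#' calibration.
#'
#' @param session A `walk_session`.
#' @param saccades Saccade table from [detect_saccades()].
#' @param cfg A [pipeline_config()].
#' @param search_s Half-width of the trough search around each detection, s.
#' @return List with `mean_waveform` (tibble `time`, `amplitude`; time 0 at
#'   the trough) and `saccades` (input plus `t_trough`, `spike_amp`).
#' @export
extract_spike_potential <- function(session, saccades,
                                    cfg = pipeline_config(),
                                    search_s = 0.04) {
  if (nrow(saccades) == 0) stop("no saccades to extract", call. = FALSE)
  fs <- session$fs$eeg
  reog <- compute_reog(session)
  bf <- signal::butter(cfg$saccade$order / 2,
                       cfg$saccade$band / (fs / 2), type = "pass")
  rf <- as.numeric(signal::filtfilt(bf, reog))
  env <- Mod(analytic_signal(rf))
  blocks <- block_windows(session)
  block_norm <- vapply(seq_len(nrow(blocks)), function(b) {
    i0 <- t_to_sample(blocks$t_start[b], fs) + 1L
    i1 <- min(t_to_sample(blocks$t_end[b], fs), length(env))
    mean(env[i0:i1])
  }, numeric(1))
  names(block_norm) <- as.character(blocks$block)

  half <- round(cfg$saccade$window_s / 2 * fs)
  hs <- round(search_s * fs)
  waves <- list()
  t_trough <- spike_amp <- rep(NA_real_, nrow(saccades))
  for (k in seq_len(nrow(saccades))) {
    ic <- t_to_sample(saccades$t[k], fs) + 1L
    s0 <- max(1, ic - hs)
    s1 <- min(length(rf), ic + hs)
    it <- s0 + which.min(rf[s0:s1]) - 1L
    if (it - half < 1 || it + half > length(rf)) next
    w <- rf[(it - half):(it + half)] / block_norm[[as.character(saccades$block[k])]]
    waves[[length(waves) + 1]] <- w
    t_trough[k] <- (it - 1) / fs
    spike_amp[k] <- abs(w[half + 1])
  }
  if (length(waves) == 0)
    stop("all saccade windows exceeded the recording", call. = FALSE)
  mw <- Reduce(`+`, waves) / length(waves)
  list(
    mean_waveform = tibble::tibble(time = seq(-half, half) / fs, amplitude = mw),
    saccades = dplyr::mutate(saccades, t_trough = t_trough,
                             spike_amp = spike_amp))
}

#' Fit the spike-amplitude to saccade-size calibration
#'
#' Least-squares second-order polynomial mapping normalised spike amplitude to
#' saccade size, fitted on controlled-saccade calibration points. Estimation
#' outside the calibrated amplitude range is clamped to the range edges.
#'
#' @param points Tibble with `size` (degrees) and `amplitude` (normalised
#'   spike amplitude); at least 3 distinct sizes.
#' @return An object of class `size_calibration`.
#' @export
fit_size_calibration <- function(points) {
  if (length(unique(points$size)) < 3)
    stop("need at least 3 distinct calibration sizes", call. = FALSE)
  fit <- lm(size ~ amplitude + I(amplitude^2), data = points)
  rng <- range(points$amplitude)
  # monotonicity check of the fitted curve inside the calibrated range
  grid <- seq(rng[1], rng[2], length.out = 101)
  pred <- coef(fit)[1] + coef(fit)[2] * grid + coef(fit)[3] * grid^2
  if (any(diff(pred) < 0))
    warning("calibration fit is non-monotone inside the calibrated range",
            call. = FALSE)
  structure(list(coef = coef(fit), range = rng, points = points,
                 residuals = resid(fit)), class = "size_calibration")
}

#' Estimate saccade size from spike amplitude
#'
#' Evaluates the calibration polynomial; amplitudes outside the calibrated
#' range are clamped (flagged in the `clamped` attribute).
#'
#' @param cal A `size_calibration`.
#' @param amplitude Normalised spike amplitudes.
#' @return Estimated sizes in degrees, with attribute `clamped`.
#' @export
estimate_saccade_size <- function(cal, amplitude) {
  clamped <- amplitude < cal$range[1] | amplitude > cal$range[2]
  a <- pmin(pmax(amplitude, cal$range[1]), cal$range[2])
  est <- cal$coef[[1]] + cal$coef[[2]] * a + cal$coef[[3]] * a^2
  attr(est, "clamped") <- clamped
  est
}

#' @export
print.size_calibration <- function(x, ...) {
  cat("<size_calibration> size = ",
      signif(x$coef[[1]], 4), " + ", signif(x$coef[[2]], 4), " a + ",
      signif(x$coef[[3]], 4), " a^2  (a in [",
      signif(x$range[1], 3), ", ", signif(x$range[2], 3), "])\n", sep = "")
  invisible(x)
}

#' Detect strong head movements from the gyroscope
#'
#' Per recording block, time points whose rotational speed (magnitude of the
#' mean-centred 3-axis angular velocity) deviates from the block mean by more
#' than `sd_mult` (2.5) block SDs are marked; marked points within a 2-second
#' window are assigned to one head-movement event.
#'
#' @param session A `walk_session`.
#' @param cfg A [pipeline_config()].
#' @return Tibble `t_start`, `t_end`, `block`.
#' @export
detect_head_movements <- function(session, cfg = pipeline_config()) {
  fs <- session$fs$eeg
  blocks <- block_windows(session)
  purrr::map_dfr(seq_len(nrow(blocks)), function(b) {
    i0 <- t_to_sample(blocks$t_start[b], fs) + 1L
    i1 <- min(t_to_sample(blocks$t_end[b], fs), ncol(session$gyro))
    g <- session$gyro[, i0:i1, drop = FALSE]
    g <- g - rowMeans(g)
    speed <- sqrt(colSums(g^2))
    thr <- mean(speed) + cfg$head$sd_mult * stats::sd(speed)
    sup <- which(speed > thr)
    if (length(sup) == 0) return(NULL)
    grp <- group_time_points((i0 - 1 + sup - 1) / fs, cfg$head$merge_s)
    grp$block <- blocks$block[b]
    grp |> dplyr::select("t_start", "t_end", "block")
  })
}

#' Count artifact events inside each trial window
#'
#' Counts events whose time falls in the half-open trial window
#' `[t_start, t_end)`.
#'
#' @param trials Trial table with `trial_id`, `t_start`, `t_end`.
#' @param blinks,saccades,head_moves Event tables (from the detectors) or
#'   `NULL`.
#' @return `trials` with integer columns `n_blinks`, `n_saccades`, `n_head`
#'   (for the event tables supplied).
#' @export
count_events_per_trial <- function(trials, blinks = NULL, saccades = NULL,
                                   head_moves = NULL) {
  count_in <- function(times) {
    vapply(seq_len(nrow(trials)), function(i)
      sum(times >= trials$t_start[i] & times < trials$t_end[i]),
      integer(1))
  }
  if (!is.null(blinks)) trials$n_blinks <- count_in(blinks$t_peak %||% blinks$time)
  if (!is.null(saccades)) trials$n_saccades <- count_in(saccades$t %||% saccades$time)
  if (!is.null(head_moves)) trials$n_head <- count_in(head_moves$t_start)
  trials
}
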