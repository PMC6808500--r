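# Shared fixtures: sessions are expensive to synthesize, so test files share
# cached instances built once per run at fixed seeds.

.fixtures <- new.env(parent = emptyenv())

cached_session <- function(seed = 7, n_blocks = 1) {
  key <- sprintf("ses_%d_%d", seed, n_blocks)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- simulate_session(sim_config(seed = seed,
                                                    n_blocks = n_blocks))
  .fixtures[[key]]
}

# single-condition, single-period config for cheap spectral ground-truth runs
tiny_config <- function(seed, amp = 2) {
  amap <- matrix(amp, 1, 1, dimnames = list("still", "1"))
  tmap <- matrix(0.3, 1, 1, dimnames = list("still", "1"))
  sim_config(seed = seed, n_blocks = 1, walking_conditions = "still",
             contrast_levels = 1, ssvep_amplitude_map = amap,
             observer_threshold_map = tmap,
             alpha_amplitude_map = c(still = 3),
             hf_noise_map = c(still = 1))
}

# recall / precision of detected vs ground-truth event times
match_events <- function(detected, truth, tol) {
  if (length(truth) == 0 || length(detected) == 0)
    return(c(recall = NA_real_, precision = NA_real_))
  c(recall = mean(vapply(truth, function(t)
      any(abs(detected - t) <= tol), logical(1))),
    precision = mean(vapply(detected, function(d)
      any(abs(truth - d) <= tol), logical(1))))
}

# minimal hand-built session carrying only what a specific detector needs
stub_session <- function(signals = NULL, gyro = NULL, fs = 500, dur = 60,
                         events = NULL) {
  n <- round(dur * fs)
  lay <- channel_layout()
  labels <- c(lay$eeg, lay$eog, lay$earlobe)
  if (is.null(signals))
    signals <- matrix(0, length(labels), n, dimnames = list(labels, NULL))
  if (is.null(gyro))
    gyro <- matrix(0, 3, n, dimnames = list(c("gyro_x", "gyro_y", "gyro_z"),
                                            NULL))
  if (is.null(events))
    events <- tibble::tibble(time = 0, kind = "block_start",
                             condition = "still", contrast = NA_real_,
                             block = 1L, target_location = NA_character_)
  structure(list(signals = signals, gyro = gyro,
                 motion = matrix(0, 3, round(dur * 120),
                                 dimnames = list(c("back", "ankle_l",
                                                   "ankle_r"), NULL)),
                 events = events, fs = list(eeg = fs, motion = 120),
                 channel_labels = lay, ground_truth = list(),
                 alpha_peak = 10, participant = 1L, recording_s = dur),
            class = "walk_session")
}
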