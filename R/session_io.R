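#' Write a session to disk (EDF + TSV + JSON)
#'
#' Signals (EEG/EOG/earlobe and gyroscope at 500 Hz, motion at 120 Hz) go into
#' one EDF file; the event table and the ground-truth artifact lists are
#' written as tab-separated text; session metadata as JSON.
#'
#' @param session A `walk_session`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "walk_session"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fs <- session$fs$eeg
  sigs <- c(
    purrr::map(rownames(session$signals), function(l)
      list(label = l, fs = fs, unit = "uV", data = session$signals[l, ])),
    purrr::map(rownames(session$gyro), function(l)
      list(label = l, fs = fs, unit = "deg/s", data = session$gyro[l, ])),
    purrr::map(rownames(session$motion), function(l)
      list(label = l, fs = session$fs$motion, unit = "m/s",
           data = session$motion[l, ]))
  )
  write_edf(file.path(dir, "session.edf"), sigs)
  readr::write_tsv(session$events, file.path(dir, "events.tsv"))
  for (nm in c("blinks", "saccades", "head_moves")) {
    gt <- session$ground_truth[[nm]]
    if (!is.null(gt)) readr::write_tsv(gt, file.path(dir, paste0("gt_", nm, ".tsv")))
  }
  if (!is.null(session$ground_truth$responses))
    readr::write_tsv(session$ground_truth$responses,
                     file.path(dir, "gt_responses.tsv"))
  jsonlite::write_json(
    list(fs_eeg = fs, fs_motion = session$fs$motion,
         alpha_peak = session$alpha_peak, participant = session$participant,
         recording_s = session$recording_s),
    file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a session from disk
#'
#' Reads the EDF + TSV layout produced by [write_session()], normalises units,
#' and verifies the session invariants: the full 24-channel montage must be
#' present and all event times must lie within the recording.
#'
#' @param dir Directory containing `session.edf`, `events.tsv`, `meta.json`
#'   and optional ground-truth TSVs.
#' @return A `walk_session`.
#' @export
read_session <- function(dir) {
  edf_path <- file.path(dir, "session.edf")
  if (!file.exists(edf_path)) stop("missing session.edf in ", dir, call. = FALSE)
  edf <- read_edf(edf_path)
  labels <- vapply(edf$signals, function(s) s$label, character(1))
  lay <- channel_layout()
  expected <- c(lay$eeg, lay$eog, lay$earlobe)
  missing <- setdiff(expected, labels)
  if (length(missing) > 0)
    stop("format error: missing channel label(s): ",
         paste(missing, collapse = ", "), call. = FALSE)

  get <- function(l) edf$signals[[match(l, labels)]]$data
  signals <- do.call(rbind, lapply(expected, get))
  rownames(signals) <- expected
  gyro_labels <- grep("^gyro", labels, value = TRUE)
  motion_labels <- intersect(c("back", "ankle_l", "ankle_r"), labels)
  gyro <- do.call(rbind, lapply(gyro_labels, get))
  rownames(gyro) <- gyro_labels
  motion <- do.call(rbind, lapply(motion_labels, get))
  rownames(motion) <- motion_labels

  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  events <- readr::read_tsv(file.path(dir, "events.tsv"),
                            show_col_types = FALSE,
                            col_types = readr::cols(
                              time = "d", kind = "c", condition = "c",
                              contrast = "d", block = "i",
                              target_location = "c"))
  dur <- ncol(signals) / meta$fs_eeg
  if (any(diff(events$time) < -1e-9))
    stop("consistency error: event times must be non-decreasing", call. = FALSE)
  if (any(events$time < 0 | events$time > dur))
    stop("consistency error: event time outside recording", call. = FALSE)

  gt <- list()
  for (nm in c("blinks", "saccades", "head_moves", "responses")) {
    p <- file.path(dir, paste0("gt_", nm, ".tsv"))
    if (file.exists(p)) gt[[nm]] <- readr::read_tsv(p, show_col_types = FALSE)
  }
  structure(list(
    signals = signals, gyro = gyro, motion = motion, events = events,
    fs = list(eeg = meta$fs_eeg, motion = meta$fs_motion),
    channel_labels = lay, ground_truth = gt,
    alpha_peak = meta$alpha_peak, participant = meta$participant,
    recording_s = dur
  ), class = "walk_session")
}
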