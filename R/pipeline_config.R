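#' Analysis pipeline configuration
#'
#' Houses every numeric constant of the analysis pipeline. Defaults are the
#' canonical values of the method: 1 Hz high-pass / 100 Hz low-pass windowed-
#' sinc FIR filtering, Welch spectra with 1-second windows and 50% overlap,
#' SSVEP at 15 Hz referenced to 13/14/16/17 Hz, alpha referenced to
#' 10/11/12 Hz, high-frequency band 20-99 Hz, MAD-median exclusion with scale
#' 0.6745 and cutoff 2.24, the 20/40/15 uV blink rules with a 100 ms merge,
#' 20-90 Hz sixth-order Butterworth saccade filtering with a 2.5 SD threshold
#' and 20 ms grouping over an 80 ms spike window, 2.5 SD / 2 s head-movement
#' rules, a 1 s hit window with a 2.5 s pre-target press exclusion, and the
#' staircase parameters (1-up-4-down for titration; 1-up-3-down with 6%/3%
#' steps and 13 reversals for threshold estimation).
#'
#' @param ... Named overrides of any default (nested lists are replaced
#'   field-by-field).
#' @return An object of class `pipeline_config`.
#' @export
#' @examples
#' cfg <- pipeline_config()
#' cfg$mad$cutoff
pipeline_config <- function(...) {
  cfg <- list(
    fs = 500,
    filter = list(low = 1, high = 100, method = "fir_kaiser",
                  ripple_db = 60, transition_frac = 0.25, min_transition = 1),
    welch = list(window_s = 1.0, overlap = 0.5, taper = "hamming"),
    ssvep_freq = 15,
    ssvep_reference_freqs = c(13, 14, 16, 17),
    alpha_band = c(8, 12),
    alpha_reference_freqs = c(10, 11, 12),
    hf_band = c(20, 99),
    mad = list(scale = 0.6745, cutoff = 2.24),
    blink = list(hp = 0.2, lp = 20, cross = 20, min_peak = 40,
                 min_sd = 15, merge_s = 0.1, sd_window_s = 0.4),
    saccade = list(band = c(20, 90), order = 6, sd_mult = 2.5,
                   group_s = 0.02, window_s = 0.08, warmup_s = 0.1),
    head = list(sd_mult = 2.5, merge_s = 2),
    behavior = list(hit_window_s = 1.0, pre_press_exclusion_s = 2.5),
    envelope = list(band = c(14.5, 15.5), taper = "hamming",
                    fir_s = 1.0, edge_s = 0.5),
    perturbation = list(window = c(0.2, 0.6), alt_window = c(0.2, 1.0),
                        baseline = c(-1, 0)),
    staircase = list(rule_main = "1up4down", step_main = 0.03,
                     rule_followup = "1up3down", step_initial = 0.06,
                     step_after = 0.03, step_switch_reversal = 4,
                     n_reversals = 13, n_last_reversals = 10),
    n_select_channels = 3
  )
  overrides <- list(...)
  cfg <- merge_config(cfg, overrides)
  class(cfg) <- "pipeline_config"
  validate_pipeline_config(cfg)
}

merge_config <- function(base, overrides) {
  for (nm in names(overrides)) {
    if (!nm %in% names(base))
      stop("unknown configuration field: ", nm, call. = FALSE)
    if (is.list(base[[nm]]) && is.list(overrides[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], overrides[[nm]])
    } else {
      base[[nm]] <- overrides[[nm]]
    }
  }
  base
}

validate_pipeline_config <- function(cfg) {
  nyq <- cfg$fs / 2
  check_band <- function(b, nm) {
    if (length(b) != 2 || b[1] >= b[2] || b[1] < 0 || b[2] > nyq)
      stop("validation error: ", nm, " must be an increasing band within (0, ",
           nyq, "]", call. = FALSE)
  }
  check_band(cfg$hf_band, "hf_band")
  check_band(cfg$alpha_band, "alpha_band")
  check_band(cfg$saccade$band, "saccade$band")
  check_band(cfg$envelope$band, "envelope$band")
  if (cfg$filter$low <= 0 || cfg$filter$high >= nyq ||
      cfg$filter$low >= cfg$filter$high)
    stop("validation error: filter band must satisfy 0 < low < high < Nyquist",
         call. = FALSE)
  for (v in c(cfg$mad$scale, cfg$mad$cutoff, cfg$welch$window_s,
              cfg$blink$cross, cfg$blink$min_peak, cfg$blink$min_sd,
              cfg$saccade$sd_mult, cfg$head$sd_mult,
              cfg$behavior$hit_window_s))
    if (!is.numeric(v) || v <= 0)
      stop("validation error: constants must be positive", call. = FALSE)
  if (cfg$welch$overlap < 0 || cfg$welch$overlap >= 1)
    stop("validation error: welch$overlap must be in [0, 1)", call. = FALSE)
  cfg
}

#' Load a pipeline configuration from YAML or JSON
#'
#' An empty or absent file yields all defaults; present fields override
#' defaults and are validated.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `pipeline_config`.
#' @export
load_config <- function(path) {
  overrides <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(overrides) || length(overrides) == 0) return(pipeline_config())
  do.call(pipeline_config, overrides)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  cat("  welch:", x$welch$window_s, "s windows,",
      x$welch$overlap * 100, "% overlap\n")
  cat("  ssvep:", x$ssvep_freq, "Hz ref",
      paste(x$ssvep_reference_freqs, collapse = "/"), "Hz\n")
  cat("  mad: scale", x$mad$scale, "cutoff", x$mad$cutoff, "\n")
  invisible(x)
}
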