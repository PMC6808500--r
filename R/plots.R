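#' Mean power spectrum by walking condition
#'
#' @param spectra Spectrum table from [compute_spectra()].
#' @param trials Trial table carrying `trial_id` and `condition`.
#' @param max_freq Upper frequency limit of the plot, Hz.
#' @return A ggplot object (log10 power vs frequency, one line per condition).
#' @export
plot_spectrum <- function(spectra, trials, max_freq = 40) {
  d <- spectra |>
    dplyr::left_join(trials |> dplyr::select("trial_id", "condition"),
                     by = "trial_id") |>
    dplyr::filter(.data$freq > 0, .data$freq <= max_freq) |>
    dplyr::group_by(.data$condition, .data$freq) |>
    dplyr::summarise(power = mean(.data$power), .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$freq, y = .data$power,
                                  colour = .data$condition)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Frequency (Hz)", y = expression(Power~(mu*V^2/Hz)),
                  colour = "Condition") +
    ggplot2::theme_minimal()
}

#' Detection rate per surround contrast and walking condition
#'
#' @param cells Behavioural cell table from [behavior_cells()].
#' @return A ggplot object.
#' @export
plot_detection_rates <- function(cells) {
  ggplot2::ggplot(cells, ggplot2::aes(x = factor(.data$contrast),
                                      y = .data$detection_rate,
                                      colour = .data$condition,
                                      group = .data$condition)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "Surround contrast", y = "Detection rate",
                  colour = "Condition") +
    ggplot2::theme_minimal()
}

#' Target-locked SSVEP amplitude curve
#'
#' @param perturbation Output of [evoked_perturbation()] (uses its `curve`
#'   attribute).
#' @return A ggplot object.
#' @export
plot_perturbation <- function(perturbation) {
  curve <- attr(perturbation, "curve")
  win <- range(curve$time[curve$time >= 0])
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$time, y = .data$amplitude)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "Time from target onset (s)",
                  y = expression(SSVEP~amplitude~(mu*V))) +
    ggplot2::theme_minimal()
}

#' Cell means of a spectral analysis
#'
#' Referenced SSVEP power per contrast level and walking condition.
#'
#' @param object A `walk_analysis` from [analyze_session()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot walk_analysis
#' @export
autoplot.walk_analysis <- function(object, ...) {
  ggplot2::ggplot(object$cells,
                  ggplot2::aes(x = factor(.data$contrast), y = .data$ref_ssvep,
                               colour = .data$condition,
                               group = .data$condition)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "Surround contrast",
                  y = expression(Referenced~SSVEP~power~(mu*V^2/Hz)),
                  colour = "Condition") +
    ggplot2::theme_minimal()
}
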