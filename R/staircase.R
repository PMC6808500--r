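#' Create a transformed up/down staircase
#'
#' `1upKdown` rule: any miss raises the stimulus level by the current step;
#' `K` consecutive hits lower it by the step and reset the counter. Such a
#' staircase converges to the level where the K-fold hit probability is 0.5,
#' i.e. percent correct 0.5^(1/4) = 84% for 1-up-4-down and 0.5^(1/3) = 79%
#' for 1-up-3-down. For the 1-up-3-down threshold procedure the step size
#' switches from `step` to `step_after` at the `step_switch_reversal`-th
#' reversal and the run terminates after `n_reversals` reversals.
#'
#' @param rule `"1up4down"` or `"1up3down"`.
#' @param level Initial stimulus level.
#' @param step Initial step size (level units).
#' @param step_after Step size after the switch reversal (`NULL` = fixed step).
#' @param step_switch_reversal Reversal count at which the step switches.
#' @param n_reversals Reversal count at which the run terminates (`Inf` = run
#'   forever).
#' @return A `staircase` object.
#' @export
#' @examples
#' st <- staircase("1up4down", level = 0.8, step = 0.03)
#' st <- staircase_step(st, correct = TRUE)
#' st$level
staircase <- function(rule = c("1up4down", "1up3down"), level, step,
                      step_after = NULL, step_switch_reversal = 4,
                      n_reversals = Inf) {
  rule <- match.arg(rule)
  structure(list(
    rule = rule, k_down = if (rule == "1up4down") 4L else 3L,
    level = level, step = step, step_after = step_after,
    step_switch_reversal = step_switch_reversal, n_reversals = n_reversals,
    consecutive_correct = 0L, last_direction = 0L, trial = 0L,
    reversal_trial = integer(0), reversal_level = numeric(0),
    history_level = numeric(0), history_correct = logical(0),
    finished = FALSE, clamped = FALSE
  ), class = "staircase")
}

#' Advance a staircase by one trial
#'
#' @param state A [staircase()] object.
#' @param correct Whether the response on this trial was correct (a hit).
#' @return The updated `staircase`; `$finished` becomes `TRUE` once the
#'   reversal criterion is met. Levels are clamped at 0 (flagged `clamped`).
#' @export
staircase_step <- function(state, correct) {
  stopifnot(inherits(state, "staircase"))
  if (state$finished) return(state)
  state$trial <- state$trial + 1L
  state$history_level <- c(state$history_level, state$level)
  state$history_correct <- c(state$history_correct, correct)

  direction <- 0L
  if (correct) {
    state$consecutive_correct <- state$consecutive_correct + 1L
    if (state$consecutive_correct >= state$k_down) {
      direction <- -1L
      state$consecutive_correct <- 0L
    }
  } else {
    direction <- 1L
    state$consecutive_correct <- 0L
  }

  if (direction != 0L) {
    if (state$last_direction != 0L && direction != state$last_direction) {
      state$reversal_trial <- c(state$reversal_trial, state$trial)
      state$reversal_level <- c(state$reversal_level, state$level)
      if (!is.null(state$step_after) &&
          length(state$reversal_trial) == state$step_switch_reversal)
        state$step <- state$step_after
      if (length(state$reversal_trial) >= state$n_reversals)
        state$finished <- TRUE
    }
    state$last_direction <- direction
    state$level <- state$level + direction * state$step
    if (state$level < 0) {
      state$level <- 0
      state$clamped <- TRUE
    }
  }
  state
}

#' Trial history of a staircase
#'
#' @param state A `staircase` object.
#' @return Tibble `trial`, `level`, `correct`.
#' @export
staircase_history <- function(state) {
  tibble::tibble(trial = seq_along(state$history_level),
                 level = state$history_level,
                 correct = state$history_correct)
}

#' Reversal points of a staircase
#'
#' @param state A `staircase` object.
#' @return Tibble `trial`, `level` (one row per reversal, in order).
#' @export
staircase_reversals <- function(state) {
  tibble::tibble(trial = state$reversal_trial, level = state$reversal_level)
}

#' Run a staircase against a simulated observer
#'
#' The observer answers each trial correctly with probability
#' [psi_detect()]`(level, threshold, slope, lapse)`.
#'
#' @param state A [staircase()] object.
#' @param threshold,slope,lapse Observer psychometric parameters.
#' @param n_trials Maximum number of trials.
#' @return The final `staircase` (with full history and reversals).
#' @export
run_staircase <- function(state, threshold, slope, lapse = 0,
                          n_trials = 2000) {
  for (i in seq_len(n_trials)) {
    if (state$finished) break
    p <- psi_detect(state$level, threshold, slope, lapse)
    state <- staircase_step(state, runif(1) < p)
  }
  state
}

#' Threshold estimate from the last reversals
#'
#' Mean stimulus level of the last `n_last` reversal points (the follow-up
#' procedure averages the last 10 of 13).
#'
#' @param state A finished `staircase`.
#' @param n_last Number of final reversals to average.
#' @return Threshold estimate (level units).
#' @export
staircase_threshold <- function(state, n_last = 10) {
  nr <- length(state$reversal_level)
  if (nr < n_last)
    stop("only ", nr, " reversals; need ", n_last, call. = FALSE)
  mean(tail(state$reversal_level, n_last))
}

#' @export
print.staircase <- function(x, ...) {
  cat("<staircase ", x$rule, "> trial ", x$trial, ", level ",
      signif(x$level, 4), ", ", length(x$reversal_trial), " reversals",
      if (x$finished) " (finished)", "\n", sep = "")
  invisible(x)
}

#' Staircase track plot
#'
#' Level per trial with reversal points marked.
#'
#' @param state A `staircase` object with history.
#' @return A ggplot object.
#' @export
plot_staircase <- function(state) {
  ggplot2::ggplot(staircase_history(state),
                  ggplot2::aes(x = .data$trial, y = .data$level)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(ggplot2::aes(shape = .data$correct), size = 1.5) +
    ggplot2::geom_point(data = staircase_reversals(state), colour = "red",
                        size = 2) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1)) +
    ggplot2::labs(x = "Trial", y = "Stimulus level",
                  title = paste("Staircase", state$rule),
                  shape = "Correct") +
    ggplot2::theme_minimal()
}
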