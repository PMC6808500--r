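#' Score button presses against target onsets
#'
#' A press is a hit for the earliest unassigned target whose onset lies within
#' `hit_window_s` (1 s) before the press; each press is assigned to at most
#' one target and each target collects at most one press. All unassigned
#' presses are false alarms, attributed to the condition/contrast cell active
#' at press time.
#'
#' @param events Event table with `target_onset` and `button_press` rows.
#' @param cfg A [pipeline_config()].
#' @return Tibble with one row per target: `condition`, `contrast`, `block`,
#'   `location`, `t_target`, `hit`, `rt`; false alarms are attached as the
#'   `false_alarms` attribute (tibble `time`, `condition`, `contrast`).
#' @export
score_responses <- function(events, cfg = pipeline_config()) {
  targets <- events |> dplyr::filter(.data$kind == "target_onset") |>
    dplyr::arrange(.data$time)
  presses <- events |> dplyr::filter(.data$kind == "button_press") |>
    dplyr::arrange(.data$time)
  win <- cfg$behavior$hit_window_s

  hit <- rep(FALSE, nrow(targets))
  rt <- rep(NA_real_, nrow(targets))
  assigned <- rep(FALSE, nrow(presses))
  for (j in seq_len(nrow(presses))) {
    tp <- presses$time[j]
    cand <- which(!hit & targets$time < tp & tp <= targets$time + win)
    if (length(cand) > 0) {
      i <- cand[1]  # earliest unassigned target in window
      hit[i] <- TRUE
      rt[i] <- tp - targets$time[i]
      assigned[j] <- TRUE
    }
  }

  out <- tibble::tibble(
    condition = targets$condition, contrast = targets$contrast,
    block = targets$block, location = targets$target_location,
    t_target = targets$time, hit = hit, rt = rt)
  attr(out, "false_alarms") <- presses[!assigned, ] |>
    dplyr::select("time", "condition", "contrast", "block")
  out
}

#' Per-cell behavioural summary
#'
#' Detection rate (hits / targets), mean RT over hits, and false-alarm count
#' per walking condition x contrast cell.
#'
#' @param scored Output of [score_responses()].
#' @return Tibble `condition`, `contrast`, `n_targets`, `detection_rate`,
#'   `mean_rt`, `false_alarms`.
#' @export
behavior_cells <- function(scored) {
  fa <- attr(scored, "false_alarms")
  fa_counts <- if (!is.null(fa) && nrow(fa) > 0) {
    fa |>
      dplyr::filter(!is.na(.data$contrast)) |>
      dplyr::count(.data$condition, .data$contrast, name = "false_alarms")
  } else {
    tibble::tibble(condition = character(0), contrast = numeric(0),
                   false_alarms = integer(0))
  }
  scored |>
    dplyr::group_by(.data$condition, .data$contrast) |>
    dplyr::summarise(
      n_targets = dplyr::n(),
      detection_rate = mean(.data$hit),
      mean_rt = mean(.data$rt, na.rm = TRUE),
      .groups = "drop") |>
    dplyr::left_join(fa_counts, by = c("condition", "contrast")) |>
    dplyr::mutate(false_alarms = dplyr::coalesce(.data$false_alarms, 0L))
}

#' Target preference index
#'
#' Normalised sum of absolute deviations of per-location detection rates from
#' their mean: `sum(|T - t_i|) / (6 T)` with `T = mean(t_i)`. 0 when all four
#' locations are detected equally; 1 when all detections fall on a single
#' location. Undefined (error) when no targets were detected (`T = 0`).
#'
#' @param rates Numeric vector of 4 per-location detection rates.
#' @return Index in `[0, 1]`.
#' @export
#' @examples
#' preference_index(c(0.5, 0.5, 0.5, 0.5))  # 0
#' preference_index(c(0.8, 0, 0, 0))        # 1
preference_index <- function(rates) {
  stopifnot(length(rates) == 4, all(rates >= 0))
  T_bar <- mean(rates)
  if (T_bar == 0)
    stop("preference index undefined: no targets detected (T = 0)",
         call. = FALSE)
  sum(abs(T_bar - rates)) / (6 * T_bar)
}

#' Simulation null for the preference index
#'
#' Distributes the observed number of detections independently and uniformly
#' over the four locations `n_sims` times, computes the preference index of
#' each simulated distribution, and returns the fraction of simulated indices
#' strictly larger than the observed one.
#'
#' @param observed_index Observed preference index.
#' @param n_detected Total number of detected targets.
#' @param n_targets_per_loc Targets presented per location (rate denominator).
#' @param n_sims Number of simulations (default 1000).
#' @return List with `p` and the vector of `sim_indices`.
#' @export
preference_null <- function(observed_index, n_detected, n_targets_per_loc,
                            n_sims = 1000) {
  stopifnot(n_detected > 0)
  sims <- vapply(seq_len(n_sims), function(i) {
    loc <- sample.int(4, n_detected, replace = TRUE)
    counts <- tabulate(loc, nbins = 4)
    preference_index(counts / n_targets_per_loc)
  }, numeric(1))
  list(p = mean(sims > observed_index), sim_indices = sims)
}

#' Relative threshold difference between walking and standing
#'
#' `(walking - still) / (walking + still)`, in `[-1, 1]`.
#'
#' @param walk,still Detection thresholds under walking/standing.
#' @return The ratio.
#' @export
relative_threshold_diff <- function(walk, still) {
  if (any(walk + still <= 0))
    stop("undefined: walking + still threshold must be positive", call. = FALSE)
  (walk - still) / (walk + still)
}

#' Baseline-matched participant subset
#'
#' Ranks participants by a key (descending; ties broken by participant id) and
#' removes the top `n_exclude`, equalising a baseline difference across the
#' remaining subset.
#'
#' @param table Tibble with one row per participant.
#' @param rank_key Column name of the ranking key.
#' @param n_exclude Number of top-ranked participants to drop.
#' @param id Column name of the participant id.
#' @return The retained rows, with attribute `excluded` (the dropped rows).
#' @export
baseline_matched_subset <- function(table, rank_key, n_exclude,
                                    id = "participant") {
  if (n_exclude >= nrow(table))
    stop("n_exclude must be smaller than the number of participants",
         call. = FALSE)
  ord <- order(-table[[rank_key]], table[[id]])
  dropped <- ord[seq_len(n_exclude)]
  out <- table[setdiff(seq_len(nrow(table)), dropped), ]
  attr(out, "excluded") <- table[dropped, ]
  out
}
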