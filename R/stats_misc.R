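#' Paired t test with Cohen's d_z
#'
#' Two-tailed paired t test; the effect size d_z is the mean of the pairwise
#' differences divided by their SD.
#'
#' @param x,y Paired numeric vectors of equal length (>= 2).
#' @return One-row tibble: `statistic` (t), `df`, `p.value`, `d_z`,
#'   `mean_diff`.
#' @export
paired_t <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  d <- x - y
  if (stats::sd(d) == 0)
    stop("zero-variance differences: paired t undefined", call. = FALSE)
  tt <- t.test(x, y, paired = TRUE)
  tibble::tibble(
    statistic = unname(tt$statistic), df = unname(tt$parameter),
    p.value = tt$p.value, d_z = mean(d) / stats::sd(d), mean_diff = mean(d))
}

#' Benjamini-Hochberg false-discovery-rate control
#'
#' Step-up adjusted p-values and the rejection set at level `q`.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @param q FDR level.
#' @return Tibble `p`, `p_adjusted`, `rejected`, in input order.
#' @export
fdr_bh <- function(p, q = 0.05) {
  stopifnot(all(p >= 0 & p <= 1))
  adj <- p.adjust(p, method = "BH")
  tibble::tibble(p = p, p_adjusted = adj, rejected = adj <= q)
}

#' Median split of trials by raw SSVEP power, with HF-power matching
#'
#' Within each walking condition, trials are split at the median raw SSVEP
#' power into a weak and a strong group (the median trial goes to the weak
#' group on odd counts). For the walking conditions, the five trials with the
#' lowest high-frequency power are removed from the weak group and the five
#' with the highest from the strong group, eliminating the HF-power confound
#' between groups; the trimming is skipped (with a warning) when either group
#' would drop below five trials.
#'
#' @param trials Trial table with `trial_id`, `condition`.
#' @param power Tibble with `trial_id`, `raw_power` (raw SSVEP power) and
#'   `hf_power`.
#' @param walking_conditions Conditions receiving the HF trimming.
#' @param n_trim Trials trimmed from each group (default 5).
#' @return `trials` with columns `ssvep_group` (`"weak"`/`"strong"`) and
#'   `trimmed` (logical; trimmed trials keep their group label).
#' @export
median_split_matched <- function(trials, power,
                                 walking_conditions = c("slow", "normal"),
                                 n_trim = 5) {
  d <- dplyr::left_join(trials, power, by = "trial_id")
  counts <- table(d$condition)
  if (any(counts < 12))
    stop("need at least 12 trials per walking condition", call. = FALSE)
  d <- d |>
    dplyr::group_by(.data$condition) |>
    dplyr::mutate(ssvep_group = ifelse(.data$raw_power <= median(.data$raw_power),
                                       "weak", "strong")) |>
    dplyr::ungroup()
  d$trimmed <- FALSE
  for (cond in intersect(walking_conditions, unique(d$condition))) {
    weak <- which(d$condition == cond & d$ssvep_group == "weak")
    strong <- which(d$condition == cond & d$ssvep_group == "strong")
    if (length(weak) < 2 * n_trim || length(strong) < 2 * n_trim) {
      warning("HF trimming skipped for '", cond,
              "': groups would fall below ", n_trim, " trials", call. = FALSE)
      next
    }
    d$trimmed[weak[order(d$hf_power[weak])[seq_len(n_trim)]]] <- TRUE
    d$trimmed[strong[order(-d$hf_power[strong])[seq_len(n_trim)]]] <- TRUE
  }
  d
}

#' Band-power contrast between SSVEP median-split groups
#'
#' Mean band power of untrimmed trials per group for the standard bands
#' (delta 2-3, theta 4-7, alpha 8-12, high-frequency 20-99 Hz).
#'
#' @param split Output of [median_split_matched()].
#' @param spectra Spectrum table from [compute_spectra()].
#' @param channels Channels to average over.
#' @param bands Named list of bands.
#' @return Tibble `condition`, `band`, `weak`, `strong`.
#' @export
split_band_powers <- function(split, spectra, channels = NULL,
                              bands = list(delta = c(2, 3), theta = c(4, 7),
                                           alpha = c(8, 12), hf = c(20, 99))) {
  keep <- split |> dplyr::filter(!.data$trimmed)
  purrr::imap_dfr(bands, function(band, nm) {
    bp <- trial_band_power(spectra, band, channels)
    dplyr::left_join(keep, bp, by = "trial_id") |>
      dplyr::group_by(.data$condition, .data$ssvep_group) |>
      dplyr::summarise(power = mean(.data$power), .groups = "drop") |>
      tidyr::pivot_wider(names_from = "ssvep_group", values_from = "power") |>
      dplyr::mutate(band = nm, .before = 1)
  }) |> dplyr::select("condition", "band", "weak", "strong")
}

#' Count-matched averaging
#'
#' Averages a measure within each stratum of an artifact count (e.g. number
#' of blinks per trial), then takes the unweighted mean across strata,
#' removing the confound of unequal count distributions between conditions.
#'
#' @param counts Integer vector (per-trial artifact counts).
#' @param measure Numeric vector (per-trial measure).
#' @return Unweighted mean of the stratum means.
#' @export
#' @examples
#' count_matched_average(c(0, 0, 0, 1), c(1, 1, 1, 3))  # (1 + 3) / 2 = 2
count_matched_average <- function(counts, measure) {
  stopifnot(length(counts) == length(measure))
  strata <- tapply(measure, counts, mean)
  mean(strata)
}

#' Two-level regression of trial SSVEP power on alpha power and artifacts
#'
#' Level 1: per participant, trial SSVEP power is regressed on trial alpha
#' power and the per-trial numbers of blinks and saccades by ordinary least
#' squares, with SSVEP and alpha power z-scored within each testing block
#' (removing between-block power shifts). Level 2: each predictor's slopes
#' are tested against zero with a one-sample t across participants.
#' Participants with a rank-deficient level-1 design (e.g. constant alpha)
#' are skipped with a warning.
#'
#' @param trials Tibble with columns `participant`, `block`, `ssvep`,
#'   `alpha`, `n_blinks`, `n_saccades`.
#' @return List with `slopes` (tibble participant x predictor) and `group`
#'   (tibble per predictor: mean slope, `statistic`, `df`, `p.value`).
#' @export
two_level_regression <- function(trials) {
  preds <- c("alpha", "n_blinks", "n_saccades")
  slopes <- purrr::map_dfr(unique(trials$participant), function(p) {
    d <- trials |> dplyr::filter(.data$participant == p)
    if (nrow(d) < length(preds) + 2) {
      warning("participant ", p, " skipped: too few trials", call. = FALSE)
      return(NULL)
    }
    zs <- function(x) if (stats::sd(x) > 0) (x - mean(x)) / stats::sd(x) else x * 0
    d <- d |>
      dplyr::group_by(.data$block) |>
      dplyr::mutate(ssvep = zs(.data$ssvep), alpha = zs(.data$alpha)) |>
      dplyr::ungroup()
    X <- cbind(1, d$alpha, d$n_blinks, d$n_saccades)
    if (qr(X)$rank < ncol(X)) {
      warning("participant ", p, " skipped: rank-deficient design",
              call. = FALSE)
      return(NULL)
    }
    fit <- lm(ssvep ~ alpha + n_blinks + n_saccades, data = d)
    tibble::tibble(participant = p, predictor = preds,
                   slope = unname(coef(fit)[-1]))
  })
  group <- slopes |>
    dplyr::group_by(.data$predictor) |>
    dplyr::group_modify(function(g, key) {
      if (nrow(g) < 2)
        return(tibble::tibble(mean_slope = mean(g$slope),
                              statistic = NA_real_, df = NA_real_,
                              p.value = NA_real_))
      tt <- t.test(g$slope)
      tibble::tibble(mean_slope = mean(g$slope),
                     statistic = unname(tt$statistic),
                     df = unname(tt$parameter), p.value = tt$p.value)
    }) |>
    dplyr::ungroup()
  list(slopes = slopes, group = group)
}
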