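#' Within-subjects (repeated-measures) ANOVA with Greenhouse-Geisser correction
#'
#' One- or two-factor fully within-subjects ANOVA computed directly from sums
#' of squares. For each effect, sphericity is assessed with Mauchly's test on
#' the orthonormal-contrast covariance matrix; when violated (p < `alpha`),
#' the Greenhouse-Geisser epsilon multiplies both degrees of freedom before
#' the p-value is computed. Partial eta squared is
#' `SS_effect / (SS_effect + SS_error)`.
#'
#' @param data Tibble in long format: one row per subject x cell, complete
#'   crossed design.
#' @param dv Name of the response column.
#' @param within Character vector of 1 or 2 within-subject factor columns.
#' @param subject Name of the subject id column.
#' @param gg_alpha Mauchly significance level gating the GG correction.
#' @return An object of class `rm_anova`; see [tidy.rm_anova()].
#' @export
#' @examples
#' d <- tidyr::expand_grid(s = 1:8, a = c("x", "y", "z"))
#' d$y <- rnorm(nrow(d)) + as.numeric(factor(d$a))
#' fit <- rm_anova(d, "y", "a", "s")
#' tidy(fit)
rm_anova <- function(data, dv, within, subject, gg_alpha = 0.05) {
  stopifnot(length(within) %in% c(1, 2))
  d <- data[, c(subject, within, dv)]
  names(d) <- c(".s", paste0(".w", seq_along(within)), ".y")
  if (anyNA(d$.y)) stop("missing cells in the design", call. = FALSE)
  d$.s <- factor(d$.s)
  for (w in grep("^\\.w", names(d), value = TRUE)) d[[w]] <- factor(d[[w]])
  n <- nlevels(d$.s)

  # complete-design check: every subject x cell combination exactly once
  tab <- table(d[, setdiff(names(d), ".y")])
  if (any(tab != 1))
    stop("design must be complete with one observation per subject x cell",
         call. = FALSE)

  grand <- mean(d$.y)
  ss <- function(means, mult) mult * sum((means - grand)^2)
  m_s <- tapply(d$.y, d$.s, mean)

  if (length(within) == 1) {
    a <- nlevels(d$.w1)
    m_a <- tapply(d$.y, d$.w1, mean)
    ss_a <- ss(m_a, n)
    ss_s <- ss(m_s, a)
    ss_tot <- sum((d$.y - grand)^2)
    ss_err <- ss_tot - ss_a - ss_s
    eff <- effect_row(d, "A", ss_a, ss_err, (a - 1), (a - 1) * (n - 1),
                      within, gg_alpha, n)
    res <- eff
  } else {
    a <- nlevels(d$.w1); b <- nlevels(d$.w2)
    m_a <- tapply(d$.y, d$.w1, mean)
    m_b <- tapply(d$.y, d$.w2, mean)
    m_ab <- tapply(d$.y, list(d$.w1, d$.w2), mean)
    m_as <- tapply(d$.y, list(d$.w1, d$.s), mean)
    m_bs <- tapply(d$.y, list(d$.w2, d$.s), mean)

    ss_a <- ss(m_a, n * b)
    ss_b <- ss(m_b, n * a)
    ss_s <- ss(m_s, a * b)
    ss_ab <- sum((m_ab - outer(m_a, m_b, `+`) + grand)^2) * n
    ss_as <- sum((m_as - outer(m_a - grand, m_s - grand, `+`) - grand)^2) * b
    ss_bs <- sum((m_bs - outer(m_b - grand, m_s - grand, `+`) - grand)^2) * a
    ss_tot <- sum((d$.y - grand)^2)
    ss_abs <- ss_tot - ss_a - ss_b - ss_s - ss_ab - ss_as - ss_bs

    res <- dplyr::bind_rows(
      effect_row(d, "A", ss_a, ss_as, a - 1, (a - 1) * (n - 1),
                 within, gg_alpha, n),
      effect_row(d, "B", ss_b, ss_bs, b - 1, (b - 1) * (n - 1),
                 within, gg_alpha, n),
      effect_row(d, "A:B", ss_ab, ss_abs, (a - 1) * (b - 1),
                 (a - 1) * (b - 1) * (n - 1), within, gg_alpha, n))
  }
  structure(list(table = res, within = within, dv = dv, n_subjects = n,
                 gg_alpha = gg_alpha), class = "rm_anova")
}

# Builds one result row, including sphericity assessment of the effect.
effect_row <- function(d, effect, ss_eff, ss_err, df1, df2, within,
                       gg_alpha, n) {
  Y <- subject_cell_matrix(d, effect)
  C <- effect_contrasts(d, effect)
  sph <- sphericity(Y, C, n)
  use_gg <- !is.na(sph$mauchly_p) && sph$mauchly_p < gg_alpha
  eps <- if (use_gg) sph$gg_eps else 1
  ms_eff <- ss_eff / df1
  ms_err <- ss_err / df2
  Fv <- if (ms_err > 0) ms_eff / ms_err else if (ms_eff == 0) 0 else Inf
  p <- pf(Fv, df1 * eps, df2 * eps, lower.tail = FALSE)
  label <- switch(effect, A = within[1], B = within[2],
                  `A:B` = paste(within, collapse = ":"))
  tibble::tibble(
    effect = label, ss = ss_eff, ss_error = ss_err,
    df1 = df1, df2 = df2, statistic = Fv,
    gg_epsilon = sph$gg_eps, mauchly_w = sph$mauchly_w,
    mauchly_p = sph$mauchly_p, gg_applied = use_gg,
    df1_adj = df1 * eps, df2_adj = df2 * eps,
    p.value = p,
    pes = if (ss_eff + ss_err > 0) ss_eff / (ss_eff + ss_err) else NA_real_)
}

# subjects x cells matrix of means for the cells spanned by an effect
subject_cell_matrix <- function(d, effect) {
  f <- switch(effect,
              A = interaction(d$.w1, drop = TRUE),
              B = interaction(d$.w2, drop = TRUE),
              `A:B` = interaction(d$.w1, d$.w2, drop = TRUE))
  m <- tapply(d$.y, list(d$.s, f), mean)
  m
}

# orthonormal contrast matrix for an effect (columns orthonormal, sum-to-zero)
effect_contrasts <- function(d, effect) {
  helm <- function(k) {
    m <- stats::contr.helmert(k)
    sweep(m, 2, sqrt(colSums(m^2)), `/`)
  }
  if (effect %in% c("A", "B")) {
    k <- if (effect == "A") nlevels(d$.w1) else nlevels(d$.w2)
    helm(k)
  } else {
    # interaction contrasts: Kronecker of the two factors' contrasts,
    # consistent with interaction(d$.w1, d$.w2) column ordering
    kronecker(helm(nlevels(d$.w2)), helm(nlevels(d$.w1)))
  }
}

# Mauchly's W and Greenhouse-Geisser epsilon on the contrast covariance.
sphericity <- function(Y, C, n) {
  if (ncol(C) < 2)
    return(list(mauchly_w = NA_real_, mauchly_p = NA_real_, gg_eps = 1))
  Z <- Y %*% C
  S <- stats::cov(Z)
  k <- ncol(S)
  if (sum(diag(S)) <= 0)  # zero contrast variance: sphericity trivially holds
    return(list(mauchly_w = NA_real_, mauchly_p = NA_real_, gg_eps = 1))
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  gg <- (sum(ev))^2 / (k * sum(ev^2))
  gg <- max(gg, 1 / k)
  if (n - 1 < k)  # covariance singular: Mauchly undefined
    return(list(mauchly_w = NA_real_, mauchly_p = NA_real_, gg_eps = gg))
  W <- det(S) / (sum(diag(S)) / k)^k
  if (W <= 0)
    return(list(mauchly_w = W, mauchly_p = 0, gg_eps = gg))
  # chi-square approximation with the standard second-order correction term
  rho <- 1 - (2 * k^2 + k + 2) / (6 * k * (n - 1))
  chi <- -(n - 1) * rho * log(W)
  df <- k * (k + 1) / 2 - 1
  omega <- (k + 2) * (k - 1) * (k - 2) * (2 * k^3 + 6 * k^2 + 3 * k + 2) /
    (288 * k^2 * (n - 1)^2 * rho^2)
  p <- pchisq(chi, df, lower.tail = FALSE) +
    omega * (pchisq(chi, df + 4, lower.tail = FALSE) -
               pchisq(chi, df, lower.tail = FALSE))
  list(mauchly_w = W, mauchly_p = p, gg_eps = gg)
}

#' @export
print.rm_anova <- function(x, ...) {
  cat("Within-subjects ANOVA on '", x$dv, "' (n = ", x$n_subjects,
      " subjects)\n", sep = "")
  tab <- x$table
  for (i in seq_len(nrow(tab))) {
    cat(sprintf("  %-24s F(%.4g, %.4g) = %.3f, p = %.4g, pes = %.3f%s\n",
                tab$effect[i], tab$df1_adj[i], tab$df2_adj[i],
                tab$statistic[i], tab$p.value[i], tab$pes[i],
                if (tab$gg_applied[i]) " [GG]" else ""))
  }
  invisible(x)
}

#' Tidy a within-subjects ANOVA
#'
#' @param x An `rm_anova` object.
#' @param ... Unused.
#' @return Tibble with one row per effect: `effect`, `df1`, `df2`,
#'   `statistic` (F), `gg_epsilon`, `gg_applied`, adjusted dfs, `p.value`,
#'   and partial eta squared (`pes`).
#' @method tidy rm_anova
#' @export
tidy.rm_anova <- function(x, ...) x$table

#' One-line summary of a within-subjects ANOVA
#'
#' @param x An `rm_anova` object.
#' @param ... Unused.
#' @return One-row tibble: number of subjects, factors, smallest adjusted
#'   p-value.
#' @method glance rm_anova
#' @export
glance.rm_anova <- function(x, ...) {
  tibble::tibble(
    n_subjects = x$n_subjects,
    n_effects = nrow(x$table),
    min_p = min(x$table$p.value))
}
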