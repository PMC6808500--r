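test_that("rm_anova matches the aov error-strata oracle to 1e-10", {
  set.seed(31)
  for (rep in 1:3) {
    d <- tidyr::expand_grid(s = factor(1:8), a = factor(1:3), b = factor(1:4))
    d$y <- rnorm(nrow(d)) + as.numeric(d$a) * 0.4 +
      as.numeric(d$a) * as.numeric(d$b) * 0.15
    fit <- tidy(rm_anova(d, "y", c("a", "b"), "s"))
    or <- summary(stats::aov(y ~ a * b + Error(s / (a * b)), data = d))
    f_or <- c(or[["Error: s:a"]][[1]]$`F value`[1],
              or[["Error: s:b"]][[1]]$`F value`[1],
              or[["Error: s:a:b"]][[1]]$`F value`[1])
    p_or <- c(or[["Error: s:a"]][[1]]$`Pr(>F)`[1],
              or[["Error: s:b"]][[1]]$`Pr(>F)`[1],
              or[["Error: s:a:b"]][[1]]$`Pr(>F)`[1])
    expect_equal(fit$statistic, f_or, tolerance = 1e-10)
    # uncorrected p at nominal dfs matches aov
    p_mine <- pf(fit$statistic, fit$df1, fit$df2, lower.tail = FALSE)
    expect_equal(p_mine, p_or, tolerance = 1e-10)
    expect_equal(fit$df1, c(2, 3, 6))
    expect_equal(fit$df2, c(14, 21, 42))
  }
})

test_that("rm_anova sphericity quantities match the car / mauchly.test oracles", {
  set.seed(32)
  d <- tidyr::expand_grid(s = factor(1:10), a = factor(1:3), b = factor(1:4))
  d$y <- rnorm(nrow(d)) + rep(rnorm(10, sd = 1.5), each = 12) *
    as.numeric(d$a)
  fit <- tidy(rm_anova(d, "y", c("a", "b"), "s"))

  wide <- tidyr::pivot_wider(d, names_from = c("a", "b"), values_from = "y")
  mlm <- stats::lm(as.matrix(wide[, -1]) ~ 1)
  id <- expand.grid(b = factor(1:4), a = factor(1:3))[, c("a", "b")]
  av <- suppressWarnings(car::Anova(mlm, idata = id, idesign = ~ a * b,
                                    type = 3))
  s <- suppressWarnings(summary(av, multivariate = FALSE))
  expect_equal(unname(fit$gg_epsilon), unname(s$pval.adjustments[, "GG eps"]),
               tolerance = 1e-8)
  expect_equal(unname(fit$mauchly_w),
               unname(s$sphericity.tests[, "Test statistic"]),
               tolerance = 1e-8)

  # one-way Mauchly matches stats::mauchly.test
  d1 <- tidyr::expand_grid(s = factor(1:12), a = factor(1:4))
  set.seed(33)
  d1$y <- rnorm(nrow(d1)) + rep(rnorm(12), each = 4) *
    c(1, 2, 0.5, 1)[as.numeric(d1$a)]
  f1 <- tidy(rm_anova(d1, "y", "a", "s"))
  w1 <- tidyr::pivot_wider(d1, names_from = "a", values_from = "y")
  mt <- stats::mauchly.test(stats::lm(as.matrix(w1[, -1]) ~ 1), X = ~1)
  expect_equal(f1$mauchly_w, unname(mt$statistic), tolerance = 1e-10)
  expect_equal(f1$mauchly_p, mt$p.value, tolerance = 1e-3)
})

test_that("rm_anova degenerate designs behave as specified", {
  # all responses equal: F = 0
  d <- tidyr::expand_grid(s = factor(1:6), a = factor(1:3))
  d$y <- 5
  expect_equal(tidy(rm_anova(d, "y", "a", "s"))$statistic, 0)

  # 2-level factor: epsilon exactly 1 (one difference variable)
  d2 <- tidyr::expand_grid(s = factor(1:8), a = factor(1:2))
  set.seed(34)
  d2$y <- rnorm(nrow(d2))
  expect_equal(tidy(rm_anova(d2, "y", "a", "s"))$gg_epsilon, 1)

  # missing cells error
  d3 <- d[-1, ]
  expect_error(rm_anova(d3, "y", "a", "s"), "complete")
})

test_that("paired t statistic, p and d_z match an independent formula oracle", {
  expect_error(paired_t(1:5, 1:5), "zero-variance")

  # worked pair set evaluated via the textbook formulas
  x <- c(12.1, 14.2, 13.8, 11.5, 15.0, 13.3, 12.8, 14.6)
  y <- c(11.3, 13.1, 13.9, 10.8, 14.2, 12.5, 12.9, 13.4)
  res <- paired_t(x, y)
  d <- x - y
  t_manual <- mean(d) / (sd(d) / sqrt(length(d)))
  p_manual <- 2 * pt(abs(t_manual), length(d) - 1, lower.tail = FALSE)
  expect_equal(res$statistic, t_manual, tolerance = 1e-12)
  expect_equal(res$p.value, p_manual, tolerance = 1e-12)
  expect_equal(res$df, 7)
  expect_equal(res$d_z, mean(d) / sd(d), tolerance = 1e-12)

  # large-sample d_z approaches shift / sd
  set.seed(35)
  a <- rnorm(4000)
  b <- a - (0.5 + rnorm(4000, sd = 1))
  expect_equal(paired_t(a, b)$d_z, 0.5, tolerance = 0.06)
})

test_that("Benjamini-Hochberg control matches the hand step-up oracle", {
  r <- fdr_bh(c(0.01, 0.02, 0.03, 0.04), q = 0.05)
  expect_true(all(r$rejected))
  expect_false(any(fdr_bh(rep(1, 6))$rejected))

  bh_oracle <- function(p, q) {
    m <- length(p)
    o <- order(p)
    k <- which(p[o] <= q * seq_len(m) / m)
    rej <- logical(m)
    if (length(k) > 0) rej[o[seq_len(max(k))]] <- TRUE
    rej
  }
  set.seed(36)
  for (i in 1:25) {
    p <- runif(sample(3:40, 1))^sample(1:3, 1)
    r <- fdr_bh(p, q = 0.05)
    expect_identical(r$rejected, bh_oracle(p, 0.05))
    # adjusted p non-decreasing in sorted order
    expect_true(all(diff(r$p_adjusted[order(r$p)]) >= -1e-15))
  }
})

test_that("median split with HF matching recovers alpha-SSVEP coupling", {
  gen_subject <- function(seed, rho) {
    set.seed(seed)
    n <- 40
    purrr::map_dfr(c("still", "slow", "normal"), function(cond) {
      z <- rnorm(n)
      tibble::tibble(
        trial_id = seq_len(n) + n * match(cond, c("still", "slow", "normal")),
        condition = cond,
        raw_power = exp(0.4 * z) + rnorm(n, sd = 0.05),
        alpha = 2 + rho * z + sqrt(1 - rho^2) * rnorm(n),
        hf_power = rexp(n))
    })
  }
  split_alpha_diff <- function(seed, rho) {
    d <- gen_subject(seed, rho)
    sp <- median_split_matched(d[, c("trial_id", "condition")],
                               d[, c("trial_id", "raw_power", "hf_power")])
    keep <- dplyr::filter(sp, !trimmed) |>
      dplyr::left_join(d[, c("trial_id", "alpha")], by = "trial_id")
    mean(keep$alpha[keep$ssvep_group == "strong"]) -
      mean(keep$alpha[keep$ssvep_group == "weak"])
  }
  # coupled generator: strong-SSVEP group has higher alpha across subjects
  diffs <- vapply(1:20, split_alpha_diff, numeric(1), rho = 0.6)
  expect_lt(t.test(diffs)$p.value, 0.05)
  expect_gt(mean(diffs), 0)
  # no coupling: difference centred on zero
  diffs0 <- vapply(1:20, split_alpha_diff, numeric(1), rho = 0)
  expect_gt(t.test(diffs0)$p.value, 0.05)

  # tie rule: odd trial count puts the median trial in the weak group
  odd <- tibble::tibble(trial_id = 1:13, condition = "still")
  podd <- tibble::tibble(trial_id = 1:13, raw_power = 1:13, hf_power = 1)
  sp_odd <- median_split_matched(odd, podd,
                                 walking_conditions = character(0))
  expect_equal(sum(sp_odd$ssvep_group == "weak"), 7)
  expect_equal(sp_odd$ssvep_group[7], "weak")

  # HF trimming removes 5 + 5 trials in walking conditions
  d <- gen_subject(99, 0.5)
  sp <- median_split_matched(d[, c("trial_id", "condition")],
                             d[, c("trial_id", "raw_power", "hf_power")])
  trim_by_cond <- tapply(sp$trimmed, sp$condition, sum)
  expect_equal(as.integer(trim_by_cond[c("slow", "normal")]), c(10L, 10L))
  expect_equal(as.integer(trim_by_cond["still"]), 0L)

  expect_error(median_split_matched(odd[1:5, ], podd[1:5, ]), "at least 12")
})

test_that("count-matched averaging removes count confounds", {
  expect_equal(count_matched_average(c(2, 2, 2), c(4, 5, 6)), 5)  # plain mean
  expect_equal(count_matched_average(c(0, 0, 0, 1), c(1, 1, 1, 3)), 2)

  # measure depends only on the count: matched means are equal across
  # conditions with different count distributions
  f <- function(k) 10 - 2 * k
  counts_a <- c(0, 0, 0, 1, 1, 2)
  counts_b <- c(0, 1, 2, 2, 2, 2)
  expect_equal(count_matched_average(counts_a, f(counts_a)),
               count_matched_average(counts_b, f(counts_b)))
})

test_that("two-level regression recovers slope signs and skips degenerate fits", {
  gen_trials <- function(p, beta_alpha = 0.5, beta_blink = -0.2) {
    n <- 60
    set.seed(p * 7 + 1)
    tibble::tibble(
      participant = p,
      block = rep(1:3, each = n / 3),
      alpha = rnorm(n, mean = rep(c(0, 1, 2), each = n / 3)),
      n_blinks = rpois(n, 1),
      n_saccades = rpois(n, 2)) |>
      dplyr::mutate(ssvep = beta_alpha * alpha + beta_blink * n_blinks +
                      rnorm(n, sd = 0.8))
  }
  trials <- purrr::map_dfr(1:25, gen_trials)
  res <- two_level_regression(trials)
  g <- res$group
  expect_lt(g$p.value[g$predictor == "alpha"], 0.05)
  expect_gt(g$mean_slope[g$predictor == "alpha"], 0)
  expect_lt(g$p.value[g$predictor == "n_blinks"], 0.05)
  expect_lt(g$mean_slope[g$predictor == "n_blinks"], 0)
  expect_gt(g$p.value[g$predictor == "n_saccades"], 0.2)

  # constant alpha within a participant: that participant is skipped
  degen <- gen_trials(99)
  degen$alpha <- 1
  expect_warning(res2 <- two_level_regression(dplyr::bind_rows(
    gen_trials(1), gen_trials(2), gen_trials(3), degen)), "skipped")
  expect_false(99 %in% res2$slopes$participant)
})

test_that("null two-level regression keeps its type-I error near 5%", {
  set.seed(38)
  rejections <- replicate(120, {
    trials <- purrr::map_dfr(1:12, function(p) tibble::tibble(
      participant = p, block = rep(1:2, each = 15),
      alpha = rnorm(30), n_blinks = rpois(30, 1), n_saccades = rpois(30, 2),
      ssvep = rnorm(30)))
    g <- two_level_regression(trials)$group
    g$p.value[g$predictor == "alpha"] < 0.05
  })
  expect_equal(mean(rejections), 0.05, tolerance = 0.05)
})
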