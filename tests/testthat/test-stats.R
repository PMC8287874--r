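make_threshold_table <- function(n = 8, seed = 1, effect = c(0.08, 0, 0)) {
  withr::with_seed(seed, {
    tb <- tidyr::expand_grid(subject = sprintf("s%02d", 1:n),
                             condition = c("upright", "inverted", "random"))
    shift <- effect[match(tb$condition, c("upright", "inverted", "random"))]
    tb$threshold <- rnorm(nrow(tb), 0.45, 0.05) +
      rep(rnorm(n, 0, 0.03), each = 3) + shift
    tb
  })
}

test_that("one-way RM-ANOVA matches the brute-force SS oracle and aov", {
  tb <- make_threshold_table(n = 6, seed = 2)
  res <- rm_anova_oneway(tb)
  oracle <- brute_force_rm_anova(tb$threshold, tb$subject, tb$condition)
  expect_equal(res$F, oracle$F, tolerance = 1e-12)
  expect_equal(res$df_num, oracle$df1)
  expect_equal(res$df_den, oracle$df2)
  expect_equal(res$p, oracle$p, tolerance = 1e-12)
  expect_equal(res$partial_eta_sq, oracle$pes, tolerance = 1e-12)
  # cross-check against the aov Error-strata route
  fit <- stats::aov(threshold ~ condition + Error(factor(subject) / condition),
                    data = tb)
  tab <- summary(fit)[["Error: factor(subject):condition"]][[1]]
  expect_equal(res$F, tab["condition", "F value"], tolerance = 1e-10)
  expect_equal(res$p, tab["condition", "Pr(>F)"], tolerance = 1e-10)
})

test_that("the SS decomposition is exact and location-invariant", {
  tb <- make_threshold_table(n = 10, seed = 3)
  res <- rm_anova_oneway(tb)
  expect_equal(res$ss_total, res$ss_subject + res$ss_condition + res$ss_error,
               tolerance = 1e-12)
  tb2 <- dplyr::mutate(tb, threshold = threshold + 5)
  expect_equal(rm_anova_oneway(tb2)$F, res$F, tolerance = 1e-9)
  # identical condition means give F ~ 0
  tb3 <- tidyr::expand_grid(subject = 1:5, condition = c("a", "b", "c"))
  tb3$threshold <- rep(rnorm(5), each = 3)
  expect_lt(rm_anova_oneway(tb3)$F, 1e-10)
  # incomplete designs are rejected
  expect_error(rm_anova_oneway(tb[-1, ]), "complete")
})

test_that("with two conditions F equals t squared", {
  tb <- make_threshold_table(n = 9, seed = 4)
  tb2 <- tb[tb$condition != "random", ]
  f <- rm_anova_oneway(tb2)$F
  t_ <- posthoc_bonferroni(tb2, pair = c("inverted", "upright"),
                           n_comparisons = 1)$t
  expect_equal(f, t_^2, tolerance = 1e-9)
})

test_that("paired post hoc tests report Bonferroni p and Cohen's d = t/sqrt(n)", {
  tb <- make_threshold_table(n = 12, seed = 5)
  ph <- posthoc_bonferroni(tb)
  expect_equal(nrow(ph), 3L)
  expect_equal(ph$p_bonferroni, pmin(1, 3 * ph$p_raw))
  expect_equal(ph$cohens_d, ph$t / sqrt(12), tolerance = 1e-12)
  expect_equal(ph$df, rep(11, 3))
  # the printed-value identity: t = 3.00 with n = 30 gives d = 0.548
  expect_equal(3.00 / sqrt(30), 0.5477, tolerance = 1e-4)
  # 5-pair toy set against hand arithmetic
  a <- c(0.50, 0.61, 0.47, 0.55, 0.58)
  b <- c(0.42, 0.55, 0.44, 0.49, 0.50)
  toy <- tibble::tibble(subject = rep(1:5, 2),
                        condition = rep(c("x", "y"), each = 5),
                        threshold = c(a, b))
  d <- a - b
  t_hand <- mean(d) / (sd(d) / sqrt(5))
  ph2 <- posthoc_bonferroni(toy, pair = c("x", "y"), n_comparisons = 1)
  expect_equal(ph2$t, t_hand, tolerance = 1e-12)
  # identical vectors: t = 0, d = 0
  same <- tibble::tibble(subject = rep(1:4, 2),
                         condition = rep(c("x", "y"), each = 4),
                         threshold = rep(c(1, 2, 3, 4), 2))
  ph3 <- posthoc_bonferroni(same, pair = c("x", "y"))
  expect_equal(ph3$t, 0)
  expect_equal(ph3$cohens_d, 0)
})

test_that("behavioral indices subtract the right conditions per subject", {
  tb <- tibble::tibble(
    subject = rep(c("s1", "s2"), each = 3),
    condition = rep(c("upright", "inverted", "random"), 2),
    threshold = c(0.7, 0.4, 0.6, 0.5, 0.3, 0.5)
  )
  idx <- behavioral_index(tb, "upright", "inverted")
  expect_equal(idx$index, c(0.3, 0.2))
  # non-upright-face variant averages the two non-upright conditions
  idx2 <- behavioral_index(tb, "upright", c("inverted", "random"))
  expect_equal(idx2$index, c(0.7 - 0.5, 0.5 - 0.4))
  # equal thresholds give a zero index
  tb0 <- dplyr::mutate(tb, threshold = 0.5)
  expect_equal(behavioral_index(tb0, "upright", "random")$index, c(0, 0))
  # row order of the input does not matter (alignment audit)
  shuffled <- tb[sample(nrow(tb)), ]
  expect_equal(behavioral_index(shuffled, "upright", "inverted"), idx)
  expect_error(behavioral_index(tb[-1, ], "upright", "inverted"), "per requested")
})

test_that("brain-behavior correlations match hand-computed Pearson r", {
  x <- c(0.1, 0.3, 0.2, 0.5, 0.4, 0.35, 0.15, 0.45, 0.25, 0.05)
  idx <- tibble::tibble(subject = 1:10, index = x)
  # exact linear relations
  acc1 <- tibble::tibble(subject = 1:10, accuracy = 2 * x + 1)
  expect_equal(correlate_brain_behavior(idx, acc1)$r, 1, tolerance = 1e-12)
  acc2 <- tibble::tibble(subject = 1:10, accuracy = -x)
  expect_equal(correlate_brain_behavior(idx, acc2)$r, -1, tolerance = 1e-12)
  # 10-point toy set against covariance/SD arithmetic
  withr::with_seed(6, y <- x + rnorm(10, 0, 0.1))
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  res <- correlate_brain_behavior(idx, tibble::tibble(subject = 1:10, accuracy = y))
  expect_equal(res$r, r_hand, tolerance = 1e-12)
  # p from the t transform with df = n - 2
  t_r <- r_hand * sqrt(8 / (1 - r_hand^2))
  expect_equal(res$p, 2 * pt(abs(t_r), 8, lower.tail = FALSE), tolerance = 1e-12)
  # affine invariance
  res2 <- correlate_brain_behavior(
    dplyr::mutate(idx, index = 3 * index - 1),
    tibble::tibble(subject = 1:10, accuracy = 0.5 * y + 2))
  expect_equal(res2$r, r_hand, tolerance = 1e-12)
  # Bonferroni over the ROI family
  multi <- dplyr::bind_rows(
    tibble::tibble(subject = 1:10, roi = "V3", accuracy = y),
    tibble::tibble(subject = 1:10, roi = "FFA", accuracy = rev(y))
  )
  resm <- correlate_brain_behavior(idx, multi, n_rois = 10)
  expect_equal(resm$p_bonferroni, pmin(1, resm$p * 10))
  # degenerate inputs error
  expect_error(correlate_brain_behavior(
    idx, tibble::tibble(subject = 1:10, accuracy = 0.5)), "variance")
})

test_that("the three-way RM-ANOVA layout reports every effect with its own error term", {
  withr::with_seed(7, {
    tb <- tidyr::expand_grid(subject = sprintf("s%02d", 1:6),
                             hemisphere = c("lh", "rh"),
                             condition = c("upright", "inverted", "random"),
                             roi = c("V1", "V3", "FFA"))
    tb$beta <- rnorm(nrow(tb), 0.1, 0.05) +
      ifelse(tb$hemisphere == "lh", 0.05, 0)
  })
  res <- rm_anova(tb, dv = "beta", within = c("hemisphere", "condition", "roi"))
  expect_setequal(
    res$term,
    c("hemisphere", "condition", "roi", "hemisphere:condition",
      "hemisphere:roi", "condition:roi", "hemisphere:condition:roi")
  )
  expect_true(all(res$partial_eta_sq >= 0 & res$partial_eta_sq <= 1))
  expect_equal(res$df_num[res$term == "hemisphere"], 1)
  expect_equal(res$df_den[res$term == "hemisphere"], 5)
  expect_equal(res$df_num[res$term == "condition:roi"], 4)
  # one-way fallback agrees with the dedicated path
  one <- make_threshold_table(n = 5, seed = 8)
  expect_equal(rm_anova(one)$F, rm_anova_oneway(one)$F)
})
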