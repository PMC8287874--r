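#' One-way repeated-measures ANOVA
#'
#' Partitions the total sum of squares of a complete within-subject design
#' into subject, condition, and subject-by-condition (error) components:
#' `F = MS_condition / MS_error` with `df = (k - 1, (n - 1)(k - 1))`, and
#' partial eta squared `SS_condition / (SS_condition + SS_error)`.
#' Sphericity is assumed (no Greenhouse-Geisser correction), matching the
#' uncorrected degrees of freedom convention of the reference analysis.
#'
#' @param table data frame with one row per subject x condition
#'   observation.
#' @param dv,within,subject column names of the dependent variable, the
#'   within-subject factor, and the subject identifier.
#' @return One-row tibble of class `anova_result`: `term`, `F`, `df_num`,
#'   `df_den`, `p`, `partial_eta_sq`, plus the SS decomposition
#'   (`ss_condition`, `ss_subject`, `ss_error`, `ss_total`).
#' @examples
#' tb <- tidyr::expand_grid(subject = 1:6, condition = c("a", "b", "c"))
#' tb$threshold <- rnorm(nrow(tb)) + (tb$condition == "a")
#' rm_anova_oneway(tb)
#' @export
rm_anova_oneway <- function(table, dv = "threshold", within = "condition",
                            subject = "subject") {
  y <- table[[dv]]
  cond <- factor(table[[within]])
  subj <- factor(table[[subject]])
  if (anyNA(y)) abort("missing values in the dependent variable.")
  k <- nlevels(cond); n <- nlevels(subj)
  if (k < 2L || n < 2L) abort("need at least 2 conditions and 2 subjects.")
  counts <- table(subj, cond)
  if (any(counts != 1L))
    abort("design must be complete: exactly one observation per subject x condition.")

  gm <- mean(y)
  cond_means <- tapply(y, cond, mean)
  subj_means <- tapply(y, subj, mean)
  ss_cond <- n * sum((cond_means - gm)^2)
  ss_subj <- k * sum((subj_means - gm)^2)
  ss_total <- sum((y - gm)^2)
  ss_err <- ss_total - ss_cond - ss_subj
  df_num <- k - 1L
  df_den <- (n - 1L) * (k - 1L)
  f <- (ss_cond / df_num) / (ss_err / df_den)
  out <- tibble(
    term = within, F = f, df_num = df_num, df_den = df_den,
    p = stats::pf(f, df_num, df_den, lower.tail = FALSE),
    partial_eta_sq = ss_cond / (ss_cond + ss_err),
    ss_condition = ss_cond, ss_subject = ss_subj,
    ss_error = ss_err, ss_total = ss_total
  )
  class(out) <- c("anova_result", class(out))
  out
}

#' Repeated-measures ANOVA with multiple within-subject factors
#'
#' Fits the fully-within design through [stats::aov()] with
#' `Error(subject/(f1 * f2 * ...))` strata and reports, for every effect,
#' the F ratio against its own subject-by-effect error stratum together
#' with partial eta squared. Used for the hemisphere x condition x ROI
#' layout; the one-way layout has a faster dedicated path in
#' [rm_anova_oneway()].
#'
#' @param table data frame, one row per subject x cell observation.
#' @param dv dependent-variable column name.
#' @param within character vector of within-subject factor column names.
#' @param subject subject identifier column name.
#' @return Tibble: `term`, `F`, `df_num`, `df_den`, `p`,
#'   `partial_eta_sq`.
#' @export
rm_anova <- function(table, dv = "threshold", within = "condition",
                     subject = "subject") {
  if (length(within) == 1L)
    return(dplyr::select(rm_anova_oneway(table, dv, within, subject),
                         "term":"partial_eta_sq"))
  df <- data.frame(
    .y = table[[dv]],
    .subject = factor(table[[subject]]),
    lapply(stats::setNames(within, within), function(w) factor(table[[w]]))
  )
  rhs <- paste(within, collapse = " * ")
  fml <- stats::as.formula(
    sprintf(".y ~ %s + Error(.subject/(%s))", rhs, rhs))
  fit <- stats::aov(fml, data = df)
  strata <- summary(fit)
  purrr::map(strata, function(s) {
    tab <- s[[1]]
    terms <- trimws(rownames(tab))
    eff <- terms != "Residuals"
    if (!any(eff)) return(NULL)
    resid_row <- which(terms == "Residuals")
    purrr::map(which(eff), function(i) tibble(
      term = terms[i],
      F = tab[i, "F value"],
      df_num = tab[i, "Df"],
      df_den = tab[resid_row, "Df"],
      p = tab[i, "Pr(>F)"],
      partial_eta_sq = tab[i, "Sum Sq"] /
        (tab[i, "Sum Sq"] + tab[resid_row, "Sum Sq"])
    )) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
}

#' Bonferroni-corrected paired t tests between conditions
#'
#' Paired t test on the within-subject differences for one condition pair
#' (or, by default, all three pairwise comparisons of the design), with
#' Bonferroni correction over `n_comparisons` tests and Cohen's d for
#' paired data (`d = mean difference / SD of differences`, equivalently
#' `t / sqrt(n)`).
#'
#' @param table data frame with subject, condition, and threshold columns.
#' @param pair length-2 character vector of condition levels to compare;
#'   `NULL` compares all pairs.
#' @param dv,within,subject column names.
#' @param n_comparisons Bonferroni family size (3 for the three pairwise
#'   tests).
#' @return Tibble: `pair`, `t`, `df`, `p_raw`, `p_bonferroni` (capped at
#'   1), `cohens_d`, `mean_difference`.
#' @export
posthoc_bonferroni <- function(table, pair = NULL, dv = "threshold",
                               within = "condition", subject = "subject",
                               n_comparisons = 3) {
  cond <- factor(table[[within]])
  pairs <- if (is.null(pair)) utils::combn(levels(cond), 2, simplify = FALSE)
           else list(pair)
  purrr::map(pairs, function(pr) {
    wide <- table[table[[within]] %in% pr, c(subject, within, dv)]
    wide <- tidyr::pivot_wider(wide, names_from = dplyr::all_of(within),
                               values_from = dplyr::all_of(dv))
    a <- wide[[pr[1]]]; b <- wide[[pr[2]]]
    if (length(a) < 2L) abort("need at least 2 paired observations.")
    n <- length(a)
    if (stats::sd(a - b) == 0) {
      # degenerate: all within-subject differences identical
      d0 <- mean(a - b)
      return(tibble(
        pair = paste(pr, collapse = " - "),
        t = if (d0 == 0) 0 else sign(d0) * Inf,
        df = n - 1,
        p_raw = if (d0 == 0) 1 else 0,
        p_bonferroni = if (d0 == 0) 1 else 0,
        cohens_d = if (d0 == 0) 0 else sign(d0) * Inf,
        mean_difference = d0
      ))
    }
    tt <- stats::t.test(a, b, paired = TRUE)
    tibble(
      pair = paste(pr, collapse = " - "),
      t = unname(tt$statistic),
      df = unname(tt$parameter),
      p_raw = tt$p.value,
      p_bonferroni = min(1, n_comparisons * tt$p.value),
      cohens_d = unname(tt$statistic) / sqrt(n),
      mean_difference = unname(tt$estimate)
    )
  }) |> purrr::list_rbind()
}

#' Per-subject behavioral index
#'
#' The difference in behavioral thresholds between two stimulus conditions,
#' per subject: `threshold_a - threshold_b`. For the non-upright-face
#' variant, `condition_b` names both non-upright conditions and the index
#' subtracts their per-subject mean.
#'
#' @param table data frame with subject, condition, threshold columns.
#' @param condition_a single condition name.
#' @param condition_b one condition name, or several to be averaged (e.g.
#'   `c("inverted", "random")`).
#' @param dv,within,subject column names.
#' @return Tibble: `subject`, `index`, ordered by subject.
#' @export
behavioral_index <- function(table, condition_a, condition_b,
                             dv = "threshold", within = "condition",
                             subject = "subject") {
  need <- c(condition_a, condition_b)
  tab <- table[table[[within]] %in% need, c(subject, within, dv)]
  names(tab) <- c("subject", "condition", "threshold")
  counts <- dplyr::count(tab, .data$subject)
  if (any(counts$n != length(need)))
    abort("every subject must have one threshold per requested condition.")
  tab |>
    dplyr::group_by(.data$subject) |>
    dplyr::summarise(
      index = mean(.data$threshold[.data$condition %in% condition_a]) -
        mean(.data$threshold[.data$condition %in% condition_b]),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$subject)
}

#' Pearson correlation between a behavioral index and decoding accuracy
#'
#' Aligns the two per-subject vectors by subject id and reports Pearson's r
#' with a two-sided p value from the t transform (`df = n - 2`), plus a
#' Bonferroni-adjusted p over the ROI family.
#'
#' @param index tibble from [behavioral_index()] (`subject`, `index`).
#' @param accuracy tibble with `subject` and `accuracy` columns (one ROI),
#'   or `subject`, `roi`, `accuracy` for several ROIs.
#' @param n_rois Bonferroni family size; defaults to the number of ROIs
#'   present.
#' @return Tibble of class `brain_behavior_result`: `roi`, `n`, `r`, `p`,
#'   `p_bonferroni`.
#' @export
correlate_brain_behavior <- function(index, accuracy, n_rois = NULL) {
  if (!"roi" %in% names(accuracy)) accuracy$roi <- "roi"
  n_rois <- n_rois %||% dplyr::n_distinct(accuracy$roi)
  out <- accuracy |>
    dplyr::inner_join(index, by = "subject") |>
    dplyr::group_by(.data$roi) |>
    dplyr::group_modify(function(d, key) {
      if (nrow(d) < 3L) abort("need at least 3 subjects per ROI.")
      if (stats::sd(d$index) == 0 || stats::sd(d$accuracy) == 0)
        abort("zero variance in index or accuracy.")
      ct <- stats::cor.test(d$index, d$accuracy, method = "pearson")
      tibble(n = nrow(d), r = unname(ct$estimate), p = ct$p.value)
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(p_bonferroni = pmin(1, .data$p * n_rois))
  class(out) <- c("brain_behavior_result", class(out))
  out
}
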