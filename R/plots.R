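#' @import ggplot2
NULL

#' Plot a depth map
#'
#' @param x a [depth_map()].
#' @param ... unused.
#' @return A ggplot raster of depth, masked-out cells blank.
#' @export
autoplot.depth_map <- function(x, ...) {
  d <- tidy(x)
  d$depth[!d$in_target] <- NA_real_
  ggplot(d, aes(x = .data$col, y = -.data$row, fill = .data$depth)) +
    geom_raster() +
    scale_fill_gradient2(low = "black", mid = "grey50", high = "white",
                         na.value = "grey20") +
    coord_equal() +
    labs(x = NULL, y = NULL, fill = "depth") +
    theme_void()
}

#' Plot a rendered stereogram as a red/cyan anaglyph dot field
#'
#' @param x a `stereo_pair` from [render_rds()].
#' @param ... unused.
#' @return A ggplot of left-eye (red) and right-eye (cyan) dot positions.
#' @export
autoplot.stereo_pair <- function(x, ...) {
  half <- x$dots$disparity_arcmin / 60 / 2
  s <- x$meta$spec$stim_size_deg
  d <- dplyr::bind_rows(
    dplyr::mutate(x$dots, eye = "left", x_eye = wrap_x(.data$x_deg + half, s)),
    dplyr::mutate(x$dots, eye = "right", x_eye = wrap_x(.data$x_deg - half, s))
  )
  ggplot(d, aes(x = .data$x_eye, y = .data$y_deg, colour = .data$eye)) +
    geom_point(size = 0.4, alpha = 0.7) +
    scale_colour_manual(values = c(left = "red", right = "cyan3")) +
    coord_equal() +
    labs(x = "x (deg)", y = "y (deg)", colour = NULL) +
    theme_minimal()
}

#' Plot a staircase trajectory
#'
#' Test intensity across trials, colored by outcome, with the final
#' threshold estimate as a horizontal line.
#'
#' @param x a `staircase_run` from [run_staircase()].
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.staircase_run <- function(x, ...) {
  ggplot(x$history, aes(x = .data$trial, y = .data$intensity)) +
    geom_line(colour = "grey60") +
    geom_point(aes(colour = .data$outcome, shape = .data$phase)) +
    geom_hline(yintercept = x$estimate$value, linetype = "dashed") +
    labs(x = "trial", y = "intensity", colour = NULL, shape = NULL) +
    theme_minimal()
}

#' Plot a recursive-elimination decoding trace
#'
#' Held-out accuracy as the surviving pattern shrinks, one line per fold.
#'
#' @param x an `rfe_result` from [rfe_decode()].
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.rfe_result <- function(x, ...) {
  ggplot(tidy(x), aes(x = .data$voxel_count, y = .data$accuracy,
                      group = .data$fold, colour = factor(.data$fold))) +
    geom_line(alpha = 0.8) +
    geom_hline(yintercept = 0.5, linetype = "dotted") +
    scale_x_reverse() +
    labs(x = "surviving voxels", y = "held-out accuracy", colour = "fold") +
    theme_minimal()
}

#' Plot a searchlight accuracy map
#'
#' Accuracy per center voxel, one panel per axial slice.
#'
#' @param x a `searchlight_map` from [searchlight()].
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.searchlight_map <- function(x, ...) {
  ggplot(x, aes(x = .data$x, y = .data$y, fill = .data$accuracy)) +
    geom_tile() +
    facet_wrap(~ z, labeller = label_both) +
    scale_fill_viridis_c(limits = c(0, 1)) +
    coord_equal() +
    labs(x = "x (mm)", y = "y (mm)", fill = "accuracy") +
    theme_minimal()
}

#' Plot per-condition behavioral thresholds
#'
#' Condition means with +/- 1 SEM error bars and individual-subject
#' points.
#'
#' @param thresholds tibble with `subject`, `condition`, `threshold`.
#' @return A ggplot.
#' @export
plot_thresholds <- function(thresholds) {
  summ <- thresholds |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(mean = mean(.data$threshold),
                     sem = stats::sd(.data$threshold) / sqrt(dplyr::n()),
                     .groups = "drop")
  ggplot(summ, aes(x = .data$condition, y = .data$mean)) +
    geom_col(fill = "grey80", colour = "grey30", width = 0.6) +
    geom_errorbar(aes(ymin = .data$mean - .data$sem,
                      ymax = .data$mean + .data$sem), width = 0.15) +
    geom_jitter(data = thresholds,
                aes(x = .data$condition, y = .data$threshold),
                width = 0.08, alpha = 0.5, size = 1) +
    labs(x = NULL, y = "threshold") +
    theme_minimal()
}
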