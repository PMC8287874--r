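#' Stimulus specification for random-dot stereograms
#'
#' Geometry and dot parameters for one disparity-defined random-dot
#' stereogram (RDS). Defaults follow the psychophysics display: an
#' 8.68 x 8.68 deg stimulus containing a 6.45 deg (vertical) x 4.55 deg
#' (horizontal) oval target, dots of 0.05 deg at 20 dots/deg^2, and a
#' maximum target disparity of 5.3 arcmin (5.4 arcmin for the in-bore
#' variant of the task).
#'
#' @param stim_size_deg stimulus width/height (deg).
#' @param target_size_deg length-2 numeric, vertical x horizontal target
#'   extent (deg).
#' @param max_disparity_arcmin maximum absolute disparity on the target
#'   surface (arcmin).
#' @param dot_density_per_deg2 dots per square degree.
#' @param dot_size_deg dot diameter (deg).
#' @param snr fraction of target dots carrying the surface disparity
#'   (signal) as opposed to a random disparity (noise); in `[0, 1]`.
#' @param depth_sign `"near"` (crossed disparity) or `"far"` (uncrossed).
#' @param background_grid_square_deg size of the decorative background
#'   reference-grid squares (deg); cosmetic only.
#' @return A list of class `stimulus_spec`.
#' @export
stimulus_spec <- function(stim_size_deg = 8.68,
                          target_size_deg = c(6.45, 4.55),
                          max_disparity_arcmin = 5.3,
                          dot_density_per_deg2 = 20,
                          dot_size_deg = 0.05,
                          snr = 1,
                          depth_sign = c("near", "far"),
                          background_grid_square_deg = 0.5) {
  depth_sign <- match.arg(depth_sign)
  assert_scalar_prob(snr, "snr")
  vals <- c(stim_size_deg, target_size_deg, max_disparity_arcmin,
            dot_density_per_deg2, dot_size_deg, background_grid_square_deg)
  if (!all(is.finite(vals)) || any(vals <= 0))
    abort("all geometry parameters must be positive and finite.")
  if (length(target_size_deg) != 2L)
    abort("`target_size_deg` must be c(vertical, horizontal).")
  if (any(target_size_deg > stim_size_deg))
    abort("target must fit inside the stimulus.")
  structure(
    list(
      stim_size_deg = stim_size_deg,
      target_size_deg = target_size_deg,
      max_disparity_arcmin = max_disparity_arcmin,
      dot_density_per_deg2 = dot_density_per_deg2,
      dot_size_deg = dot_size_deg,
      snr = snr,
      depth_sign = depth_sign,
      background_grid_square_deg = background_grid_square_deg
    ),
    class = "stimulus_spec"
  )
}

# Nearest-neighbour lookup of scaled disparity (arcmin) at dot positions.
# Grid rows run top (+y) to bottom; columns left (-x) to right, covering the
# target rectangle.
sample_depth_at <- function(depth, x, y, spec) {
  half_v <- spec$target_size_deg[1] / 2
  half_h <- spec$target_size_deg[2] / 2
  nr <- nrow(depth$values); nc <- ncol(depth$values)
  r <- pmin(pmax(ceiling((half_v - y) / (2 * half_v) * nr), 1L), nr)
  c <- pmin(pmax(ceiling((x + half_h) / (2 * half_h) * nc), 1L), nc)
  peak <- max(abs(depth$values[depth$mask]))
  if (peak == 0) abort("depth map is blank: max |depth| must be > 0 to render.")
  scale <- spec$max_disparity_arcmin / peak
  depth$values[cbind(r, c)] * scale
}

#' Render a depth map as a random-dot stereogram
#'
#' Places dots uniformly at the specified density over the stimulus square,
#' then assigns disparities: within the oval target region, an exact count
#' of `floor(snr * n_target)` dots (chosen without replacement) are signal
#' dots carrying the depth map's local disparity — the map is scaled
#' linearly so its absolute maximum maps to `spec$max_disparity_arcmin` —
#' while the remaining target dots are noise dots with disparities drawn
#' uniformly from that same +/- range. Surround dots sit at zero disparity
#' (the fixation plane). `depth_sign = "near"` renders the surface in
#' crossed disparity (positive here), `"far"` uncrossed.
#'
#' Disparity is applied as a symmetric +/- d/2 horizontal shift of each
#' eye's dot about the cyclopean position; dots shifted past the stimulus
#' edge wrap horizontally.
#'
#' @param depth a [depth_map()] describing the target surface.
#' @param spec a [stimulus_spec()].
#' @param seed integer seed controlling dot placement, polarity, and noise
#'   disparities.
#' @param pixels_per_degree rasterization density of the left/right images.
#' @return A `stereo_pair`: list with `dots` (tibble: `x_deg`, `y_deg`,
#'   `disparity_arcmin`, `polarity`, `role`), `left_image`, `right_image`
#'   (matrices in `[0, 1]`), and `meta` (spec + seed).
#' @examples
#' dm <- depth_map(matrix(rnorm(64), 8, 8))
#' pair <- render_rds(dm, stimulus_spec(snr = 0.5), seed = 1)
#' table(pair$dots$role)
#' @export
render_rds <- function(depth, spec = stimulus_spec(), seed = NULL,
                       pixels_per_degree = 40) {
  stopifnot(is_depth_map(depth), inherits(spec, "stimulus_spec"))
  local_seed(seed, {
    s <- spec$stim_size_deg
    n_dots <- round(spec$dot_density_per_deg2 * s^2)
    x <- stats::runif(n_dots, -s / 2, s / 2)
    y <- stats::runif(n_dots, -s / 2, s / 2)
    polarity <- sample(c("black", "white"), n_dots, replace = TRUE)

    half_v <- spec$target_size_deg[1] / 2
    half_h <- spec$target_size_deg[2] / 2
    in_target <- (x / half_h)^2 + (y / half_v)^2 <= 1

    disparity <- numeric(n_dots)
    role <- rep("surround", n_dots)
    idx_target <- which(in_target)
    n_target <- length(idx_target)
    if (n_target > 0) {
      n_signal <- floor(spec$snr * n_target)
      idx_signal <- if (n_signal > 0) sample(idx_target, n_signal) else integer(0)
      idx_noise <- setdiff(idx_target, idx_signal)
      sgn <- if (spec$depth_sign == "near") 1 else -1
      if (length(idx_signal)) {
        disparity[idx_signal] <-
          sgn * sample_depth_at(depth, x[idx_signal], y[idx_signal], spec)
        role[idx_signal] <- "signal"
      }
      if (length(idx_noise)) {
        disparity[idx_noise] <- stats::runif(
          length(idx_noise), -spec$max_disparity_arcmin, spec$max_disparity_arcmin
        )
        role[idx_noise] <- "noise"
      }
    }

    dots <- tibble(
      x_deg = x, y_deg = y, disparity_arcmin = disparity,
      polarity = polarity, role = role
    )
    new_stereo_pair(dots, spec, seed, pixels_per_degree)
  })
}

# Wrap x coordinates into [-s/2, s/2).
wrap_x <- function(x, s) ((x + s / 2) %% s) - s / 2

new_stereo_pair <- function(dots, spec, seed, pixels_per_degree) {
  s <- spec$stim_size_deg
  half_shift <- dots$disparity_arcmin / 60 / 2
  left <- rasterize_dots(wrap_x(dots$x_deg + half_shift, s), dots$y_deg,
                         dots$polarity, spec, pixels_per_degree)
  right <- rasterize_dots(wrap_x(dots$x_deg - half_shift, s), dots$y_deg,
                          dots$polarity, spec, pixels_per_degree)
  structure(
    list(dots = dots, left_image = left, right_image = right,
         meta = list(spec = spec, seed = seed,
                     pixels_per_degree = pixels_per_degree)),
    class = "stereo_pair"
  )
}

# Paint square dots on a mid-gray canvas. Rows top-to-bottom, columns
# left-to-right; black dots 0, white dots 1, background 0.5.
rasterize_dots <- function(x, y, polarity, spec, ppd) {
  s <- spec$stim_size_deg
  n_px <- max(1L, round(s * ppd))
  img <- matrix(0.5, n_px, n_px)
  half_dot_px <- max(0L, floor(spec$dot_size_deg * ppd / 2))
  cx <- pmin(pmax(ceiling((x + s / 2) / s * n_px), 1L), n_px)
  cy <- pmin(pmax(ceiling((s / 2 - y) / s * n_px), 1L), n_px)
  val <- ifelse(polarity == "white", 1, 0)
  for (k in seq_along(cx)) {
    rr <- max(1L, cy[k] - half_dot_px):min(n_px, cy[k] + half_dot_px)
    cc <- max(1L, cx[k] - half_dot_px):min(n_px, cx[k] + half_dot_px)
    img[rr, cc] <- val[k]
  }
  img
}

#' @export
print.stereo_pair <- function(x, ...) {
  cat(sprintf(
    "<stereo_pair> %d dots (%s), snr = %.2f, max |disparity| = %.2f arcmin\n",
    nrow(x$dots),
    paste(names(table(x$dots$role)), table(x$dots$role),
          sep = "=", collapse = ", "),
    x$meta$spec$snr, max(abs(x$dots$disparity_arcmin))
  ))
  invisible(x)
}

#' @export
tidy.stereo_pair <- function(x, ...) x$dots

#' Render a clear two-interval depth-discrimination pair
#'
#' Builds the two stimuli of one fine ("feature") discrimination trial:
#' a reference surface whose disparity peak is fixed (7.8 arcmin, crossed)
#' and a target surface whose peak is offset from the reference by a small
#' amount expressed in arcseconds (at most 150 arcsec). Both stimuli are
#' rendered noise-free (snr = 1).
#'
#' @param depth a [depth_map()].
#' @param spec a [stimulus_spec()]; its `snr` and `max_disparity_arcmin`
#'   are overridden (snr = 1; peaks set by `reference_disparity_arcmin`
#'   and the offset).
#' @param reference_disparity_arcmin peak disparity of the reference
#'   surface (arcmin, crossed).
#' @param target_offset_arcsec disparity offset of the target peak relative
#'   to the reference, in arcseconds; `|offset| <= 150`.
#' @param seed integer seed (shared placement randomness; the two stimuli
#'   use derived seeds).
#' @param pixels_per_degree rasterization density.
#' @return A list with elements `reference` and `target`, each a
#'   `stereo_pair`.
#' @export
render_feature_pair <- function(depth, spec = stimulus_spec(),
                                reference_disparity_arcmin = 7.8,
                                target_offset_arcsec = 120,
                                seed = NULL, pixels_per_degree = 40) {
  if (!is.numeric(target_offset_arcsec) || abs(target_offset_arcsec) > 150)
    abort("`target_offset_arcsec` must lie within +/-150 arcsec.")
  # the clear-discrimination surfaces are entirely crossed: maps containing
  # negative depths are shifted onto a nonnegative pedestal so the peak maps
  # to the reference disparity and no point falls behind fixation
  vmin <- min(depth$values[depth$mask])
  if (vmin < 0) {
    depth <- depth_map((depth$values - vmin) * depth$mask, depth$mask,
                       depth$pixels_per_degree)
  }
  ref_spec <- spec
  ref_spec$snr <- 1
  ref_spec$depth_sign <- "near"
  ref_spec$max_disparity_arcmin <- reference_disparity_arcmin
  tgt_spec <- ref_spec
  tgt_spec$max_disparity_arcmin <-
    reference_disparity_arcmin + target_offset_arcsec / 60
  list(
    reference = render_rds(depth, ref_spec,
                           seed = if (is.null(seed)) NULL else derive_seed(seed, "ref"),
                           pixels_per_degree = pixels_per_degree),
    target = render_rds(depth, tgt_spec,
                        seed = if (is.null(seed)) NULL else derive_seed(seed, "tgt"),
                        pixels_per_degree = pixels_per_degree)
  )
}

#' Write a rendered stereogram to disk
#'
#' Writes a side-by-side grayscale PNG (left | right), a red/cyan anaglyph
#' PNG (left eye in the red channel, right eye in green/blue), and the dot
#' list as CSV (`x_deg`, `y_deg`, `disparity_arcmin`, `polarity`, `role`).
#'
#' @param pair a `stereo_pair` from [render_rds()].
#' @param path_prefix output path prefix; files are written as
#'   `<prefix>_sbs.png`, `<prefix>_anaglyph.png`, `<prefix>_dots.csv`.
#' @return Invisibly, a named character vector of the written paths.
#' @export
export_stimulus <- function(pair, path_prefix) {
  stopifnot(inherits(pair, "stereo_pair"))
  dir <- dirname(path_prefix)
  if (!dir.exists(dir)) abort(sprintf("directory does not exist: %s", dir))
  sbs <- cbind(pair$left_image, pair$right_image)
  ana <- array(0, c(nrow(pair$left_image), ncol(pair$left_image), 3))
  ana[, , 1] <- pair$left_image
  ana[, , 2] <- pair$right_image
  ana[, , 3] <- pair$right_image
  paths <- c(
    side_by_side = paste0(path_prefix, "_sbs.png"),
    anaglyph = paste0(path_prefix, "_anaglyph.png"),
    dots = paste0(path_prefix, "_dots.csv")
  )
  png::writePNG(sbs, paths[["side_by_side"]])
  png::writePNG(ana, paths[["anaglyph"]])
  utils::write.csv(pair$dots, paths[["dots"]], row.names = FALSE)
  invisible(paths)
}

#' Synthesize one of the three stimulus classes
#'
#' Convenience wrapper mapping a base (upright) depth map to one of the
#' three experimental classes: `"upright"` leaves the map as is,
#' `"inverted"` rotates it 180 degrees in the picture plane, and
#' `"random"` replaces it with a depth-power-matched phase-scrambled
#' surface.
#'
#' @param depth base upright [depth_map()].
#' @param class one of `"upright"`, `"inverted"`, `"random"`.
#' @param seed integer seed (used by the `"random"` class).
#' @return A [depth_map()].
#' @export
make_stimulus_class <- function(depth, class = c("upright", "inverted", "random"),
                                seed = NULL) {
  class <- match.arg(class)
  switch(class,
    upright = depth,
    inverted = invert_depth_map(depth),
    random = phase_randomize(depth, seed = seed)
  )
}
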