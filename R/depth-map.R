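#' Depth maps
#'
#' A `depth_map` is a rectangular grid of relative depth values together with
#' a logical oval mask marking the target region, and a sampling density in
#' pixels per degree of visual angle. Depth values are unitless; at render
#' time the map's global absolute maximum is scaled linearly to the stimulus
#' maximum disparity.
#'
#' @param values numeric matrix of relative depth values (finite).
#' @param mask logical matrix, same dimensions as `values`; `TRUE` marks the
#'   oval target region. Defaults to an oval inscribed in the grid.
#' @param pixels_per_degree sampling density of the grid (px/deg).
#' @return An object of class `depth_map` with elements `values`, `mask`,
#'   and `pixels_per_degree`.
#' @examples
#' dm <- depth_map(matrix(rnorm(64), 8, 8))
#' dim(dm$values)
#' @export
depth_map <- function(values, mask = NULL, pixels_per_degree = 10) {
  if (!is.matrix(values) || !is.numeric(values))
    abort("`values` must be a numeric matrix.")
  if (!all(is.finite(values)))
    abort("`values` must be finite.")
  if (is.null(mask)) mask <- oval_mask(nrow(values), ncol(values))
  if (!is.logical(mask) || !identical(dim(mask), dim(values)))
    abort("`mask` must be a logical matrix with the same dimensions as `values`.")
  if (!any(mask))
    abort("`mask` must select at least one cell.")
  structure(
    list(values = values, mask = mask, pixels_per_degree = pixels_per_degree),
    class = "depth_map"
  )
}

#' @export
print.depth_map <- function(x, ...) {
  cat(sprintf(
    "<depth_map> %d x %d grid, %d masked-in cells, max |depth| = %.3g\n",
    nrow(x$values), ncol(x$values), sum(x$mask), max(abs(x$values))
  ))
  invisible(x)
}

#' @rdname depth_map
#' @param x object to test or tidy.
#' @export
is_depth_map <- function(x) inherits(x, "depth_map")

#' Turn a depth map upside down
#'
#' Rotates both the depth values and the mask by 180 degrees in the picture
#' plane. This is the manipulation that converts an upright face into an
#' inverted face: depth content (histogram, amplitude) is untouched, only
#' its spatial arrangement changes.
#'
#' @param depth a [depth_map()].
#' @return A `depth_map` with rotated values and mask.
#' @examples
#' dm <- depth_map(matrix(1:9, 3, 3) * 1.0)
#' invert_depth_map(invert_depth_map(dm))$values == dm$values
#' @export
invert_depth_map <- function(depth) {
  stopifnot(is_depth_map(depth))
  rot180 <- function(m) m[rev(seq_len(nrow(m))), rev(seq_len(ncol(m))), drop = FALSE]
  depth_map(rot180(depth$values), rot180(depth$mask), depth$pixels_per_degree)
}

#' Phase-scramble a depth map
#'
#' Builds a depth-power-matched random surface: the map is Fourier
#' transformed, its phases are replaced by random phases, and its amplitude
#' spectrum is kept exactly. The random phase field is taken from the
#' Fourier transform of a real white-noise field, so it is
#' Hermitian-symmetric by construction (DC and Nyquist phases are 0 or pi)
#' and the inverse transform is exactly real.
#'
#' The oval mask is applied to the values before the transform; the returned
#' surface fills the full grid (used unmasked within the target region) and
#' carries the input's mask.
#'
#' @param depth a [depth_map()].
#' @param seed integer seed for the random phases.
#' @return A `depth_map` whose 2D amplitude spectrum equals the input's.
#' @examples
#' dm <- depth_map(matrix(rnorm(256), 16, 16))
#' pr <- phase_randomize(dm, seed = 1)
#' max(abs(Mod(stats::fft(pr$values)) - Mod(stats::fft(dm$values * dm$mask))))
#' @export
phase_randomize <- function(depth, seed = NULL) {
  stopifnot(is_depth_map(depth))
  v <- depth$values * depth$mask
  if (!all(is.finite(v))) abort("depth values must be finite.")
  amp <- Mod(stats::fft(v))
  noise <- local_seed(seed, matrix(stats::rnorm(length(v)), nrow(v), ncol(v)))
  ph <- Arg(stats::fft(noise))
  out <- Re(stats::fft(amp * exp(1i * ph), inverse = TRUE)) / length(v)
  depth_map(out, depth$mask, depth$pixels_per_degree)
}

#' Read a depth map from an image or text matrix
#'
#' Accepts an 8/16-bit grayscale PNG (intensity codes depth, rescaled to
#' [-1, 1]) or a whitespace-delimited text matrix of depth values.
#'
#' @param path file path (`.png` or text).
#' @param pixels_per_degree sampling density to record on the map.
#' @return A [depth_map()].
#' @export
read_depth_map <- function(path, pixels_per_degree = 10) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    vals <- img * 2 - 1
  } else {
    vals <- as.matrix(utils::read.table(path))
    dimnames(vals) <- NULL
  }
  depth_map(vals, pixels_per_degree = pixels_per_degree)
}

#' @describeIn depth_map tidy view: one row per grid cell with row/column
#'   indices (0-based), depth value and mask flag.
#' @param ... unused.
#' @export
tidy.depth_map <- function(x, ...) {
  nr <- nrow(x$values); nc <- ncol(x$values)
  tibble(
    row = rep(seq_len(nr) - 1L, times = nc),
    col = rep(seq_len(nc) - 1L, each = nr),
    depth = as.vector(x$values),
    in_target = as.vector(x$mask)
  )
}
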