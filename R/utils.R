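#' @importFrom rlang .data abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

# Evaluate `code` under a local RNG state seeded with `seed`; the caller's
# RNG stream is untouched. NULL seed runs against the ambient stream.
local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), code)
}

# Deterministic per-stage seed derivation from a single pipeline seed.
# Keeps results below .Machine$integer.max so seeds stay valid R integers.
derive_seed <- function(seed, stage, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 131 + index) %% 2147483647)
}

# Elliptical (oval) mask on an nr x nc grid, semi-axes as fractions of the
# grid half-extent.
oval_mask <- function(nr, nc, semi_y = 1, semi_x = 1) {
  y <- seq(-1, 1, length.out = nr)
  x <- seq(-1, 1, length.out = nc)
  outer(y, x, function(yy, xx) (yy / semi_y)^2 + (xx / semi_x)^2 <= 1)
}

assert_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 || x > 1)
    abort(sprintf("`%s` must be a single value in [0, 1].", name))
  invisible(x)
}
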