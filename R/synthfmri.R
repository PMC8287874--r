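#' Generate a smooth face-like depth surface
#'
#' Stand-in for a laser-scanned head model rendered as a depth map: a
#' low-pass random surface (white noise filtered with a broad Gaussian in
#' the frequency domain) plus a few localized protrusions/indentations
#' (Gaussian bumps emulating nose/brow/cheek relief), cropped by the oval
#' mask and normalized so the maximum absolute depth is 1.
#'
#' @param seed integer seed; distinct seeds give distinct surfaces.
#' @param grid_size grid side length in pixels (>= 64).
#' @param n_features number of localized bump features.
#' @param cutoff_frac low-pass cutoff as a fraction of the Nyquist
#'   frequency; power above it is suppressed.
#' @return A [depth_map()] with `max(abs(values)) == 1`.
#' @examples
#' dm <- make_face_like_depth_map(seed = 1)
#' max(abs(dm$values))
#' @export
make_face_like_depth_map <- function(seed = NULL, grid_size = 64,
                                     n_features = 4, cutoff_frac = 0.15) {
  if (grid_size < 64) abort("`grid_size` must be at least 64.")
  local_seed(seed, {
    n <- grid_size
    noise <- matrix(stats::rnorm(n * n), n, n)
    f <- stats::fft(noise)
    # radial frequency grid (cycles/sample), Gaussian low-pass
    fr <- c(seq(0, floor(n / 2)), seq(ceiling(n / 2) - 1, 1)) / n
    r2 <- outer(fr^2, fr^2, `+`)
    sigma_f <- cutoff_frac * 0.5 / 2   # cutoff_frac of Nyquist ~ 2 sigma
    smooth <- Re(stats::fft(f * exp(-r2 / (2 * sigma_f^2)), inverse = TRUE)) / (n * n)
    smooth <- smooth / stats::sd(smooth)

    xs <- seq(-1, 1, length.out = n)
    bumps <- matrix(0, n, n)
    for (k in seq_len(n_features)) {
      cx <- stats::runif(1, -0.45, 0.45)
      cy <- stats::runif(1, -0.45, 0.45)
      w <- stats::runif(1, 0.08, 0.2)
      a <- sample(c(-1, 1), 1) * stats::runif(1, 0.5, 1.5)
      bumps <- bumps + a * outer(xs, xs, function(y, x)
        exp(-((x - cx)^2 + (y - cy)^2) / (2 * w^2)))
    }
    vals <- smooth + bumps
    mask <- oval_mask(n, n, semi_y = 0.95, semi_x = 0.7)
    vals <- vals * mask
    vals <- vals / max(abs(vals))
    depth_map(vals, mask, pixels_per_degree = grid_size / 6.45)
  })
}

# The six stimulus block types: 3 conditions x 2 stimulus genders.
stimulus_block_types <- function() {
  as.vector(outer(c("upright", "inverted", "random"),
                  c("male", "female"), paste, sep = "_"))
}

#' Randomized block-design run schedule
#'
#' Builds one fMRI run: 12 stimulus blocks (each of the six stimulus types
#' — 3 conditions x 2 genders — exactly twice, in randomized order)
#' interleaved with 13 fixation blocks, beginning and ending with fixation.
#' Every block lasts 16 s; each stimulus block holds 8 trials (500 ms
#' stimulus + 1500 ms response) with 4 "near" and 4 "far" trials in random
#' order. TR is 2 s; 5 dummy volumes are assumed discarded before the
#' retained series starts.
#'
#' @param seed integer seed for block order and near/far order.
#' @param tr_s repetition time (s).
#' @param block_duration_s block length (s).
#' @return An object of class `run_design`: `blocks` (tibble: `block`,
#'   `type`, `condition`, `onset_s`, `duration_s`), `trials` (96-row
#'   tibble: `block`, `trial`, `trial_in_block`, `depth_position`,
#'   `stimulus_ms`, `response_ms`), `tr_s`, `dummy_volumes`, `n_volumes`.
#' @examples
#' d <- make_run_design(seed = 1)
#' nrow(d$trials)
#' @export
make_run_design <- function(seed = NULL, tr_s = 2, block_duration_s = 16) {
  local_seed(seed, {
    stim_order <- sample(rep(stimulus_block_types(), 2L))
    types <- character(25L)
    types[seq(1, 25, by = 2)] <- "fixation"
    types[seq(2, 24, by = 2)] <- stim_order
    blocks <- tibble(
      block = seq_along(types),
      type = types,
      condition = ifelse(types == "fixation", "fixation",
                         sub("_.*$", "", types)),
      onset_s = (seq_along(types) - 1) * block_duration_s,
      duration_s = block_duration_s
    )
    stim_blocks <- dplyr::filter(blocks, .data$type != "fixation")
    trials <- purrr::map(stim_blocks$block, function(b) tibble(
      block = b,
      trial_in_block = 1:8,
      depth_position = sample(rep(c("near", "far"), 4L)),
      stimulus_ms = 500, response_ms = 1500
    )) |> purrr::list_rbind()
    trials$trial <- seq_len(nrow(trials))
    structure(
      list(blocks = blocks, trials = trials, tr_s = tr_s,
           dummy_volumes = 5L,
           n_volumes = as.integer(sum(blocks$duration_s) / tr_s)),
      class = "run_design"
    )
  })
}

#' @export
print.run_design <- function(x, ...) {
  cat(sprintf(
    "<run_design> %d blocks (%d stimulus + %d fixation), %d trials, %d volumes @ TR %gs\n",
    nrow(x$blocks), sum(x$blocks$type != "fixation"),
    sum(x$blocks$type == "fixation"), nrow(x$trials), x$n_volumes, x$tr_s
  ))
  invisible(x)
}

#' @export
tidy.run_design <- function(x, ...) x$blocks

#' Ground-truth multivoxel activation model
#'
#' Defines, per stimulus condition, the mean activation amplitude of every
#' voxel (in percent signal change). A subset of voxels is informative:
#' their amplitudes differ between conditions by draws of SD `effect_size`;
#' all other voxels share a condition-independent amplitude. Voxel
#' coordinates are laid out on a 3D grid (2-mm pitch by default) for the
#' searchlight.
#'
#' @param n_voxels number of voxels in the synthetic ROI.
#' @param n_informative number of voxels whose amplitudes differ across
#'   conditions.
#' @param effect_size SD of the condition-specific amplitude offsets
#'   (percent signal change); 0 gives an uninformative ROI.
#' @param baseline_amplitude shared response amplitude of every voxel to
#'   any stimulus block.
#' @param conditions condition names (columns of the pattern matrix).
#' @param grid_dim 3D grid dimensions holding the voxels (must fit
#'   `n_voxels`).
#' @param voxel_size_mm grid pitch in mm.
#' @param seed integer seed.
#' @param mean_pattern optional explicit `n_voxels x length(conditions)`
#'   amplitude matrix overriding the generative defaults.
#' @return An object of class `voxel_pattern_model`: `mean_pattern`
#'   (voxels x conditions), `informative_set`, `voxel_coords`
#'   (voxels x 3, mm), `effect_size`.
#' @export
voxel_pattern_model <- function(n_voxels = 800, n_informative = 0,
                                effect_size = 0, baseline_amplitude = 1,
                                conditions = c("upright", "inverted", "random"),
                                grid_dim = c(10, 10, 10), voxel_size_mm = 2,
                                seed = NULL, mean_pattern = NULL) {
  if (n_voxels > prod(grid_dim)) {
    grid_dim <- rep(ceiling(n_voxels^(1 / 3)), 3L)
  }
  coords <- as.matrix(expand.grid(
    x = seq_len(grid_dim[1]), y = seq_len(grid_dim[2]), z = seq_len(grid_dim[3])
  ))[seq_len(n_voxels), , drop = FALSE] * voxel_size_mm
  local_seed(seed, {
    if (is.null(mean_pattern)) {
      base <- rep(baseline_amplitude, n_voxels)
      mean_pattern <- matrix(base, n_voxels, length(conditions),
                             dimnames = list(NULL, conditions))
      informative <- sort(sample(n_voxels, n_informative))
      if (n_informative > 0 && effect_size > 0) {
        mean_pattern[informative, ] <- mean_pattern[informative, ] +
          matrix(stats::rnorm(n_informative * length(conditions), 0, effect_size),
                 n_informative, length(conditions))
      }
    } else {
      stopifnot(nrow(mean_pattern) == n_voxels,
                ncol(mean_pattern) == length(conditions))
      colnames(mean_pattern) <- conditions
      informative <- which(apply(mean_pattern, 1, function(r) any(r != r[1])))
    }
    if (!all(is.finite(mean_pattern))) abort("pattern amplitudes must be finite.")
    structure(
      list(mean_pattern = mean_pattern, informative_set = informative,
           voxel_coords = coords, effect_size = effect_size,
           conditions = conditions, n_voxels = n_voxels),
      class = "voxel_pattern_model"
    )
  })
}

#' @export
print.voxel_pattern_model <- function(x, ...) {
  cat(sprintf(
    "<voxel_pattern_model> %d voxels (%d informative), effect size %.3g\n",
    x$n_voxels, length(x$informative_set), x$effect_size
  ))
  invisible(x)
}

# Marginal-variance-preserving AR(1) noise.
ar1_noise <- function(n, sigma, rho) {
  if (rho == 0) return(stats::rnorm(n, 0, sigma))
  e <- stats::rnorm(n, 0, sigma * sqrt(1 - rho^2))
  as.numeric(stats::filter(e, rho, method = "recursive"))
}

# Smooth random-walk motion nuisance series (3 translations, 3 rotations).
simulate_motion <- function(n_volumes, step_sd = 0.02) {
  m <- vapply(1:6, function(i) cumsum(stats::rnorm(n_volumes, 0, step_sd)),
              numeric(n_volumes))
  colnames(m) <- c("tx", "ty", "tz", "rx", "ry", "rz")
  m
}

#' Simulate multi-run block-design voxel time series
#'
#' For every voxel, the signal is the sum over conditions of the condition
#' boxcar convolved with a two-gamma hemodynamic response function, scaled
#' by that voxel's ground-truth amplitude, on top of a constant baseline,
#' an optional linear drift, and Gaussian noise (white, or AR(1) when
#' `ar1_rho > 0`). Motion nuisance series are generated as smooth random
#' walks. Per-volume ground-truth labels are retained.
#'
#' @param model a [voxel_pattern_model()].
#' @param n_runs number of runs (>= 2; leave-one-run-out needs at least 2).
#' @param design a single [make_run_design()] reused for every run, a list
#'   of designs (one per run), or `NULL` to generate a fresh randomized
#'   design per run.
#' @param noise list: `sigma` (noise SD, percent-signal-change units),
#'   `ar1_rho` (AR(1) coefficient), `drift` (linear drift amplitude over
#'   the run, percent).
#' @param baseline constant signal baseline.
#' @param hrf hemodynamic kernel parameters, a [hrf_params()].
#' @param seed integer seed.
#' @return An object of class `synthetic_dataset`: `runs` — list of lists
#'   with `signals` (volumes x voxels), `motion` (volumes x 6), `labels`
#'   (tibble: `volume`, `block`, `type`, `condition`) — plus `designs`,
#'   `model`, `noise`, `tr_s`, `seed`.
#' @examples
#' mod <- voxel_pattern_model(n_voxels = 20, seed = 1)
#' ds <- simulate_timeseries(mod, n_runs = 2, seed = 1)
#' dim(ds$runs[[1]]$signals)
#' @export
simulate_timeseries <- function(model, n_runs = 8, design = NULL,
                                noise = list(sigma = 1, ar1_rho = 0, drift = 0),
                                baseline = 100, hrf = hrf_params(),
                                seed = NULL) {
  stopifnot(inherits(model, "voxel_pattern_model"))
  if (n_runs < 2) abort("`n_runs` must be at least 2 (leave-one-run-out).")
  noise <- utils::modifyList(list(sigma = 1, ar1_rho = 0, drift = 0), noise)
  local_seed(seed, {
    designs <- if (is.null(design)) {
      purrr::map(seq_len(n_runs), ~ make_run_design())
    } else if (inherits(design, "run_design")) {
      rep(list(design), n_runs)
    } else {
      stopifnot(length(design) == n_runs)
      design
    }
    runs <- purrr::map(seq_len(n_runs), function(r) {
      d <- designs[[r]]
      tvol <- d$n_volumes
      kern <- two_gamma_hrf(hrf, tr_s = d$tr_s)
      regs <- condition_regressors(d, kern)     # volumes x conditions
      regs <- regs[, model$conditions, drop = FALSE]
      signal <- regs %*% t(model$mean_pattern)  # volumes x voxels
      eps <- matrix(0, tvol, model$n_voxels)
      if (noise$sigma > 0) {
        eps <- vapply(seq_len(model$n_voxels),
                      function(v) ar1_noise(tvol, noise$sigma, noise$ar1_rho),
                      numeric(tvol))
      }
      drift <- noise$drift * seq(-0.5, 0.5, length.out = tvol)
      labels <- volume_labels(d)
      list(
        signals = baseline + signal + eps + drift,
        motion = simulate_motion(tvol),
        labels = labels
      )
    })
    structure(
      list(runs = runs, designs = designs, model = model, noise = noise,
           baseline = baseline, tr_s = designs[[1]]$tr_s, seed = seed),
      class = "synthetic_dataset"
    )
  })
}

# Per-volume block labels for one run design.
volume_labels <- function(design) {
  t_mid <- (seq_len(design$n_volumes) - 0.5) * design$tr_s
  idx <- findInterval(t_mid, design$blocks$onset_s)
  tibble(
    volume = seq_len(design$n_volumes),
    block = design$blocks$block[idx],
    type = design$blocks$type[idx],
    condition = design$blocks$condition[idx]
  )
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "<synthetic_dataset> %d runs x %d volumes x %d voxels (sigma = %g, rho = %g)\n",
    length(x$runs), nrow(x$runs[[1]]$signals), ncol(x$runs[[1]]$signals),
    x$noise$sigma, x$noise$ar1_rho
  ))
  invisible(x)
}

#' @export
tidy.synthetic_dataset <- function(x, ...) {
  purrr::imap(x$runs, function(r, i) dplyr::mutate(r$labels, run = i)) |>
    purrr::list_rbind() |>
    dplyr::relocate("run")
}

#' Write a synthetic dataset as flat text files
#'
#' Writes, per run, the signal matrix (`run<k>_signals.csv`, volumes x
#' voxels), the motion series (`run<k>_motion.csv`), and an events table
#' (`run<k>_events.tsv`: onset, duration, block type).
#'
#' @param dataset a [simulate_timeseries()] result.
#' @param dir output directory (created if missing).
#' @return Invisibly, the directory path.
#' @export
export_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(dataset$runs)) {
    r <- dataset$runs[[i]]
    utils::write.csv(r$signals, file.path(dir, sprintf("run%02d_signals.csv", i)),
                     row.names = FALSE)
    utils::write.csv(r$motion, file.path(dir, sprintf("run%02d_motion.csv", i)),
                     row.names = FALSE)
    ev <- dataset$designs[[i]]$blocks[, c("onset_s", "duration_s", "type")]
    utils::write.table(ev, file.path(dir, sprintf("run%02d_events.tsv", i)),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}
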