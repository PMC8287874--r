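#' Two-gamma hemodynamic response function parameters
#'
#' Canonical double-gamma HRF: a positive gamma lobe peaking at
#' `peak_delay_s` minus a delayed undershoot lobe peaking at
#' `undershoot_delay_s`, scaled down by `peak_undershoot_ratio`. Gamma
#' lobes are parameterized by their mode: shape = delay/dispersion + 1,
#' scale = dispersion, so the positive lobe peaks at `peak_delay_s`
#' exactly.
#'
#' @param peak_delay_s time-to-peak of the positive lobe (s).
#' @param undershoot_delay_s time-to-peak of the undershoot lobe (s).
#' @param peak_dispersion,undershoot_dispersion gamma scale parameters (s).
#' @param peak_undershoot_ratio peak:undershoot amplitude ratio.
#' @param duration_s kernel support (s).
#' @return A list of class `hrf_params`.
#' @export
hrf_params <- function(peak_delay_s = 6, undershoot_delay_s = 16,
                       peak_dispersion = 1, undershoot_dispersion = 1,
                       peak_undershoot_ratio = 6, duration_s = 32) {
  if (peak_delay_s <= 0 || undershoot_delay_s <= 0)
    abort("gamma delays must be positive.")
  if (peak_undershoot_ratio <= 0) abort("`peak_undershoot_ratio` must be > 0.")
  if (peak_dispersion <= 0 || undershoot_dispersion <= 0)
    abort("dispersions must be positive.")
  structure(
    list(peak_delay_s = peak_delay_s, undershoot_delay_s = undershoot_delay_s,
         peak_dispersion = peak_dispersion,
         undershoot_dispersion = undershoot_dispersion,
         peak_undershoot_ratio = peak_undershoot_ratio,
         duration_s = duration_s),
    class = "hrf_params"
  )
}

# Unnormalized double-gamma evaluated at times t (s).
hrf_value <- function(t, p) {
  g1 <- stats::dgamma(t, shape = p$peak_delay_s / p$peak_dispersion + 1,
                      scale = p$peak_dispersion)
  g2 <- stats::dgamma(t, shape = p$undershoot_delay_s / p$undershoot_dispersion + 1,
                      scale = p$undershoot_dispersion)
  g1 - g2 / p$peak_undershoot_ratio
}

#' Sample the two-gamma hemodynamic kernel
#'
#' Evaluates the double-gamma impulse response on a dense grid, normalizes
#' it to unit peak, and samples it at the TR.
#'
#' @param params an [hrf_params()].
#' @param tr_s sampling interval (repetition time, s).
#' @return Numeric vector of kernel values at `0, tr, 2 tr, ...` up to the
#'   kernel duration, with attribute `times_s`.
#' @examples
#' k <- two_gamma_hrf(hrf_params(), tr_s = 2)
#' which.max(k)  # peak near 6 s
#' @export
two_gamma_hrf <- function(params = hrf_params(), tr_s = 2) {
  stopifnot(inherits(params, "hrf_params"))
  if (tr_s <= 0) abort("`tr_s` must be positive.")
  fine <- seq(0, params$duration_s, by = 0.01)
  peak <- max(hrf_value(fine, params))
  t <- seq(0, params$duration_s, by = tr_s)
  k <- hrf_value(t, params) / peak
  attr(k, "times_s") <- t
  k
}

# Convolve a per-volume regressor with a kernel, truncated to input length.
convolve_hrf <- function(x, kernel) {
  n <- length(x)
  out <- stats::convolve(x, rev(kernel), type = "open")[seq_len(n)]
  out
}

# Per-condition boxcar regressors (volumes x 3), genders pooled, convolved
# with the hemodynamic kernel.
condition_regressors <- function(design, kernel,
                                 conditions = c("upright", "inverted", "random")) {
  labs <- volume_labels(design)
  regs <- vapply(conditions,
                 function(cc) convolve_hrf(as.numeric(labs$condition == cc), kernel),
                 numeric(design$n_volumes))
  colnames(regs) <- conditions
  regs
}

#' Build the run-level GLM design matrix
#'
#' Ten columns: three condition regressors (the 16-s stimulus boxcars of
#' each condition, genders pooled, convolved with the two-gamma HRF and
#' truncated to the run length), six motion nuisance regressors, and a
#' constant term. Optionally, a discrete-cosine high-pass set (all cosines
#' up to `dct_cycles` cycles per run) is appended as additional nuisance
#' columns instead of pre-filtering the data.
#'
#' @param design a [make_run_design()].
#' @param motion volumes x 6 matrix of motion parameters (3 translations,
#'   3 rotations).
#' @param hrf an [hrf_params()].
#' @param dct_cycles if non-`NULL`, append discrete-cosine regressors
#'   covering up to this many cycles per run (e.g. 3).
#' @return Numeric matrix (volumes x columns) with named columns; class
#'   `design_matrix`.
#' @export
build_design <- function(design, motion, hrf = hrf_params(), dct_cycles = NULL) {
  stopifnot(inherits(design, "run_design"))
  motion <- as.matrix(motion)
  if (nrow(motion) != design$n_volumes || ncol(motion) != 6L)
    abort("`motion` must be a volumes x 6 matrix matching the design.")
  kern <- two_gamma_hrf(hrf, tr_s = design$tr_s)
  regs <- condition_regressors(design, kern)
  colnames(motion) <- paste0("motion_", c("tx", "ty", "tz", "rx", "ry", "rz"))
  X <- cbind(regs, motion, constant = 1)
  if (!is.null(dct_cycles)) {
    tvol <- design$n_volumes
    ks <- seq_len(2 * dct_cycles)   # basis k spans k/2 cycles per run
    dct <- vapply(ks, function(k)
      cos(pi * (2 * seq_len(tvol) - 1) * k / (2 * tvol)), numeric(tvol))
    colnames(dct) <- paste0("dct_", ks)
    X <- cbind(X, dct)
  }
  class(X) <- c("design_matrix", class(X))
  X
}

#' Fit an ordinary least-squares GLM per voxel
#'
#' Solves the OLS problem for every signal column against the design
#' matrix, returning raw beta weights, percent-signal-change betas
#' (100 x beta / constant-term beta), and residual variances.
#'
#' @param signals numeric vector or volumes x voxels matrix of BOLD
#'   signals.
#' @param X design matrix from [build_design()] (any full-column-rank
#'   matrix with a `constant` column works).
#' @return An object of class `glm_fit`: `betas` (terms x voxels), `psc`
#'   (same shape, percent signal change), `sigma2` (residual variance per
#'   voxel), `df_residual`, `X`.
#' @export
fit_glm <- function(signals, X) {
  signals <- as.matrix(signals)
  X <- unclass(X)
  if (nrow(signals) != nrow(X))
    abort("`signals` and design matrix must have the same number of rows.")
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    bad <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    abort(sprintf("design matrix is rank deficient; collinear column(s): %s",
                  paste(bad, collapse = ", ")))
  }
  betas <- qr.coef(qr_x, signals)
  rownames(betas) <- colnames(X)
  resid <- signals - X %*% betas
  dfr <- nrow(X) - ncol(X)
  sigma2 <- colSums(resid^2) / dfr
  psc <- if ("constant" %in% rownames(betas)) {
    sweep(betas, 2, betas["constant", ], "/") * 100
  } else NULL
  structure(
    list(betas = betas, psc = psc, sigma2 = sigma2,
         df_residual = dfr, X = X),
    class = "glm_fit"
  )
}

#' @export
print.glm_fit <- function(x, ...) {
  cat(sprintf("<glm_fit> %d terms x %d voxels, df_residual = %d\n",
              nrow(x$betas), ncol(x$betas), x$df_residual))
  invisible(x)
}

#' @export
tidy.glm_fit <- function(x, ...) {
  nb <- ncol(x$betas)
  tibble(
    voxel = rep(seq_len(nb), each = nrow(x$betas)),
    term = rep(rownames(x$betas), times = nb),
    estimate = as.vector(x$betas),
    psc = if (is.null(x$psc)) NA_real_ else as.vector(x$psc)
  )
}

#' @export
glance.glm_fit <- function(x, ...) {
  tibble(n_terms = nrow(x$betas), n_voxels = ncol(x$betas),
         df_residual = x$df_residual, mean_sigma2 = mean(x$sigma2))
}

#' Condition beta weights for ROI-averaged time courses
#'
#' For each ROI, the time course is averaged across the ROI's voxels and
#' that single series is fitted with the GLM; the three condition betas are
#' reported in percent signal change (100 x beta / constant-term beta).
#' When `signals`/`X` are lists (one element per run), runs are fitted
#' separately and betas averaged across runs.
#'
#' @param signals volumes x voxels matrix, or list of such matrices (one
#'   per run).
#' @param X design matrix, or list of design matrices matching `signals`.
#' @param roi named list of voxel index vectors defining the ROIs.
#' @return Tibble: `roi`, `condition`, `beta_psc`.
#' @export
roi_contrast <- function(signals, X, roi) {
  if (!is.list(roi) || is.null(names(roi))) abort("`roi` must be a named list.")
  if (any(lengths(roi) == 0L)) abort("empty ROI in `roi`.")
  sig_list <- if (is.list(signals)) signals else list(signals)
  x_list <- if (is.list(X) && !is.matrix(X)) X else list(X)
  stopifnot(length(sig_list) == length(x_list))
  conditions <- c("upright", "inverted", "random")
  purrr::imap(roi, function(vox, nm) {
    per_run <- purrr::map2(sig_list, x_list, function(s, x) {
      mean_tc <- rowMeans(s[, vox, drop = FALSE])
      fit <- fit_glm(mean_tc, x)
      fit$psc[conditions, 1]
    })
    est <- Reduce(`+`, per_run) / length(per_run)
    tibble(roi = nm, condition = conditions, beta_psc = unname(est))
  }) |> purrr::list_rbind()
}

#' Fit the GLM to a synthetic dataset
#'
#' Convenience wrapper: builds each run's design matrix from its schedule
#' and motion series, fits every voxel, and returns run-averaged condition
#' betas in percent signal change.
#'
#' @param dataset a [simulate_timeseries()] result.
#' @param hrf an [hrf_params()].
#' @param roi optional named list of voxel index vectors; when supplied,
#'   ROI-averaged fits are returned via [roi_contrast()].
#' @param dct_cycles optional high-pass discrete-cosine set (cycles/run).
#' @return With `roi`: tibble from [roi_contrast()]. Without: tibble
#'   `condition` x `voxel` with run-averaged `beta_psc`.
#' @export
fit_dataset_glm <- function(dataset, hrf = hrf_params(), roi = NULL,
                            dct_cycles = NULL) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  xs <- purrr::map2(dataset$designs, dataset$runs,
                    ~ build_design(.x, .y$motion, hrf, dct_cycles))
  sigs <- purrr::map(dataset$runs, "signals")
  if (!is.null(roi)) return(roi_contrast(sigs, xs, roi))
  conditions <- c("upright", "inverted", "random")
  per_run <- purrr::map2(sigs, xs, function(s, x) fit_glm(s, x)$psc[conditions, , drop = FALSE])
  est <- Reduce(`+`, per_run) / length(per_run)
  tibble(
    condition = rep(conditions, times = ncol(est)),
    voxel = rep(seq_len(ncol(est)), each = length(conditions)),
    beta_psc = as.vector(est)
  )
}
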