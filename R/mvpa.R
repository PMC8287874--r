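#' Prepare multivoxel patterns for decoding
#'
#' Converts a synthetic (or real) voxel time-series dataset into labeled
#' decoding samples: each voxel's time course is z-scored within run, the
#' condition labels are shifted forward by `shift_trs` volumes (4 s = 2 TRs
#' by default) to account for hemodynamic delay, and only volumes falling
#' inside (shifted) stimulus blocks of the two target classes are kept.
#' Stimulus genders are pooled into the three conditions.
#'
#' @param dataset a [simulate_timeseries()] result (>= 2 runs).
#' @param pair the 2-class problem: either a character vector of two
#'   condition names (e.g. `c("upright", "random")`) or a named list of two
#'   condition groups for pooled classes (e.g.
#'   `list(upright = "upright", nonface = c("inverted", "random"))`).
#' @param shift_trs hemodynamic shift in volumes.
#' @param on_zero_variance `"drop"` removes voxels with zero within-run
#'   variance with a warning; `"error"` aborts.
#' @return An object of class `pattern_dataset`: `samples` (n x voxels,
#'   z-scored), `labels` (factor with the two class names), `run`, `block`
#'   (integer ids per sample), `voxel_coords`, `voxel_id` (column ->
#'   original voxel index), `shift_applied_trs`.
#' @export
prepare_patterns <- function(dataset, pair = c("upright", "random"),
                             shift_trs = 2L,
                             on_zero_variance = c("drop", "error")) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  on_zero_variance <- match.arg(on_zero_variance)
  groups <- if (is.list(pair)) pair else stats::setNames(as.list(pair), pair)
  if (length(groups) != 2L) abort("`pair` must define exactly two classes.")

  zero_var <- integer(0)
  per_run <- purrr::imap(dataset$runs, function(r, i) {
    sds <- apply(r$signals, 2, stats::sd)
    zv <- which(sds == 0)
    if (length(zv)) zero_var <<- union(zero_var, zv)
    z <- scale(r$signals)
    labs <- r$labels
    n <- nrow(z)
    shifted_cond <- c(rep(NA_character_, shift_trs),
                      labs$condition[seq_len(n - shift_trs)])
    shifted_block <- c(rep(NA_integer_, shift_trs),
                       labs$block[seq_len(n - shift_trs)])
    cls <- rep(NA_character_, n)
    for (g in names(groups)) cls[shifted_cond %in% groups[[g]]] <- g
    keep <- !is.na(cls)
    list(samples = z[keep, , drop = FALSE],
         labels = cls[keep],
         block = shifted_block[keep],
         run = rep(i, sum(keep)))
  })

  samples <- do.call(rbind, purrr::map(per_run, "samples"))
  labels <- factor(unlist(purrr::map(per_run, "labels")), levels = names(groups))
  run <- unlist(purrr::map(per_run, "run"))
  block <- unlist(purrr::map(per_run, "block"))

  for (r in unique(run)) {
    if (dplyr::n_distinct(labels[run == r]) < 2L)
      abort(sprintf("run %d is missing one of the two classes.", r))
  }

  voxel_id <- seq_len(ncol(samples))
  if (length(zero_var)) {
    if (on_zero_variance == "error")
      abort(sprintf("%d voxel(s) have zero within-run variance.", length(zero_var)))
    warn(sprintf("dropping %d zero-variance voxel(s) before decoding.",
                 length(zero_var)))
    samples <- samples[, -zero_var, drop = FALSE]
    voxel_id <- voxel_id[-zero_var]
  }

  structure(
    list(samples = unname(samples), labels = labels, run = run, block = block,
         voxel_coords = dataset$model$voxel_coords[voxel_id, , drop = FALSE],
         voxel_id = voxel_id, shift_applied_trs = shift_trs,
         classes = names(groups)),
    class = "pattern_dataset"
  )
}

#' Construct a pattern dataset from tabular data
#'
#' Entry point for voxel patterns that did not come through
#' [simulate_timeseries()] — e.g. real preprocessed samples, or directly
#' constructed matrices in tests. Samples are assumed already z-scored and
#' hemodynamically shifted; set `shift_applied_trs` to record the shift.
#'
#' @param samples numeric matrix, samples x voxels.
#' @param labels class label per sample (2 classes).
#' @param run run id per sample (>= 2 runs, each with both classes).
#' @param block block id per sample; defaults to one block per
#'   run-by-class cell.
#' @param voxel_coords optional voxels x 3 coordinate matrix (mm), needed
#'   for the searchlight.
#' @param shift_applied_trs hemodynamic shift already applied, in TRs.
#' @return A `pattern_dataset`.
#' @export
pattern_dataset <- function(samples, labels, run, block = NULL,
                            voxel_coords = NULL, shift_applied_trs = 0L) {
  samples <- as.matrix(samples)
  labels <- factor(labels)
  if (nlevels(labels) != 2L) abort("`labels` must have exactly two classes.")
  stopifnot(length(labels) == nrow(samples), length(run) == nrow(samples))
  if (is.null(block))
    block <- as.integer(interaction(run, labels, drop = TRUE))
  if (dplyr::n_distinct(run) < 2L) abort("need at least 2 runs.")
  for (r in unique(run)) {
    if (dplyr::n_distinct(labels[run == r]) < 2L)
      abort(sprintf("run %s is missing one of the two classes.", r))
  }
  if (!is.null(voxel_coords)) {
    voxel_coords <- as.matrix(voxel_coords)
    stopifnot(nrow(voxel_coords) == ncol(samples), ncol(voxel_coords) == 3L)
  }
  structure(
    list(samples = unname(samples), labels = labels, run = run,
         block = block, voxel_coords = voxel_coords,
         voxel_id = seq_len(ncol(samples)),
         shift_applied_trs = as.integer(shift_applied_trs),
         classes = levels(labels)),
    class = "pattern_dataset"
  )
}

#' @export
print.pattern_dataset <- function(x, ...) {
  cat(sprintf(
    "<pattern_dataset> %d samples x %d voxels, classes %s, %d runs, shift %d TRs\n",
    nrow(x$samples), ncol(x$samples), paste(x$classes, collapse = " vs "),
    dplyr::n_distinct(x$run), x$shift_applied_trs
  ))
  invisible(x)
}

#' @export
tidy.pattern_dataset <- function(x, ...) {
  tibble(sample = seq_along(x$labels), label = as.character(x$labels),
         run = x$run, block = x$block)
}

# Linear soft-margin SVM fit; returns model + signed weight vector.
fit_linear_svm <- function(x, y, cost = 1) {
  m <- e1071::svm(x, y, kernel = "linear", cost = cost, scale = FALSE)
  w <- drop(t(m$coefs) %*% m$SV)
  list(model = m, weights = w)
}

svm_accuracy <- function(x_train, y_train, x_test, y_test, cost = 1) {
  m <- e1071::svm(x_train, y_train, kernel = "linear", cost = cost, scale = FALSE)
  mean(stats::predict(m, x_test) == y_test)
}

# --- Gram-factor SVM machinery ---------------------------------------------
# libSVM recomputes the linear kernel from raw features on every call, which
# dominates the cost of the elimination loop. Since the linear-SVM solution
# depends on the samples only through their Gram matrix, each fit is run on a
# Cholesky factor of the (jittered) Gram instead: identical kernel values,
# identical libSVM solution, at rank(G) <= n feature dimensions. The Gram is
# maintained across elimination steps by rank-k downdates.

chol_jitter <- function(G, eps) chol(G + diag(eps, nrow(G)))

# Fit on the Gram factor; weights mapped back through the original features.
svm_fit_gram <- function(G, x_feat, y, cost, eps) {
  R <- tryCatch(chol_jitter(G, eps), error = function(e) NULL)
  if (is.null(R)) return(fit_linear_svm(x_feat, y, cost))
  m <- e1071::svm(t(R), y, kernel = "linear", cost = cost, scale = FALSE)
  w <- drop(t(m$coefs) %*% x_feat[m$index, , drop = FALSE])
  list(model = m, weights = w, chol = R)
}

# Held-out accuracy of a Gram-factor fit: test samples are lifted into the
# factor basis so that their kernel against training samples equals C_te.
# Falls back to a direct fit if the jittered Gram is not factorizable.
svm_accuracy_gram <- function(G, x_tr, y_tr, C_te, x_te, y_te, cost, eps) {
  fit <- svm_fit_gram(G, x_tr, y_tr, cost, eps)
  if (is.null(fit$chol))
    return(svm_accuracy(x_tr, y_tr, x_te, y_te, cost))
  z_te <- t(forwardsolve(t(fit$chol), t(C_te)))
  mean(stats::predict(fit$model, z_te) == y_te)
}

# Voxel ranking scores from `n_resamples` draws of `frac` of the training
# samples (block boundaries ignored, per the resampling rule). `G` is the
# training Gram over the active voxels; `x` the matching feature matrix.
resampled_weights <- function(x, y, n_resamples = 20, frac = 0.8, cost = 1,
                              G = NULL, eps = NULL) {
  n <- nrow(x)
  if (is.null(G)) G <- tcrossprod(x)
  if (is.null(eps)) eps <- gram_eps(G)
  w <- vapply(seq_len(n_resamples), function(j) {
    idx <- sample(n, max(2L, round(frac * n)))
    while (dplyr::n_distinct(y[idx]) < 2L) idx <- sample(n, max(2L, round(frac * n)))
    svm_fit_gram(G[idx, idx], x[idx, , drop = FALSE],
                 droplevels(y[idx]), cost, eps)$weights
  }, numeric(ncol(x)))
  w  # voxels x resamples
}

gram_eps <- function(G) 1e-8 * max(mean(diag(G)), 1e-12)

rank_scores <- function(w, method = c("abs_of_mean", "mean_of_abs")) {
  method <- match.arg(method)
  switch(method,
    abs_of_mean = abs(rowMeans(w)),
    mean_of_abs = rowMeans(abs(w))
  )
}

#' Leave-one-run-out linear SVM decoding (no feature elimination)
#'
#' @param patterns a [prepare_patterns()] result.
#' @param voxels optional column indices restricting the pattern.
#' @param cost soft-margin penalty.
#' @param labels optional replacement label vector (used by permutation
#'   tests).
#' @return Tibble: `fold` (left-out run), `accuracy`; the mean accuracy is
#'   in attribute `accuracy`.
#' @export
decode_loro <- function(patterns, voxels = NULL, cost = 1, labels = NULL) {
  stopifnot(inherits(patterns, "pattern_dataset"))
  y <- labels %||% patterns$labels
  x <- if (is.null(voxels)) patterns$samples
       else patterns$samples[, voxels, drop = FALSE]
  folds <- sort(unique(patterns$run))
  acc <- vapply(folds, function(f) {
    tr <- patterns$run != f
    svm_accuracy(x[tr, , drop = FALSE], droplevels(y[tr]),
                 x[!tr, , drop = FALSE], y[!tr], cost)
  }, numeric(1))
  out <- tibble(fold = folds, accuracy = acc)
  attr(out, "accuracy") <- mean(acc)
  out
}

#' Recursive feature elimination decoding
#'
#' The decoding pipeline: for each leave-one-run-out fold, voxels are
#' eliminated iteratively — on every step the classifier is trained on 20
#' resamples of 80% of the training samples (drawn without regard to block
#' boundaries), each voxel's weight is averaged over the resamples, voxels
#' are ranked by the absolute average weight, and the five lowest-ranked
#' voxels are eliminated (the final elimination is truncated so that
#' exactly `stop_size` voxels remain). After every elimination the
#' surviving pattern is retrained on the full training set and scored on
#' the held-out run. The final accuracy is the mean across folds of the
#' accuracy at `stop_size`.
#'
#' @param patterns a [prepare_patterns()] result with more than
#'   `stop_size` voxels.
#' @param stop_size final pattern size (250 in the reference protocol).
#' @param step_size voxels eliminated per step.
#' @param n_resamples resampled classifiers per step.
#' @param resample_frac fraction of training samples per resample.
#' @param cost soft-margin penalty (fixed; no per-fold tuning).
#' @param rank_method `"abs_of_mean"` ranks by |mean signed weight| (the
#'   default reading of "average weights"); `"mean_of_abs"` by the mean of
#'   |weight|.
#' @param seed integer seed; identical seeds give identical elimination
#'   orders and accuracies.
#' @param labels optional replacement labels (permutation tests).
#' @return An object of class `rfe_result`: `trace` (tibble: `fold`,
#'   `step`, `voxel_count`, `accuracy`, `eliminated` list-column of
#'   original voxel ids), `fold_accuracies`, `final_accuracy`,
#'   `final_pattern_size`, `survivors` (per-fold surviving original voxel
#'   ids), `pair`.
#' @examples
#' \donttest{
#' mod <- voxel_pattern_model(n_voxels = 40, n_informative = 10,
#'                            effect_size = 2, seed = 1)
#' ds <- simulate_timeseries(mod, n_runs = 2, seed = 1)
#' pat <- prepare_patterns(ds, c("upright", "random"))
#' res <- rfe_decode(pat, stop_size = 20, seed = 1)
#' res$final_accuracy
#' }
#' @export
rfe_decode <- function(patterns, stop_size = 250, step_size = 5,
                       n_resamples = 20, resample_frac = 0.8, cost = 1,
                       rank_method = c("abs_of_mean", "mean_of_abs"),
                       seed = NULL, labels = NULL) {
  stopifnot(inherits(patterns, "pattern_dataset"))
  rank_method <- match.arg(rank_method)
  n_vox <- ncol(patterns$samples)
  if (stop_size >= n_vox)
    abort("`stop_size` must be smaller than the number of voxels.")
  y_all <- labels %||% patterns$labels
  local_seed(seed, {
    folds <- sort(unique(patterns$run))
    trace_rows <- list()
    survivors <- list()
    fold_acc <- numeric(length(folds))
    for (fi in seq_along(folds)) {
      f <- folds[fi]
      tr <- patterns$run != f
      x_tr <- patterns$samples[tr, , drop = FALSE]
      y_tr <- droplevels(y_all[tr])
      x_te <- patterns$samples[!tr, , drop = FALSE]
      y_te <- y_all[!tr]
      # training Gram and train-test cross-kernel over the active voxels,
      # downdated as voxels are eliminated
      G <- tcrossprod(x_tr)
      C_te <- tcrossprod(x_te, x_tr)
      eps <- gram_eps(G)
      active <- seq_len(n_vox)
      step <- 0L
      acc <- NA_real_
      while (length(active) > stop_size) {
        step <- step + 1L
        w <- resampled_weights(x_tr[, active, drop = FALSE], y_tr,
                               n_resamples, resample_frac, cost, G = G, eps = eps)
        score <- rank_scores(w, rank_method)
        n_elim <- min(step_size, length(active) - stop_size)
        drop_pos <- order(score, seq_along(score))[seq_len(n_elim)]
        elim_cols <- active[drop_pos]
        eliminated <- patterns$voxel_id[elim_cols]
        G <- G - tcrossprod(x_tr[, elim_cols, drop = FALSE])
        C_te <- C_te - tcrossprod(x_te[, elim_cols, drop = FALSE],
                                  x_tr[, elim_cols, drop = FALSE])
        active <- active[-drop_pos]
        acc <- svm_accuracy_gram(G, x_tr[, active, drop = FALSE], y_tr,
                                 C_te, x_te[, active, drop = FALSE], y_te,
                                 cost, eps)
        trace_rows[[length(trace_rows) + 1L]] <- tibble(
          fold = f, step = step, voxel_count = length(active),
          accuracy = acc, eliminated = list(eliminated)
        )
      }
      fold_acc[fi] <- acc
      survivors[[fi]] <- patterns$voxel_id[active]
    }
    structure(
      list(
        trace = purrr::list_rbind(trace_rows),
        fold_accuracies = tibble(fold = folds, accuracy = fold_acc),
        final_accuracy = mean(fold_acc),
        final_pattern_size = stop_size,
        survivors = stats::setNames(survivors, paste0("fold_", folds)),
        pair = patterns$classes
      ),
      class = "rfe_result"
    )
  })
}

#' @export
print.rfe_result <- function(x, ...) {
  cat(sprintf(
    "<rfe_result> %s vs %s: final accuracy %.3f at %d voxels (%d folds)\n",
    x$pair[1], x$pair[2], x$final_accuracy, x$final_pattern_size,
    nrow(x$fold_accuracies)
  ))
  invisible(x)
}

#' @export
tidy.rfe_result <- function(x, ...) dplyr::select(x$trace, -"eliminated")

#' @export
glance.rfe_result <- function(x, ...) {
  tibble(pair = paste(x$pair, collapse = " vs "),
         final_accuracy = x$final_accuracy,
         final_pattern_size = x$final_pattern_size,
         n_folds = nrow(x$fold_accuracies))
}

# Permute class labels at the block level within each run: every (shifted)
# block keeps its samples together and is reassigned a class drawn from the
# run's block-class multiset.
permute_block_labels <- function(patterns) {
  y <- as.character(patterns$labels)
  for (r in unique(patterns$run)) {
    in_run <- patterns$run == r
    blocks <- unique(patterns$block[in_run])
    block_class <- vapply(blocks, function(b)
      y[in_run & patterns$block == b][1], character(1))
    new_class <- sample(block_class)
    for (k in seq_along(blocks)) {
      y[in_run & patterns$block == blocks[k]] <- new_class[k]
    }
  }
  factor(y, levels = levels(patterns$labels))
}

#' Permutation baseline for decoding accuracy
#'
#' Re-runs the decoding pipeline on label permutations to obtain the null
#' distribution of accuracies. Labels are permuted at the block level
#' within each run, preserving the run/block structure and class balance.
#' By default each permutation uses a reduced pipeline (a single
#' 20-resample ranking pass selecting the top `stop_size` voxels per fold)
#' for tractability; `method = "full"` reruns the exact recursive
#' elimination, and `method = "loro"` decodes without voxel selection.
#'
#' @param patterns a [prepare_patterns()] result.
#' @param n number of permutations (1000 in the reference protocol; fewer
#'   than 100 triggers a warning).
#' @param stop_size selected pattern size (ignored for `method = "loro"`
#'   or when the dataset has at most `stop_size` voxels).
#' @param method `"reduced"`, `"full"`, or `"loro"`.
#' @param cost soft-margin penalty.
#' @param baseline_quantile summary order statistic reported as the
#'   baseline (upper 95th percentile of the null by default).
#' @param seed integer seed.
#' @return An object of class `permutation_null`: `null_accuracies`,
#'   `baseline`, `n_permutations`, `method`, `seed`.
#' @export
permutation_baseline <- function(patterns, n = 1000, stop_size = 250,
                                 method = c("reduced", "full", "loro"),
                                 cost = 1, baseline_quantile = 0.95,
                                 seed = NULL) {
  stopifnot(inherits(patterns, "pattern_dataset"))
  method <- match.arg(method)
  if (n < 100) warn("fewer than 100 permutations: baseline will be noisy.")
  if (ncol(patterns$samples) <= stop_size) method <- "loro"
  local_seed(seed, {
    null_acc <- vapply(seq_len(n), function(i) {
      y <- permute_block_labels(patterns)
      decode_with_pipeline(patterns, y, method, stop_size, cost)
    }, numeric(1))
    structure(
      list(null_accuracies = null_acc,
           baseline = unname(stats::quantile(null_acc, baseline_quantile)),
           n_permutations = n, method = method,
           baseline_quantile = baseline_quantile, seed = seed),
      class = "permutation_null"
    )
  })
}

# One decoding under a given label assignment, by pipeline flavour.
decode_with_pipeline <- function(patterns, y, method, stop_size, cost) {
  if (method == "loro" || ncol(patterns$samples) <= stop_size) {
    return(attr(decode_loro(patterns, cost = cost, labels = y), "accuracy"))
  }
  if (method == "full") {
    return(rfe_decode(patterns, stop_size = stop_size, cost = cost,
                      labels = y)$final_accuracy)
  }
  # reduced: one ranking pass per fold, top stop_size voxels
  folds <- sort(unique(patterns$run))
  acc <- vapply(folds, function(f) {
    tr <- patterns$run != f
    x_tr <- patterns$samples[tr, , drop = FALSE]
    y_tr <- droplevels(y[tr])
    w <- resampled_weights(x_tr, y_tr, 20, 0.8, cost)
    score <- rank_scores(w)
    keep <- order(score, seq_along(score), decreasing = TRUE)[seq_len(stop_size)]
    svm_accuracy(x_tr[, keep, drop = FALSE], y_tr,
                 patterns$samples[!tr, keep, drop = FALSE], y[!tr], cost)
  }, numeric(1))
  mean(acc)
}

#' @export
print.permutation_null <- function(x, ...) {
  cat(sprintf(
    "<permutation_null> %d permutations (%s): mean %.3f, baseline (q%.2f) %.3f\n",
    x$n_permutations, x$method, mean(x$null_accuracies),
    x$baseline_quantile, x$baseline
  ))
  invisible(x)
}

#' @export
tidy.permutation_null <- function(x, ...) {
  tibble(permutation = seq_along(x$null_accuracies),
         accuracy = x$null_accuracies)
}

#' @export
glance.permutation_null <- function(x, ...) {
  tibble(n_permutations = x$n_permutations, method = x$method,
         null_mean = mean(x$null_accuracies), baseline = x$baseline)
}

#' Searchlight decoding map
#'
#' Slides a spherical neighborhood (6-mm radius by default) across the
#' voxel grid; at each center, all voxels within the sphere are decoded
#' with a leave-one-run-out linear SVM (no feature elimination) and the
#' accuracy is written to the center voxel.
#'
#' @param patterns a [prepare_patterns()] result with voxel coordinates.
#' @param radius_mm sphere radius.
#' @param cost soft-margin penalty.
#' @return A tibble of class `searchlight_map`: `voxel`, `x`, `y`, `z`
#'   (mm), `n_in_sphere`, `accuracy`.
#' @export
searchlight <- function(patterns, radius_mm = 6, cost = 1) {
  stopifnot(inherits(patterns, "pattern_dataset"))
  coords <- patterns$voxel_coords
  if (is.null(coords) || nrow(coords) != ncol(patterns$samples))
    abort("voxel coordinates are required for the searchlight.")
  r2 <- radius_mm^2
  res <- purrr::map(seq_len(nrow(coords)), function(v) {
    d2 <- colSums((t(coords) - coords[v, ])^2)
    nb <- which(d2 <= r2)
    if (length(nb) < 2L)
      abort(sprintf("searchlight sphere at voxel %d contains < 2 voxels.", v))
    acc <- attr(decode_loro(patterns, voxels = nb, cost = cost), "accuracy")
    tibble(voxel = v, x = coords[v, 1], y = coords[v, 2], z = coords[v, 3],
           n_in_sphere = length(nb), accuracy = acc)
  }) |> purrr::list_rbind()
  class(res) <- c("searchlight_map", class(res))
  res
}
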