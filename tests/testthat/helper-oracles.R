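# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: direct O(N^4) DFT, explicit convolution loops,
# explicit sum-of-squares arithmetic.

# Brute-force 2D DFT amplitude spectrum (quadruple loop).
brute_force_dft_amplitude <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  for (u in 0:(nr - 1)) {
    for (v in 0:(nc - 1)) {
      acc <- 0 + 0i
      for (r in 0:(nr - 1)) {
        for (c in 0:(nc - 1)) {
          acc <- acc + m[r + 1, c + 1] *
            exp(-2i * pi * (u * r / nr + v * c / nc))
        }
      }
      out[u + 1, v + 1] <- Mod(acc)
    }
  }
  out
}

# Direct discrete convolution, truncated to length(x).
brute_force_convolve <- function(x, k) {
  n <- length(x)
  out <- numeric(n)
  for (t in seq_len(n)) {
    for (j in seq_along(k)) {
      if (t - j + 1 >= 1) out[t] <- out[t] + x[t - j + 1] * k[j]
    }
  }
  out
}

# Direct sum-of-squares one-way repeated-measures ANOVA (explicit loops).
brute_force_rm_anova <- function(y, subject, condition) {
  subject <- as.character(subject); condition <- as.character(condition)
  subj <- unique(subject); cond <- unique(condition)
  n <- length(subj); k <- length(cond)
  gm <- mean(y)
  ss_cond <- 0
  for (cc in cond) ss_cond <- ss_cond + n * (mean(y[condition == cc]) - gm)^2
  ss_subj <- 0
  for (ss in subj) ss_subj <- ss_subj + k * (mean(y[subject == ss]) - gm)^2
  ss_tot <- sum((y - gm)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  f <- (ss_cond / (k - 1)) / (ss_err / ((n - 1) * (k - 1)))
  list(F = f, df1 = k - 1, df2 = (n - 1) * (k - 1),
       p = pf(f, k - 1, (n - 1) * (k - 1), lower.tail = FALSE),
       pes = ss_cond / (ss_cond + ss_err))
}

# Lattice-point enumeration: voxels within radius_mm of a center on an
# integer grid with the given pitch.
brute_force_sphere_count <- function(radius_mm, pitch_mm) {
  r <- ceiling(radius_mm / pitch_mm)
  count <- 0L
  for (i in -r:r) for (j in -r:r) for (k in -r:r) {
    if ((i^2 + j^2 + k^2) * pitch_mm^2 <= radius_mm^2) count <- count + 1L
  }
  count
}

# Fixed-seed pattern dataset with a planted linear signal, built without
# the synthetic fMRI generator (raw samples straight into pattern_dataset).
make_planted_patterns <- function(n_per_run = 100, n_runs = 2, n_voxels = 60,
                                  n_signal = 10, amplitude = 1, seed = 1) {
  withr::with_seed(seed, {
    n <- n_per_run * n_runs
    y <- rep(rep(c("a", "b"), each = 5), length.out = n)
    w <- c(rep(amplitude, n_signal), rep(0, n_voxels - n_signal))
    x <- matrix(rnorm(n * n_voxels), n, n_voxels) +
      outer(ifelse(y == "a", 1, -1), w)
    pattern_dataset(x, y, run = rep(seq_len(n_runs), each = n_per_run))
  })
}
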