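test_that("inverting a depth map rotates values and mask by 180 degrees", {
  m <- matrix(0, 5, 7)
  m[2, 3] <- 1.5
  dm <- depth_map(m, matrix(TRUE, 5, 7))
  inv <- invert_depth_map(dm)
  # cell (r, c) -> (R - 1 - r, C - 1 - c) in 0-based indexing
  expect_equal(inv$values[5 - 2 + 1, 7 - 3 + 1], 1.5)
  expect_equal(sum(inv$values != 0), 1L)
  # involution
  expect_identical(invert_depth_map(inv)$values, dm$values)
  # point-symmetric map is a fixed point
  sym <- outer(seq(-1, 1, length.out = 5), seq(-1, 1, length.out = 5), `*`)
  dms <- depth_map(sym, matrix(TRUE, 5, 5))
  expect_equal(invert_depth_map(dms)$values, dms$values)
  # depth histogram is preserved exactly
  set.seed(1)
  dmr <- depth_map(matrix(rnorm(48), 6, 8))
  expect_identical(sort(as.vector(invert_depth_map(dmr)$values)),
                   sort(as.vector(dmr$values)))
})

test_that("phase randomization preserves the amplitude spectrum exactly", {
  # against the brute-force O(N^4) DFT oracle on an 8x8 map
  set.seed(42)
  dm <- depth_map(matrix(rnorm(64), 8, 8), matrix(TRUE, 8, 8))
  pr <- phase_randomize(dm, seed = 7)
  amp_in <- brute_force_dft_amplitude(dm$values)
  amp_out <- brute_force_dft_amplitude(pr$values)
  expect_lt(max(abs(amp_out - amp_in)) / max(amp_in), 1e-9)
  # output is real-valued and different from the input
  expect_true(all(is.finite(pr$values)))
  expect_gt(max(abs(pr$values - dm$values)), 1e-3)
  # all-zero map maps to all-zero
  z <- depth_map(matrix(0, 8, 8), matrix(TRUE, 8, 8))
  expect_equal(max(abs(phase_randomize(z, seed = 1)$values)), 0)
})

test_that("amplitude conservation holds across many maps and seeds", {
  set.seed(3)
  worst <- 0
  for (i in 1:200) {
    dm <- depth_map(matrix(rnorm(256), 16, 16), matrix(TRUE, 16, 16))
    pr <- phase_randomize(dm, seed = i)
    a_in <- Mod(stats::fft(dm$values))
    a_out <- Mod(stats::fft(pr$values))
    worst <- max(worst, max(abs(a_out - a_in)) / max(a_in))
  }
  expect_lt(worst, 1e-9)
})

test_that("one matched random surface is produced per input map", {
  maps <- purrr::map(1:4, ~ make_face_like_depth_map(seed = .x))
  scrambled <- purrr::imap(maps, ~ phase_randomize(.x, seed = 100 + .y))
  expect_length(scrambled, 4L)
  # each output matches its own input's (masked) spectrum, not the others'
  for (i in 1:4) {
    a_out <- Mod(stats::fft(scrambled[[i]]$values))
    a_own <- Mod(stats::fft(maps[[i]]$values * maps[[i]]$mask))
    expect_lt(max(abs(a_out - a_own)) / max(a_own), 1e-9)
  }
  expect_gt(max(abs(scrambled[[1]]$values - scrambled[[2]]$values)), 1e-3)
})

test_that("rendered stereograms have the specified dot count and disparity bounds", {
  dm <- make_face_like_depth_map(seed = 5)
  spec <- stimulus_spec(snr = 0.6)
  pair <- render_rds(dm, spec, seed = 11)
  # density x area, computed independently
  expect_equal(nrow(pair$dots), round(20 * 8.68^2))
  expect_lte(max(abs(pair$dots$disparity_arcmin)), 5.3 + 1e-12)
  # fuzz the bound over seeds and SNR levels
  for (s in 1:5) {
    p <- render_rds(dm, stimulus_spec(snr = (s - 1) / 4), seed = s)
    expect_lte(max(abs(p$dots$disparity_arcmin)), 5.3 + 1e-12)
  }
})

test_that("signal/noise assignment uses exact counts at the requested SNR", {
  dm <- make_face_like_depth_map(seed = 5)
  for (snr in c(0, 0.3, 0.82, 1)) {
    p <- render_rds(dm, stimulus_spec(snr = snr), seed = 21)
    tgt <- p$dots[p$dots$role != "surround", ]
    n_signal <- sum(tgt$role == "signal")
    expect_equal(n_signal, floor(snr * nrow(tgt)))
  }
})

test_that("snr = 1 with a flat maximal surface pins every target dot at max disparity", {
  flat <- depth_map(matrix(1, 32, 32), matrix(TRUE, 32, 32))
  p <- render_rds(flat, stimulus_spec(snr = 1), seed = 2)
  sig <- p$dots[p$dots$role == "signal", ]
  expect_gt(nrow(sig), 0)
  expect_true(all(abs(abs(sig$disparity_arcmin) - 5.3) < 1e-12))
  # far sign flips the disparity
  pf <- render_rds(flat, stimulus_spec(snr = 1, depth_sign = "far"), seed = 2)
  expect_true(all(pf$dots$disparity_arcmin[pf$dots$role == "signal"] < 0))
  expect_true(all(p$dots$disparity_arcmin[p$dots$role == "signal"] > 0))
})

test_that("snr = 0 noise disparities are uniform on the +/- max range", {
  dm <- make_face_like_depth_map(seed = 5)
  disp <- unlist(purrr::map(1:25, function(s) {
    p <- render_rds(dm, stimulus_spec(snr = 0), seed = 100 + s)
    d <- p$dots$disparity_arcmin[p$dots$role == "noise"]
    expect_true(all(p$dots$role[p$dots$disparity_arcmin != 0] == "noise"))
    d
  }))
  expect_gt(length(disp), 1e4)
  ks <- suppressWarnings(stats::ks.test(disp, "punif", -5.3, 5.3))
  expect_gt(ks$p.value, 0.01)
})

test_that("mean unsigned signal disparity tracks the scaled depth map", {
  dm <- make_face_like_depth_map(seed = 8)
  p <- render_rds(dm, stimulus_spec(snr = 1), seed = 3)
  sig <- p$dots[p$dots$role == "signal", ]
  scale <- 5.3 / max(abs(dm$values[dm$mask]))
  # analytic value: mean |scaled depth| over the grid cells dots can sample,
  # i.e. the oval target region inscribed in the grid (cells outside the
  # face's own crop carry zero depth and are included)
  grid_oval <- stereodepth:::oval_mask(nrow(dm$values), ncol(dm$values))
  analytic <- mean(abs(dm$values[grid_oval])) * scale
  expect_lt(abs(mean(abs(sig$disparity_arcmin)) - analytic) / analytic, 0.15)
})

test_that("feature-task pairs place reference and target peaks correctly", {
  # flat maximal surface: every signal dot sits exactly at the peak, so the
  # peak placement is checked without dot-sampling slack
  flat <- depth_map(matrix(1, 16, 16), matrix(TRUE, 16, 16))
  peak <- function(p) max(abs(p$dots$disparity_arcmin))
  fp <- render_feature_pair(flat, reference_disparity_arcmin = 7.8,
                            target_offset_arcsec = 120, seed = 1)
  expect_equal(peak(fp$reference), 7.8, tolerance = 1e-10)
  expect_equal(peak(fp$target), 7.8 + 2, tolerance = 1e-10)  # 120 arcsec = 2 arcmin
  # zero offset: identical peak disparities
  fp0 <- render_feature_pair(flat, target_offset_arcsec = 0, seed = 1)
  expect_equal(peak(fp0$reference), peak(fp0$target), tolerance = 1e-10)
  # structured surfaces: noise-free, all-crossed, peak bounded by the spec
  dm <- make_face_like_depth_map(seed = 5)
  fps <- render_feature_pair(dm, target_offset_arcsec = 120, seed = 1)
  for (p in fps) {
    expect_true(all(p$dots$role != "noise"))
    expect_true(all(p$dots$disparity_arcmin >= 0))
  }
  expect_lte(peak(fps$reference), 7.8 + 1e-10)
  # range limit: 150 arcsec accepted, 151 rejected
  expect_no_error(render_feature_pair(flat, target_offset_arcsec = 150, seed = 1))
  expect_error(render_feature_pair(flat, target_offset_arcsec = 151, seed = 1),
               "150")
})

test_that("exported stimuli round-trip through disk", {
  dm <- make_face_like_depth_map(seed = 5)
  pair <- render_rds(dm, stimulus_spec(snr = 0.8), seed = 4, pixels_per_degree = 20)
  dir <- withr::local_tempdir()
  paths <- export_stimulus(pair, file.path(dir, "stim"))
  expect_true(all(file.exists(paths)))
  sbs <- png::readPNG(paths[["side_by_side"]])
  expect_equal(dim(sbs), c(nrow(pair$left_image), 2 * ncol(pair$left_image)))
  # dot pixels (pure black/white) survive 8-bit quantization at exact positions
  expect_identical(which(sbs[, seq_len(ncol(pair$left_image))] == 1),
                   which(pair$left_image == 1))
  dots <- utils::read.csv(paths[["dots"]])
  expect_equal(dots$x_deg, pair$dots$x_deg, tolerance = 1e-12)
  expect_equal(dots$disparity_arcmin, pair$dots$disparity_arcmin, tolerance = 1e-12)
})

test_that("stimulus class wrapper produces the three experimental classes", {
  dm <- make_face_like_depth_map(seed = 2)
  up <- make_stimulus_class(dm, "upright")
  inv <- make_stimulus_class(dm, "inverted")
  rnd <- make_stimulus_class(dm, "random", seed = 9)
  expect_identical(up$values, dm$values)
  expect_identical(inv$values, invert_depth_map(dm)$values)
  expect_lt(max(abs(Mod(stats::fft(rnd$values)) -
                      Mod(stats::fft(dm$values * dm$mask)))) /
              max(Mod(stats::fft(dm$values))), 1e-9)
})
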