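---
title: "Models and methods behind stereodepth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind stereodepth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stereodepth)
```

stereodepth implements the computational machinery of a
psychophysics-plus-fMRI workflow on stereoscopic depth perception under
varying object context: disparity-defined random-dot stereograms of upright
faces, inverted faces, and depth-power-matched random surfaces; QUEST
adaptive threshold estimation; block-design GLM analysis; multivoxel
decoding with recursive feature elimination; and the behavioral and
brain-behavior statistics that tie the two levels together. Because face
databases, human observers, and scanners are not shippable, every stage has
a synthetic stand-in with known ground truth; this vignette explains the
models, the defaults, and what the synthetic results do and do not
establish.

## Stimulus synthesis

A stimulus starts from a **depth map**: a rectangular grid of relative depth
values with an oval mask marking the target region (`depth_map()`,
`read_depth_map()`). The three stimulus classes derive from one upright
map:

* **upright** — the map as given;
* **inverted** — the map rotated 180° in the picture plane
  (`invert_depth_map()`), which preserves the depth histogram and amplitude
  spectrum exactly while destroying the upright-face configuration;
* **random** — a phase-scrambled surface (`phase_randomize()`): the masked
  map is Fourier transformed, its phases are replaced with random phases,
  and the amplitude spectrum is retained exactly, so the surface has the
  same depth power at every spatial frequency but no structural coherence.

The random phases are taken as the phases of the Fourier transform of a
real white-noise field. That field's spectrum is Hermitian-symmetric by
construction (with DC and Nyquist phases of 0 or π), so the inverse
transform is exactly real — no imaginary residue needs to be discarded.
The mask is applied before the transform and the scrambled surface is used
unmasked inside the target region.

`render_rds()` turns a depth map into a **random-dot stereogram**. Defaults
follow the psychophysics display geometry: an 8.68° square stimulus, an
oval target of 6.45° × 4.55°, dots of 0.05° at 20 dots/deg², a maximum
target disparity of 5.3 arcmin (5.4 in the in-bore variant), and a
decorative background grid of 0.5° squares. Depth-to-disparity scaling is
linear, with the map's global absolute maximum mapping to the specified
maximum disparity. The signal-to-noise manipulation assigns an exact count
⌊snr · n_target⌋ of target dots (sampled without replacement) to carry the
surface's local disparity; the remaining target dots draw disparities
uniformly from the ± maximum range; surround dots sit on the fixation
plane. Exact-count assignment, rather than per-dot Bernoulli draws, keeps
the realized SNR constant across trials. Disparity is applied as a
symmetric ±d/2 horizontal shift of each eye's dot about the cyclopean
position (the standard stereogram convention), dots are positioned in
continuous degree coordinates and rasterized last, and dots shifted past
the stimulus edge wrap horizontally so dot count and density are preserved.
`render_feature_pair()` builds the fine-discrimination variant: two
noise-free surfaces, a reference peaking at 7.8 arcmin crossed and a target
offset by up to 150 arcsec.

Open choices made here: noise-dot disparities are drawn from a continuous
uniform distribution (a discrete set would also be consistent with the
description); the background grid is treated as purely decorative.

## Simulated observers and QUEST

The staircase machinery assumes a **Weibull psychometric function on log10
intensity**,

$$\psi(x) = \gamma + (1-\gamma-\lambda)\left(1 -
  e^{-10^{\beta (x - T + \epsilon)}}\right),$$

with defaults β = 3.5, γ = 0.5 (2-AFC guessing), λ = 0.01, and a criterion
of 82% correct. The offset ε is fixed so that ψ(T) equals the criterion:
the threshold parameter *is* the intensity at criterion. This anchoring is
the canonical QUEST parameterization and makes three contracts hold
simultaneously: a simulated observer probed at its own threshold performs
at 82%; the staircase's recommended intensity is the posterior's criterion
point; and the reported threshold estimate reads directly as a
criterion-level intensity. Without the offset, the threshold of the plain
Weibull sits at ≈ 81% under these defaults and those statements drift
apart.

`quest_create()` discretizes a Gaussian prior on the log10 threshold
(SD 2.0, centered on the initial test value) on a 201-point grid spanning
±3 prior SDs. `quest_update()` is the standard Bayes step; timeouts are
scored as incorrect. The estimate is the posterior mean (the QUEST+
convention); recommendations are clipped to the physical range ([0, 1] SNR
or [0, 150] arcsec). Intensities are handled in log10 units internally —
QUEST assumes a shift-invariant ψ on a log scale — and reported in linear
units.

A staircase (`run_staircase()`) is 4 practice + 60 test trials; the
posterior is carried over from practice, so the first test value is
determined by the practice-derived threshold. A session (`run_session()`)
is six runs — three conditions × two stimulus identities — each
interleaving two 64-trial staircases (one per stimulus gender) in strict
alternation; whether the original alternation was strict or random is not
documented, so strict was chosen for reproducibility. The per-condition
threshold is the mean of that condition's staircase estimates.

`derive_fmri_sampling_range()` implements the in-bore rule that tailors
scanner stimuli: the mean of the last 30 test values ± 1 SD, with a
fallback to a constant 80% SNR when the staircase is unreliable. The
reliability checks quantify two qualitative failure modes: lack of
asymptotic convergence is operationalized as an OLS slope of the last 30
test values exceeding 0.005 intensity units/trial in magnitude, and a
floored estimate as a 95% credible interval whose lower bound sits on the
posterior grid's minimum. "Test values" are taken post-clipping, since
those are the intensities actually presented.

## Synthetic fMRI

`make_run_design()` reproduces the block design: 12 stimulus blocks (six
types — 3 conditions × 2 genders — each exactly twice, order randomized
without further counterbalancing) interleaved with 13 fixation blocks,
bookended by fixation; 16 s per block; 8 trials per stimulus block with 4
"near" and 4 "far"; 96 trials per run; TR 2 s. The retained series is
25 × 16 s / 2 s = 200 volumes, consistent with 205 acquired minus 5
dummies.

`voxel_pattern_model()` defines the ground truth: every voxel responds to
stimulation with a baseline amplitude (1% signal change by default), and an
informative subset gets condition-specific amplitude offsets drawn with SD
`effect_size`. `simulate_timeseries()` builds each voxel's series as the
sum over conditions of the condition boxcar convolved with a two-gamma HRF,
scaled by the voxel's amplitude, plus a 100-unit baseline, optional linear
drift, and Gaussian noise (white by default, σ = 1 in percent-signal-change
units; AR(1) with ρ = 0.3 available). Motion nuisance series are smooth
random walks. Voxels live on a 3D grid at 2-mm pitch, matching the
acquisition voxel size, so searchlight geometry is realistic.

The number of runs per subject is not part of the documented protocol;
the generator defaults to 8 (consistent with a ~90-minute session including
localizers) and is configurable. What this generator does *not* emulate:
physiological noise structure, spatial autocorrelation, motion-correlated
artifacts, susceptibility distortions, and any retinotopic organisation —
so passing tests demonstrate the correctness of the analysis machinery on
its stated model, not robustness to real scanner physics.

## GLM

The HRF is the canonical double gamma. Gamma lobes are parameterized by
their mode — shape = delay/dispersion + 1, scale = dispersion — so the
positive lobe peaks exactly at the nominal 6 s and the undershoot at 16 s,
with a 6:1 peak:undershoot ratio; the kernel is normalized to unit peak.
The design matrix has exactly ten columns: three condition regressors
(genders pooled, 16-s boxcars convolved with the HRF), six motion
regressors, and a constant. High-pass filtering is available as a
discrete-cosine nuisance set (all cosines up to 3 cycles per run) appended
to the design rather than applied as a pre-filter — an equivalent
regression formulation that keeps the data untouched; it is off by default.

`fit_glm()` is ordinary least squares via QR, with an explicit error naming
collinear columns on rank deficiency. Percent signal change is computed as
100 · β / β_constant per voxel; the baseline convention is not documented
in the reference analysis, and constant-term normalization is the simplest
choice that makes the result invariant to overall signal gain. ROI analyses
fit the ROI-averaged time course (not voxelwise fits averaged afterward),
and multi-run inputs are fitted per run with betas averaged across runs.

## Multivoxel decoding

`prepare_patterns()` z-scores every voxel within run, shifts labels by 2
TRs (4 s) to absorb hemodynamic delay, keeps volumes inside shifted blocks
of the two target classes, and pools genders. Samples are individual
volumes carrying block ids — the resampling rule "without partition of
blocks" only has content if samples are finer than blocks. Zero-variance
voxels are removed with a warning (configurable to an error).

`rfe_decode()` is the decoding pipeline: leave-one-run-out folds; in each
elimination step the linear SVM (C = 1, no per-fold tuning; the solver is
libSVM via e1071) is trained on 20 resamples of 80% of the training
samples, each voxel's signed weight is averaged over the 20 resamples,
voxels are ranked by the absolute mean weight, and the five lowest are
eliminated (ties broken by voxel index; the final step is truncated so that
exactly `stop_size` voxels — 250 in the reference protocol — remain). After
each elimination the surviving pattern is retrained on the full training
set and scored on the held-out run; the final accuracy is the fold mean at
the stop size. Ranking by |mean signed weight| is the default reading of
"average weights"; mean of |weight| is available as an option.

A performance note: libSVM recomputes the linear kernel from raw features
on every call, which dominates the elimination loop's cost at realistic
voxel counts. Since the linear-SVM solution depends on the samples only
through their Gram matrix, each fit is run on a Cholesky factor of the
training Gram — identical kernel values, hence the identical libSVM
solution (the test suite verifies elimination sequences match a direct
implementation exactly) — and the Gram is downdated by rank-5 updates as
voxels are eliminated. This makes the full 800 → 250 elimination on a
400-sample dataset run in well under two minutes on one core.

`permutation_baseline()` permutes labels at the block level within run
(preserving run/block structure and class balance) and re-runs the
pipeline; the default summary is the 95th percentile of the null
distribution. The reference analysis reports a baseline of 0.53 whose
definition (null mean, percentile, or binomial cutoff) is not stated, so no
attempt is made to reproduce that number. Because a full elimination per
permutation is expensive, permutations default to a reduced pipeline (one
20-resample ranking pass selecting the top `stop_size` voxels per fold),
with `method = "full"` available.

`searchlight()` decodes a 6-mm-radius sphere around every voxel with
leave-one-run-out linear SVM and no feature elimination; on a 2-mm grid an
interior sphere contains exactly 123 voxels.

### What feature elimination does and does not guarantee

Simulations with planted informative voxels expose a real property of
SVM-RFE worth stating plainly. When a small set of voxels carries a shared
(redundant) discriminative signal, the margin optimizer spreads weight
across the set, and with strongly separable data few samples remain support
vectors — so the weight estimates for *uninformative* voxels, which are
chance combinations of those few support vectors, fluctuate at a magnitude
comparable to an individual informative voxel's share. Across elimination
steps this occasionally costs one or two members of a redundant informative
set while held-out accuracy stays at ceiling. Retention of the informative
set is therefore high but not guaranteed voxel-for-voxel; the package's
tests assert the regime-appropriate property (high recall with
above-threshold accuracy, and exact bookkeeping of the elimination
arithmetic) rather than a universally perfect recall that the algorithm
does not possess.

## Statistics

`rm_anova_oneway()` computes the one-way repeated-measures ANOVA by direct
sum-of-squares decomposition (SS_total = SS_subject + SS_condition +
SS_error), reporting F against the condition-by-subject error term,
uncorrected degrees of freedom (sphericity assumed, matching the reference
analysis convention), and partial η² = SS_cond / (SS_cond + SS_error). The
direct implementation exists because the calibration suite fits this model
tens of thousands of times; `stats::aov()` with `Error()` strata serves as
the independent cross-check in the tests and as the engine for the
multi-factor layouts (`rm_anova()` with e.g. hemisphere × condition × ROI).
`posthoc_bonferroni()` runs paired t tests with a family-size-3 Bonferroni
correction and Cohen's d = t/√n for paired designs. (Published in-bore
effect sizes reported for the in-bore replication do not follow this identity; their formula
is unknown and is not guessed.)

`behavioral_index()` is the per-subject threshold difference between two
conditions — or, for the upright-versus-non-upright analysis, between the
upright condition and the mean of the inverted and random conditions.
`correlate_brain_behavior()` reports Pearson's r with a two-sided p from
the t transform (df = n − 2) and a Bonferroni adjustment over the ROI
family (10 ROIs in the reference layout).

## The end-to-end pipeline

`run_full_pipeline()` chains every stage under a single seed: stimulus
synthesis → simulated staircase sessions (thresholds, ANOVA, post hocs, and
in-bore sampling ranges) → synthetic fMRI → GLM → the four decodings
(three pairwise and upright-vs-non-upright, with permutation baselines) →
brain-behavior correlations. Per-stage seeds derive deterministically from
the global seed, so any stage can be reproduced in isolation, and the
returned manifest records every seed and parameter; rerunning the same
config reproduces every number exactly.

Protocol constants (block structure, trial counts, criterion, shift,
resampling and elimination rules) are fixed at the reference values by the
stage functions. Problem *sizes* in the config default to desk scale —
6 subjects, 2 runs, 80 voxels, stop size 40, 100 permutations with the
reduced pipeline — chosen so the full chain runs in seconds-to-minutes on
one core while exercising every code path; study-scale sizes (22 subjects,
8 runs, 800 voxels, stop 250, 1000 permutations) are plain config values.

## Numerical choices and degenerate inputs

* Posterior underflow in QUEST (all mass lost) raises an explicit error
  rather than renormalizing garbage.
* The phase-randomized surface of an all-zero map is all-zero; rendering a
  blank depth map is an error (no disparity scale exists).
* Rank-deficient design matrices name the collinear columns.
* Paired t tests on zero-variance differences return t = 0 (identical
  vectors) or ±∞ (constant nonzero difference) rather than NaN.
* Elimination ties are broken by voxel index; eliminated sets are disjoint
  by construction.
* The Gram matrices used by the decoder carry a relative jitter of 1e-8 on
  the diagonal so Cholesky factorization succeeds when samples outnumber
  surviving voxels; the perturbation is ~1e-6 of a kernel entry and has no
  measurable effect on solutions (verified against direct fits).
* Test-suite and acceptance problem sizes (voxel counts, subject counts,
  simulation counts) are the package's own desk-scale choices, stated in
  the tests themselves.

## Known limitations

The synthetic generators are deliberately minimal: white/AR(1) noise,
no spatial correlation, no physiological confounds, simple Gaussian-bump
"faces". The statistics omit sphericity corrections by design (mirroring
the reference convention), and no observed-power computations are
provided. The package analyses tabular/matrix data; it does not read
scanner formats, and preprocessing (motion correction, normalization,
surface work) is out of scope.
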