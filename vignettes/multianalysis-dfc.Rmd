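---
title: "Multi-analysis dynamic functional connectivity: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-analysis dynamic functional connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the science it implements: the
seven dFC estimators, the comparison framework, the synthetic ground-truth
generator, and the numerical and design decisions behind them. Commands are
shown unevaluated; the README's worked example shows real output.

## 1. The estimation problem

Functional connectivity (FC) between two ROIs is classically a single
correlation over a whole scan. Dynamic FC asks how that coupling evolves
within the scan: the object of interest is a time-indexed sequence of
symmetric R×R matrices. Estimators differ in how they trade temporal
resolution against estimation noise, and in whether they assume a small set
of recurring group-level FC states. The package implements two state-free
estimators (SW, TF) and five state-based ones (CAP, SWC, CHMM, DHMM, WL)
behind one contract: state-based methods are fit once on all subjects'
concatenated data (`group fit`), then applied to each subject
(`subject apply`), producing a state time course and a dFC matrix in which
each time point carries its state's FC matrix.

## 2. Data model and preprocessing

Input is a parcellated BOLD matrix (rows = TRs, columns = ROIs in atlas
order) with a repetition time in seconds; the atlas table carries each ROI's
resting-state network (RSN) and hemisphere. Preprocessing mirrors standard
resting-state practice:

- `exclude_unassigned_rois()` drops parcels outside any network (the
  `"None"` label); a 333-parcel atlas with 47 unassigned parcels keeps 286.
- `select_uniform_rois()` reduces the parcellation (e.g. 286 → 96) with
  per-RSN quotas proportional to network size, split equally between
  hemispheres, taking evenly spaced index positions within each
  (RSN, hemisphere) block. Spatial coordinates are not part of the input,
  so index-uniform coverage stands in for spatially uniform coverage; the
  selection is fully deterministic. Largest-remainder apportionment of
  hemisphere pairs makes the total hit the target exactly when feasible.
- `highpass_filter()` is a 5th-order Butterworth applied forward and
  backward (zero phase), cutoff 0.01 Hz — the filter design is a package
  choice; the cutoff is the conventional resting-state drift bound.
- `z_standardize()` scales each ROI to mean 0, sd 1 using the *population*
  (1/T) variance. The convention is irrelevant to correlations but must be
  fixed for reproducible tests; idempotence holds to 1e-12.

## 3. State-free estimators

**Sliding window (SW).** The taper is the full discrete convolution of a
60-TR rectangle (44 s at TR = 0.72 s) with a Gaussian of σ = 3 TRs
truncated at ±3σ, so the effective support is W = 60 + 19 − 1 = 78 TRs.
This reading matters: stepped by 30 TRs, a 78-TR support yields exactly 38
fully contained windows on 1200 TRs, the standard grid all methods are
compared on (a plain 60-TR window would yield 39). The taper weights act as
observation weights in a weighted Pearson correlation; window time stamps
are window centers. Both the support convention and all window parameters
are configurable (`make_tapered_window()`).

**Time-frequency (TF).** Morlet CWT (ω₀ = 6) at `n_scales = 101` scales,
log-spaced so Fourier periods run from 2·TR to T·TR/4. Coherence is the
standard magnitude-squared WTC, `|S(W₁W₂*/s)|² / (S(|W₁|²/s)·S(|W₂|²/s))`,
with `S` a Gaussian time smoother of width equal to the scale followed by a
0.6-octave boxcar across scales. Whether coherence magnitude or its square
is averaged is an open convention; the package fixes magnitude-squared (the
textbook WTC definition) and exposes the scale-resolved field through
`wavelet_coherence_pair()`. The cone of influence uses the e-folding
distance √2·s: at each time point the coherence is averaged only over
admissible scales; the few edge points admitting no scale fall back to the
smallest (least edge-affected) scale rather than producing NaN. Values are
clipped to [0, 1]; identical inputs give exactly 1. Significance masking of
coherence is deliberately not applied — its role in scale-averaging is
unspecified in common practice, and unmasked averaging keeps the estimator
deterministic.

## 4. State-based estimators

All use K = 12 states by default (configurable; the package's synthetic
studies use K = 3).

**Two-stage k-means** (CAP, SWC): per-subject k-means with
`k_subject = 20` centroids, then k-means with `k_group = K` on the pooled
centroids, then nearest-centroid assignment of every original sample. Each
k-means uses k-means++ seeding with 10 restarts, keeping the lowest
within-cluster sum of squares; all randomness flows from one seed.
Subjects with fewer samples than `k_subject` use their sample count
(with a warning); duplicate samples that shrink a centroid set are padded
by repetition so the pooled size keeps its contract.

**CAP** clusters raw per-TR activity vectors (all frames, not
threshold-selected ones: the extended formulation clusters every time
point) and builds rank-1 state FC as centroid outer products. **SWC**
clusters the 38 per-window lower-triangle FC vectors; centroids are
devectorized with a unit diagonal (correlation convention — the diagonal is
not part of the feature vector).

**CHMM** fits a full-covariance Gaussian HMM by Baum–Welch with scaled
forward–backward recursions. Subjects are separate sequences: the initial
distribution applies at each subject's first TR and no transition is
counted across boundaries. Numerical choices: densities via Cholesky
factors; an escalating diagonal ridge (base 1e-6) whenever a factorization
fails; convergence at a relative log-likelihood change below 1e-6 (cap 100
iterations). EM is restarted from `n_restarts = 5` initializations and the
best final log-likelihood kept: the first restart initializes from k-means
on the frames (sensitive to mean structure), the rest from random
contiguous-segment covariance estimates. The segment scheme matters for
fMRI-like data — when states differ mainly in covariance, frame-space
k-means is nearly blind to them and, being almost deterministic at large N,
gives no diversity across restarts; contiguous segments are
covariance-informative because states persist in time. Decoding uses
Viterbi (a single hard state path is required downstream), not posterior
marginals.

**DHMM** reuses the clustering stage with
`n_obs = round(K · 16/24)` clusters (8 symbols at K = 12 — the ratio is
the stated convention; the product is the package's literal reading, and
`n_obs` is directly settable), feeds the window label sequences to a
categorical HMM (same EM machinery, restarts, and boundary handling), and
averages the clustering-stage dFC slices within each hidden state to form
state FC. A hidden state that attracts no window has no defined FC: it is
dropped with a warning, the states renumbered, and the drop recorded in the
fit metadata; such a fit refuses `apply_states()` on new subjects.

**WL** runs k-SVD with the hard one-atom-per-sample constraint: coding
assigns each frame to the atom maximizing |⟨d, x⟩| (coefficient = the inner
product); the update replaces each atom by the leading left singular vector
of its assigned frames, which jointly rewrites the coefficients, so the
squared reconstruction error is non-increasing — asserted per iteration in
the tests. Dead atoms reinitialize from the worst-represented sample. Atoms
are stored with their largest-magnitude element positive; the rank-1,
trace-1 state FC outer products are sign-invariant anyway.

## 5. Standardization and comparison

The common array is `dFC(subject, method, time, ROI, ROI)` on the 38-point
window grid. Per-TR methods are brought onto the grid by *nearest-TR
selection* (ties to the earlier TR), not averaging: averaging would blend
state FC matrices into patterns no state ever had, while nearest-TR
preserves the per-TR labels of CAP/CHMM/WL exactly. All similarity and
variance computations use the strict lower triangle (4560 connections at
R = 96) — the diagonal is method-dependent and carries no information.

Rank normalization (used for display and for the variance decomposition)
ranks all T′ × C values of one (subject, method) block *jointly* — exactly
the ranking a Spearman correlation of the flattened block would use — with
average ranks for ties, rescaled to [0, 1]. It is idempotent and invariant
to strictly monotone transforms.

Similarity levels follow the averaging order: within subject first (over
time for the spatial level, over connections for the temporal level), then
across subjects. Undefined correlations (zero-variance inputs — state-based
methods routinely produce flat connection time courses) become NaN,
are excluded from averages, and are counted in the result; they are never
imputed as 0. The mutual-information metric rank-transforms both vectors,
discretizes into 10 equal-frequency bins, and reports MI in bits
(identical vectors give log₂10 when the length divides evenly); it is an
intentionally simple estimator, adequate for commensurable method×method
comparisons rather than absolute MI values.

Method grouping converts similarity to distance (1 − r for correlations;
Euclidean distance used directly as the linkage distance — no ad-hoc
similarity transform; max(MI) − MI), applies Ward linkage (`ward.D2`, the
squared-distance Ward update), and cuts at 0.7 × the maximum merge height.
One degenerate case is handled explicitly: if every merge height ties (a
flat polytomy, e.g. an all-equal similarity matrix), no split is supported
and everything forms one group — a mechanical cut below the tied height
would return only singletons.

The variance decomposition rank-normalizes each (subject, method) block,
then compares `var_method` (variance over the 7 methods, averaged over
time) to `var_time` (variance over the 38 time points, averaged over
methods) per subject and connection, and to `var_subj` (variance over
subjects, averaged over time and method) per connection. Sample (n−1)
variances are used throughout so that the exchangeability null — methods as
independent permutations of one value multiset — gives an expected ratio of
1 (sampling without replacement leaves the unbiased variance estimate
unchanged). Ratios with a zero denominator are excluded from summary means.
The RSN-pair map averages the variances over all connections linking a
network pair *before* forming `ratio − 1`, so 0 means equal method- and
time-variability for that pair. The time-shuffled null permutes the time
axis independently per (subject, method) — a pure time permutation, so
fractional occupancy is preserved exactly — and reports one-sided
(≥ observed) p-values with the add-one convention.

## 6. The synthetic ground truth

`generate_markov_bold()` emulates the shape of a large resting-state
study: multi-subject, T = 1200 TRs at TR = 0.72 s, ROIs tagged with RSN
and hemisphere labels. A K-state Markov chain (default K = 3,
self-transition 0.95 ≈ 14 s mean dwell) starts from its stationary
distribution; each TR draws from the active state's Gaussian. The default
states differ purely in covariance: three mutually near-orthogonal block
partitions (contiguous, interleaved, and a Latin-square mix; within-block
r = 0.8), whose pairwise lower-triangle correlations stay below 0.15 in
magnitude — "well-separated" in exactly the sense the state-based
estimators need. A first-order variant (`synthetic_spec_activation()`)
plants mean-activity patterns instead — K unit sign-vector patterns at
equal angles in an orthogonal plane (amplitude 3, identity covariance), so
they sum to ~0 and survive z-standardization — because CAP and WL are
first-order methods and see means, not covariances.
`generate_stationary_bold()` is the K = 1 null; `make_method_group_fixture()`
plants a {3, 2, 2} block structure across 7 pseudo-methods (shared latent
dFC per block + independent noise) for end-to-end grouping tests.

What the generator does *not* emulate: hemodynamics (no HRF convolution or
balloon model), physiological noise (respiration, cardiac), motion, scanner
drift, or spatial autocorrelation beyond the planted blocks. Passing the
recovery tests therefore shows the estimators are correct under their own
generative assumptions — it does not certify behaviour under real-data
confounds, where dwell times, SNR, and noise spectra are less friendly.

## 7. Validation design and problem sizes

The test suite works at a deliberate scale — R = 12 ROIs in 3 RSNs,
10 subjects, T = 1200 for the recovery studies; smaller for unit tests —
chosen so the full seven-method pipeline runs on a desktop while exercising
every code path; full-scale dimensions (96 ROIs, 395 subjects) appear only
in structural quantities (vectorization lengths, assembly manifests) that
cost nothing to verify. Key oracles: brute-force per-segment Pearson for
the rectangular window; the stationary eigenvector of the transition matrix
for fractional occupancy; analytic block-covariance eigenvalues; exhaustive
Hungarian matching (exact for K ≤ 9) before any recovery score.

Two harness definitions deserve note. First, the ground-truth label of a
*window* is the planted state with the largest taper-weighted occupancy in
that window — the taper defines each TR's contribution to the window
estimate, and the rectangle reduces this to plain majority. Because the
default dwell (~20 TRs) is much shorter than the 78-TR window support,
windows are intrinsically mixtures and window-label accuracy is bounded
below 1 by construction; per-TR methods (CHMM) are scored against per-TR
truth. Second, on single-regime data an overparameterized Gaussian HMM
retains a genuine soft split of the one Gaussian, so individual state
covariances need not approximate the sample covariance closely; the sound
invariant — asserted in the tests — is the law of total covariance: the
occupancy-weighted mixture second moment reproduces it.

## 8. Known limitations

- The wavelet coherence smoother (Gaussian in time, boxcar across scales)
  follows common cross-wavelet practice but is one of several defensible
  kernels; coherence values depend quantitatively on it.
- The HMM fits are EM with restarts, not variational or exact inference;
  with K = 12 and short data, label switching and empty states are
  expected, and the DHMM drops empty states rather than resampling them.
- The MI metric's fixed equal-frequency binning is biased for short
  vectors (it warns below bins²).
- `select_uniform_rois()` is index-uniform, not spatially uniform; with an
  atlas whose within-RSN ordering is not spatially meaningful, "uniform
  coverage" degrades to a deterministic thinning.
- The on-disk dFC array container is a single serialized RDS file: simple,
  lossless, and self-describing within R, but not language-neutral.
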