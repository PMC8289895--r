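---
title: "Coordination complexity, CCA fusion, and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coordination complexity, CCA fusion, and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement model

`coordcca` quantifies how *coordinated* a multichannel physiological signal
is. Given an M-channel, uniformly sampled series, each channel is
time-delay-embedded into N = 15 shifted copies at a per-modality delay
spacing (0.5 s for gaze, 0.03 s for formant and delta-formant tracks, 2 s
for fMRI ROI series), and the Pearson correlation matrix of the resulting
M·N rows is computed over their common support. The rank-ordered
eigenspectrum of this channel-delay correlation matrix is the feature
vector of a session. If most variance concentrates in a few leading
eigenvalues, few modes explain the signal — low complexity. Weight spread
into the small (tail) eigenvalues means many modes are needed — high
complexity. Because every embedded row is standardized before correlation,
the spectrum is invariant to per-channel affine rescaling and to channel
order, and its sum always equals M·N (trace conservation) — both properties
are asserted in the test suite.

Delay offsets run 0, 1, ..., N−1 times the spacing. Including the zero
delay makes the aligned diagonal of every within-channel block exactly one
and keeps the block structure interpretable; delays could equally start at
one spacing, which would only drop one row per channel.

Three signal families are handled:

* **Smooth-pursuit gaze** (x, y at 1000 Hz). Blinks are detected where the
  sensor reports no value or where |Δx + Δy| exceeds 100 units per sample
  (backward difference on the raw coordinates). Maximal blink-free runs are
  trimmed by a 50 ms guard on any side adjacent to a blink — recording
  start and end are not blinks and get no guard — and kept if at least
  10 s long. Retained segments are smoothed with a unit-gain Gaussian
  kernel (σ = 21 ms, truncated at ±4σ, renormalized at the edges so no
  data is invented at blink boundaries); smoothing is applied strictly
  within segments, never across gaps. Eigenspectra are computed per 10-s
  frame with 5 s overlap, tiling each segment from its start (trailing
  partial frames are dropped), and averaged rank-by-rank across frames.
  Frames containing a constant channel are skipped and counted rather than
  failing the session; sessions with no usable frame are excluded, as
  happens to real sessions with no long between-blink interval.
* **Formant tracks** (three vocal-tract resonances at 100 Hz) and their
  discrete-time derivatives (delta-formants; one sample shorter, no
  extrapolation). One matrix and spectrum per whole recording.
* **fMRI ROI series** (21 subcortical + 48 cortical channels at 0.5 Hz).
  One spectrum per whole scan and ROI set, plus per-channel raw variances
  as summary features (no z-scoring at this stage; standardization happens
  inside the model).

The derivative threshold of 100 is expressed in input coordinate units per
sample at the native grid and is configurable, since its units depend on
the tracker calibration. Target-off gaps of the pursuit task are not
excised; frames may span them.

## The prediction model

Per feature set, session feature vectors are z-scored (so all dimensions
weigh equally) and reduced by PCA; the six composite scores (with reaction
time inverted to reaction speed so all loaded composites point the same
way) are likewise z-scored and reduced, to `m_Y` components (default 1 —
the latent cognitive factor). A CCA between the fused (concatenated)
feature PCs and the outcome PCs yields maximally correlated latent
variables U and V; prediction uses the training-fold least-squares
regression of V on U, then inverts the outcome-side CCA (pseudo-inverse of
B) and PCA maps back to composite space. With `m_Y = 1` the whole outcome
chain is scalar.

CCA is implemented by whitening both covariances (eigendecomposition with
a 1e-8 ridge on the diagonals for numerical rank safety) and an SVD of the
whitened cross-covariance; the first canonical pair is non-negatively
correlated on the training data by construction, and column signs are fixed
deterministically. The ridge makes the 1-D special case agree with the
Pearson correlation to about 1e-8 rather than machine epsilon — a deliberate
trade for stable behaviour near rank deficiency.

**Cross-validation.** Generalization is estimated by nested
leave-one-subject-out (LOSO) cross-validation: the outer loop holds out all
sessions of one subject; within each training fold an inner LOSO over the
remaining subjects selects each feature set's PCA dimensionality from
candidates 1–7 (the cap that explains ≥90% of feature variance in data of
this kind), maximizing the Spearman correlation of inner-test U and V
pooled over inner folds, with `m_Y` fixed at 1 during selection; ties break
to the smallest dimensionality. All statistics — means, SDs, PCA axes, CCA
maps, selected dimensionalities — come from training rows only and are
applied frozen to the held-out subject; a poisoning test in the suite
verifies bit-identical training fits when the held-out subject's data is
replaced by NaN. Out-of-sample U and V (V built from the held-out subject's
*true* composites through training-side maps) are pooled over folds and
summarized by Spearman correlations with t-approximation p-values; both V
and the predicted composites are reported, since either could be taken as
"the" out-of-sample target.

**Within-subject change.** A single global model (no CV), using the modal
per-fold dimensionalities from the CV run (ties to the smallest), produces
U and V for every session; successive-session differences dU, dV within
subject are correlated, and a Thorndike Case II range-restriction
adjustment with K = sd(U)/sd(dU) is reported alongside, because change
scores can have narrower range than session scores. The sample SD of U
serves as the unrestricted reference; the correction returns r unchanged at
K = 1.

## The synthetic cohort

Real cohorts of this kind are restricted-access, so the package ships a
generator that reproduces the *statistical structure* the analysis
assumes, not the physiology. A per-session latent cognition score
z = subject trait (standard normal) + within-subject drift (SD 0.3) drives:

* gaze: a circular pursuit trajectory (35 cycles over 122.5 s, radius 300
  screen units) plus autocorrelated jitter whose amplitude falls with z
  (more precise tracking at higher cognition), with Poisson-placed blink
  gaps (4/min, 100–300 ms) marked as missing samples;
* formants: three band-limited tracks around 500/1500/2500 Hz whose fast
  component grows with z (more high-frequency articulatory fluctuation);
* fMRI: channels mixing three shared AR(1) factors with idiosyncratic
  AR(1) noise, the idiosyncratic weight rising with z on a logistic scale
  (higher effective dimensionality); the session-wide subcortical — but not
  cortical — amplitude also rises weakly with z, so subcortical variance
  features carry signal and cortical ones do not;
* composites: the four cognition-linked scores load equally on z with
  independent noise (SD 0.8 on the standardized scale); impulse control and
  total symptoms are pure noise; reaction time is emitted as the
  reciprocal of the underlying speed score, forcing the pipeline to apply
  the reciprocal itself.

Each complexity dial is a strictly monotone, deterministic function of z
(`planted_complexity_params()`), perturbed per session by a log/logit-scale
nuisance draw representing cognition-unrelated state (fatigue, recording
conditions). The nuisance SDs (0.5 gaze, 0.6 formant, 0.8 fMRI, 0.2
amplitude) were calibrated once so that single-modality out-of-sample
correlations land in the moderate range typical of human multimodal
cohorts (roughly 0.2–0.6) instead of saturating near 1, and were then
frozen; fusing modalities, whose nuisances are independent, then yields the
characteristic gain of multimodal fusion. The default cohort has 28
subjects and 68 sessions under monotone attrition
(5,5,4,4,4, 3×7, 2×9, 1×7), giving 40 successive-session pairs from 21
multi-session subjects. Ground-truth z is returned separately from the
pipeline-visible data and is used only by recovery tests.

What the generator does **not** emulate: saccades and catch-up eye
movements, head motion, acoustic phonetics (the formant tracks are generic
band-limited processes), hemodynamics or spatial ROI structure, practice
effects on composites, floor/ceiling effects, and group differences.
Passing tests therefore demonstrate that the pipeline recovers a planted
latent link under realistic noise, dropout and attrition — not that any
particular physiological claim holds in real data.

## Numerical choices and degenerate inputs

* Eigenvalues come from a symmetric solver; when the embedded dimension
  exceeds the common support the nonzero spectrum is computed from the
  (smaller) Gram matrix of the standardized rows and padded with exact
  zeros — algebraically identical, asserted in tests. Tiny negative
  eigenvalues are clamped to zero; descending sort with stable ties.
* Zero-variance feature columns (e.g. the exactly-zero tail ranks of the
  cortical spectrum, whose count is fixed by the scan length) are centered
  and left unscaled by the PCA z-scoring, contributing nothing.
* Constant embedded channels raise a typed degenerate-window condition;
  framewise analysis skips and counts such frames.
* The Spearman p-value uses the t approximation; at |r| = 1 it is 0.
* Candidate dimensionalities exceeding an inner fold's feasible rank are
  capped within that fold rather than failing the fold.
* Blink spans drawn overlapping are merged before use, so the planted
  blink bookkeeping is canonical.

## Problem sizes used by the packaged checks

The test suite exercises full-scale cohorts (28 subjects / 68 sessions,
native sampling rates) for the seeded recovery checks — 20 planted and 20
matched null cohorts at seeds 1–20 — and shortened recordings (full channel
counts, 12-session cohorts) for the structural and leakage tests. The
acceptance script replicates the pipeline on five planted and five null
cohorts derived from its `--seed` argument; medians over those replicates
are what it reports. These sizes keep a complete run in the tens of
minutes on one CPU while leaving every stage at its native dimensionality.

## Known limitations

* CCA is linear; nonlinear or regularized (sparse) variants are out of
  scope, as are graph-theoretic connectivity measures.
* The unrestricted SD in the range-restriction adjustment is the sample SD
  of U, not a population value; with K near 1 the adjustment is minor.
* With `m_Y = 1`, predictions of all six composites are collinear by
  construction (a line through the composite-space mean); the `m_Y` sweep
  (`sweep_impact_dims()`) explores richer outcome spaces at the cost of
  noisier canonical directions.
* The latent factor is fitted on pooled sessions when used descriptively;
  inside cross-validation the outcome side is always refitted per training
  fold, so the two uses can differ slightly in loading.
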