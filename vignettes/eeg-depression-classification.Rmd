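---
title: "Multidimensional EEG features for depressive-disorder classification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multidimensional EEG features for depressive-disorder classification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegClassify)
```

## Overview

`eegClassify` implements a feature-based pipeline for separating
depressive-disorder (DD) patients from healthy controls (HC) using
resting-state EEG. The pipeline is: preprocessing (bandpass, downsample,
baseline correction, fixed-window segmentation), extraction of three
feature families per epoch — band power spectral density (PSD), sample
entropy (SE) and phase lag index (PLI) — minority-class oversampling
inside training folds, SVM-RFE feature ranking with cross-fold rank
aggregation and incremental forward inclusion, and strict
leave-one-subject-out (LOSO) evaluation with pooled confusion metrics.
A synthetic cohort generator with plantable group effects provides ground
truth for calibration and recovery studies.

## Preprocessing

Recordings (16 channels of the 10-20 system, 250 Hz) pass through a fixed
chain:

1. **Broadband bandpass 4-30 Hz**, 4th-order Butterworth applied
   forward-backward (`signal::filtfilt`). Zero-phase application is a
   deliberate choice: a causal filter would add a frequency-dependent phase
   delay that biases PLI estimates. The price is an effective magnitude
   roll-off of twice the design order, which we accept.
2. **Downsampling 250 to 125 Hz** by keeping every second sample. No extra
   anti-alias filter is applied: the preceding 4-30 Hz bandpass already
   confines energy far below the new 62.5 Hz Nyquist. The decimated rate
   must keep Nyquist above the 30 Hz beta edge; the constructor rejects
   anything else.
3. **Baseline correction** (per-channel mean subtraction).
4. **Segmentation** into non-overlapping windows of 4, 6, 8, 10 or 12 s,
   cut from the start; a trailing remainder is discarded. Windows do not
   overlap: overlap would multiply epoch counts without adding subjects,
   inflating apparent sample size under LOSO.

Per-band rhythm extraction (theta 4-8, alpha1 8-10, alpha2 10-13, beta
13-30 Hz) happens at the epoch level, with the same 4th-order zero-phase
Butterworth design, immediately before feature computation. Filtering the
continuous recording first and segmenting afterwards means the broadband
stage introduces no per-epoch edge transients; the short per-band epoch
filters do have edge effects, which is one reason the PLI estimator trims
epoch edges (below).

## Feature families

For 16 channels and 4 bands the canonical feature universe is
64 PSD + 64 SE + 480 PLI = 608 named columns, ordered PSD block, SE block,
PLI block; bands in canonical order inside each block; channels and pairs
in montage order. Names are `FAMILY_band_channel` (e.g. `PSD_beta_F3`) or
`FAMILY_band_chA-chB` (e.g. `PLI_alpha2_F3-P3`).

**Band PSD.** The plain rectangular-window periodogram
$P_x(f) = |X(f)|^2 / N$ averaged over the discrete frequency bins inside
the band (edges inclusive), i.e. the discrete version of the
band-normalised integral. No taper or segment averaging is applied — the
estimator is intentionally the textbook periodogram; tests pin it down via
the Parseval identity and pure-tone fixtures.

**Sample entropy.** $-\ln(A/B)$ where $B$ counts template pairs of length
$m = 2$ within Chebyshev distance $r = 0.15 \cdot SD$ and $A$ the same
pairs still matching at length $m + 1$ (Richman–Moorman convention:
templates $i = 1..N-m$ for both lengths, self-matches excluded, strict
$< r$). Because $r$ scales with the SD of the input, SE is scale-invariant,
which the tests assert to $10^{-9}$. SE is computed per band-limited
channel signal, giving the 16 x 4 = 64 SE features the feature-count
bookkeeping requires. A constant signal (SD = 0) is a degenerate-input
error, never a silent 0; if no template pair matches at length $m+1$ the
estimator returns `Inf` and the matrix builder raises an error with
epoch/channel context. The counting kernel is C++ (direct $O(N^2)$
matching); an independent naive R implementation serves as the test
oracle, with exact equality required.

**Phase lag index.** Analytic signals via the FFT half-spectrum Hilbert
method, phase difference $\Delta\phi(t) = \arg(z_1 \bar z_2)$, and
$PLI = |\langle \mathrm{sign}\,\Delta\phi\rangle|$. The estimator is
symmetric, bounded in $[0,1]$, amplitude-invariant, and blind to zero-lag
(volume-conduction-like) synchrony since $\mathrm{sign}(0) = 0$
contributes nothing. 10% of samples at each epoch edge are excluded from
the average: Hilbert phases are unreliable where the implicit periodic
extension wraps. All 120 unordered channel pairs are evaluated per band.

## Synthetic cohort generator

Because no public recording set accompanies the method, the package ships
a generator whose defaults mirror the clinical study design: 70 DD and
30 HC subjects, 16 channels, 250 Hz. Recording duration is 60 s per
subject — a free choice (the protocol does not fix it) made so that every
window length from 4 to 12 s yields at least 5 epochs per subject.

Each channel is the sum of

* 1/f-shaped background noise (spectral shaping of white noise; flat below
  1 Hz), the standard first-order description of resting EEG spectra;
* band-limited oscillations in the four bands with an alpha-dominant,
  eyes-closed-like amplitude profile (theta 0.4, alpha1 0.6, alpha2 0.6,
  beta 0.35 relative to unit background SD).

Three group effects can be planted for DD subjects:

* **Beta power** (`betaPowerEffect`, default 1.5): multiplies the DD beta
  oscillation amplitude. Its PSD footprint grows monotonically with the
  multiplier (property-tested over a grid).
* **Complexity** (`complexityEffect`, default 0.2): replaces that fraction
  of each channel's variance with a deterministic periodic waveform
  (harmonics at 6, 18 and 24 Hz), lowering sample entropy. The harmonics
  deliberately avoid the alpha bands so this zero-lag common component
  cannot mask the planted phase coupling.
* **Phase coupling** (`couplingEffect`, default 0.5): for each (disjoint)
  coupled channel pair, a shared narrowband source in the coupling band
  (default alpha2, 10-13 Hz) is mixed into the two channels with a fixed
  phase lag (default $\pi/2$, applied exactly via the source's analytic
  signal). The mixing is *band-limited*: only the channels' coupling-band
  content is partially replaced, leaving the band-power profile
  essentially unchanged, so the planted effect is genuinely a phase
  effect. An earlier whole-channel mixing design was rejected because it
  concentrated channel variance into the narrow coupling band and leaked a
  large unintended PSD signature.

Per-subject seeds are derived deterministically from the master seed, so a
cohort is reproducible bit-for-bit while subjects remain independent. The
generator does not model ocular/muscle artifacts, scalp topography or
volume conduction; passing tests therefore demonstrate correct recovery of
the planted statistical structure, not robustness to real-world artifacts
(the ICA stage real data would need is out of scope here).

`plantedFeatureSet()` bypasses signal generation entirely and simulates an
epoch-level feature matrix with a known informative subset (group mean
shift in within-subject SD units, plus a per-subject random intercept so
LOSO structure is respected). It is used where feature *selection* — not
signal processing — is under test.

## Class balancing

Clinical cohorts are imbalanced (70:30 here), so training folds are
rebalanced by SMOTE-style interpolation: for each minority sample, draw
one of its $k = 5$ nearest minority neighbours (Euclidean distance on
z-scored features — raw PSD magnitudes would otherwise dominate), draw
$\lambda \sim U[0,1]$, and append $X_i + \lambda (X_{nn} - X_i)$.
`N = "auto"` synthesises exactly enough rows to equalise counts. Three
design points:

* The balancing runs **inside each LOSO training fold only**. Oversampling
  before the split would plant interpolated copies of test-subject
  structure in the training set — subject-level leakage.
* The minority class is inferred from fold label counts, not hard-coded.
* An optional pre-step removes majority samples whose nearest neighbour is
  a minority sample (Tomek-style cleaning). It defaults to OFF because the
  balancing procedure's specified steps contain no purification algorithm;
  the hook exists for users who want the described-but-unspecified
  behaviour.

Synthetic rows carry a `synth_<parent>_<i>` subject tag and a logical
flag, so they can never be mistaken for real epochs downstream.

## Evaluation protocol

LOSO, strictly: all epochs of one subject form the test fold; the z-score
scaler and the oversampler are fit on the remaining subjects' epochs only.
Per-fold predictions are pooled into a single confusion matrix before any
metric is computed (prediction pooling), with DD the positive class —
chosen because detecting patients is the clinically costly direction; the
per-report header states this. Accuracy, precision, recall and F1 follow
the usual confusion-matrix formulas; undefined ratios (zero denominators)
surface as `NA` with a warning, never as silent zeros. The 95% CI for
accuracy uses the binomial normal approximation
$\hat p \pm 1.96 \sqrt{\hat p(1-\hat p)/n}$, clipped to $[0, 100]$%.
AUC is computed (via pROC) on pooled decision scores — signed
hyperplane distance for the SVM, class probabilities otherwise —
extending the pooling convention to scores. Per-subject accuracies (the
fraction of a subject's epochs classified correctly) are reported
alongside; their epoch-weighted mean equals pooled accuracy, an identity
the tests check on random predictions.

Classifier configurations are fixed, not tuned: SVM with RBF kernel,
$C = 1$, $\gamma = 1/(n_{feat} \cdot \sigma^2)$ (variance-adaptive); KNN
with $k = 5$ uniform votes; random forest with 100 trees (Gini); XGBoost
with 100 rounds at learning rate 0.1. LightGBM and CatBoost are accepted
as configuration kinds but have no backend in this package and fail
loudly at fit time.

### Below-chance accuracy on null data

On cohorts with *no* planted effects, pooled LOSO accuracy lands far
*below* 50% — often near 0 at small cohort sizes. This is the documented
anti-learning pathology of leave-one-subject-out designs: each subject
forms a tight cluster in feature space; removing a subject shifts its own
class's training distribution away from it, and the margin consistently
places the held-out cluster on the wrong side. Class balancing removes the
majority-vote component of this bias but not the geometric component. The
correct chance reference for this design is therefore the *permutation*
band (re-running the full fold loop under subject-level label shuffles),
not a nominal 50%; the calibration tests assert that the observed null
accuracy falls inside the 95% band of 50 shuffles, and they do so on a
10 + 10-subject cohort because the accuracy grid of smaller cohorts is too
coarse for stable quantiles.

## Feature selection

**Per-fold ranking.** SVM-RFE with a *linear* kernel: fit, remove the
feature with the smallest $|w|$, repeat; elimination order defines the
ranking (last survivor = rank 1, step 1 by default). The linear kernel is
required — margin weight magnitudes are undefined for the RBF kernel used
in classification; this is standard SVM-RFE practice. One ranking is
produced per LOSO iteration (100 iterations for a 100-subject cohort;
generally one per subject), each seeing only its training fold. Ties in
$|w|$ eliminate the lower column index first, so exact duplicates occupy
adjacent worst ranks — a documented, deterministic rule.

**Aggregation.** Two rules are provided because the method is described
both ways in different places:

* `modal` (default): position $p$ of the global order takes the
  not-yet-selected feature occurring most often within rank positions
  $1..p$ across iterations; ties break by smaller rank sum, then smaller
  index.
* `ranksum`: features sorted by ascending column-wise rank sum, ties by
  index.

Both return permutations and agree exactly on unanimous ranking matrices
(property-tested); when they disagree the divergence is visible to the
caller rather than hidden behind a single rule.

**Forward inclusion.** For prefix sizes $s = 1..n$ (optionally capped and
strided for large $n$; the cap is always evaluated), the full LOSO
evaluation runs on the top-$s$ features; the optimum is the smallest
prefix attaining the maximal pooled accuracy. Every evaluation inside the
curve is a complete, leakage-free LOSO run.

## Problem sizes used in the shipped checks

The test-suite and acceptance-script cohorts are sized for a desk-scale
study while preserving the protocol: planted-effect discrimination uses
8 + 8 subjects x 60 s (96 epochs at the 10-s window), null calibration
10 + 10 subjects with 50 label shuffles, and selection recovery ten
20-subject feature-level cohorts with 5 informative + 45 noise features.
With the default generator settings these sizes give reproducible,
seed-stable outcomes for every check the package makes.

## Known limitations

* The generator's group effects are stylised (stationary narrowband
  sources, deterministic complexity component); it validates the
  pipeline's statistical machinery, not clinical performance.
* Sample entropy at long epochs is $O(N^2)$ per channel and band; the C++
  kernel keeps the default problem sizes comfortable, but very long
  windows scale quadratically.
* Headline accuracies from the motivating clinical study (94.48% at
  153 features, and the per-window accuracy tables) were obtained on a
  non-deposited 100-subject clinical cohort and are not reproducible from
  synthetic data; the package's checks therefore target structural
  counts, estimator oracles and planted-effect recovery instead.
* Only SVM, KNN, RF and XGBoost backends are available; LGBM/CAT kinds
  are recognised but unimplemented.
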