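---
title: "Hybrid source-space brain networks from concurrent EEG-fNIRS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid source-space brain networks from concurrent EEG-fNIRS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

hbnet builds classification features for emotion recognition from two
complementary network views of concurrent EEG-fNIRS recordings, both
expressed in cortical source space: a directed *causal* network among
parcellated EEG source signals, and a *neurovascular coupling* network
linking each source region to each fNIRS channel. This vignette explains the
models, the assumptions behind them, the parameters that matter, what the
bundled simulator does and does not emulate, and the numerical choices the
implementation makes.

## The model, stage by stage

**Source localization.** Scalp EEG follows the linear forward model
`X = L J + noise`, where `L` (electrodes x dipoles) is the lead field. The
inverse problem is solved with the minimum norm estimate,

```
J = L' (L L' + alpha^-1 I)^-1 X,
```

i.e. Tikhonov regularization with an identity source prior. Dipole series
are then averaged within each atlas region ("parcellation") to give one
source signal per region, at the full EEG time resolution. The package does
not build head models: `L` and the dipole-to-region membership are inputs
(exported from standard neuroimaging toolchains, or synthetic). Any atlas
size is accepted; a DKT-style parcellation of the cortex yields 62 regions,
while the bundled simulator defaults to 8.

`alpha` is nowhere fixed by the method's description, so the default anchors
it to the data scale: `alpha^-1 = trace(L L') / u / SNR^2` with an assumed
amplitude SNR of 3, the conventional regularization strength for evoked
data. It is config-overridable (`inverse_alpha`).

**Causal networks.** Source signals are cut into 3 s windows advanced by
1.5 s, each window is linearly detrended (Granger analysis assumes weak
stationarity), and every ordered pair of regions is scored with bivariate
Granger causality: the log ratio of residual variances between an
autoregression of the target on its own `p` lags and the same regression
augmented with `p` lags of the driver. Both models are fit by OLS on the
same `r - p` target points, so the statistic is nonnegative by construction.
The per-window order `p` is chosen once per window by BIC pooled over all
pairs (default search up to `p_max = 10`), not per pair; a single shared
order keeps the `c(c-1)` fits coherent and the cost linear in `p_max`. The
diagonal of the causal matrix is fixed at zero: self-causality is undefined
under the bivariate model. Raw statistics are kept as features; no
significance thresholding is applied.

Under the null of independent Gaussian series the likelihood-ratio statistic
`(r - p) * F` is asymptotically chi-square with `p` degrees of freedom; the
test suite checks the empirical 95th percentile against this reference.

**Coupling networks.** Neurovascular coupling links regional neural activity
to local hemodynamics. Each source signal's activity is summarized by its
normalized time-varying band power: a Hann-window STFT (1 s window, 0.1 s
hop), power summed over 0.5-45 Hz per frame, min-max normalized to [0, 1]
per trial, and linearly interpolated from frame centers back onto the
sample grid. That envelope, convolved with the canonical double-gamma HRF
`g(t, 6) - g(t, 16)/16` (32 s support, samples scaled by dt so the result is
sampling-rate invariant, truncated to the first n samples), is the predicted
fNIRS contribution of that region. The c predicted series form the design
matrix of a general linear model fit to the measured (HbO) fNIRS window by
least squares; the coupling strength is the absolute value of each
coefficient. Prediction and normalization happen on the whole trial before
segmentation, then predicted and measured streams are segmented identically
and one GLM is fit per window.

Choices the method description leaves open, fixed here once: STFT window
1 s/hop 0.1 s (resolves the EEG band while tracking second-scale power
changes typical of video stimuli); min-max normalization per trial, with an
exactly-degenerate rule mapping an effectively constant envelope
(relative range below 1e-8) to all zeros rather than amplifying machine
noise; no intercept or drift regressors in the design (measured fNIRS is
band-passed to 0.01-0.2 Hz and baseline-corrected upstream, which removes
DC); all-zero design columns are dropped with a warning and reported as
zero coefficients; a rank-deficient design falls back to the minimum-norm
pseudoinverse.

**Hybrid features and evaluation.** Per window, the `c x c` causal matrix
and the `c x d` coupling matrix are concatenated column-wise into a
`c x (c+d)` hybrid network and flattened row-major into a feature vector
(`SG`, `SC` and `SG_SC` denote causal-only, coupling-only and hybrid
feature kinds). Evaluation is stratified 5-fold cross-validation repeated 5
times with reseeded folds, using a linear-kernel SVM (C = 1) and a
10-nearest-neighbor classifier; features are z-scored with training-fold
statistics only. Fold assignment is at the window level by default, which
replicates the protocol the networks are built for but lets the 1.5 s
window overlap leak information between folds; `fold_unit = "trial"` is
provided for leakage-free estimates and gives systematically lower
accuracies.

## The synthetic study

The simulator stands in for a request-only concurrent EEG-fNIRS emotion
corpus and generates one subject's labeled study:

* sources: a stable VAR whose lag-k coefficient matrix is the class
  adjacency scaled by `0.6^(k-1)`, Gaussian innovations (sd 1), 500 burn-in
  samples discarded so retained segments are stationary;
* EEG: every dipole carries its region's series, mixed through a random
  Gaussian lead field (16 electrodes, 24 dipoles over 8 regions by
  default), plus sensor noise (sd 0.5);
* fNIRS: HRF-convolved normalized source power mixed by a nonnegative
  coupling-weight matrix exactly as the coupling module computes it, plus
  per-channel noise at 10 dB SNR (noise sd defined against the demeaned
  clean channel: constant offsets are not signal power), stored at 11 Hz;
* classes: 4 classes x 15 trials of 30 s. Class identity perturbs both the
  adjacency (rectified Gaussian on off-diagonal entries, sd
  `0.2 x effect_size`) and the coupling weights (sd `0.3 x effect_size`),
  with templates rescaled to companion spectral radius at most 0.9;
  `effect_size = 0` yields a null dataset with identical classes.

Defaults were chosen once as a realistic desk-scale emulation: 30 s
approximates a segment of a 1-2 min emotion video; 8 regions / 4 channels
keep a 60-trial study tractable on one CPU while preserving every
structural property the method exercises (directed edges, region-channel
coupling, window overlap). What the simulator deliberately does *not*
emulate: head geometry (the lead field is random Gaussian), physiological
artifacts (cardiac, Mayer waves, motion), nonlinear hemodynamics, and
nonstationary stimulus-locked dynamics. Passing tests on this generator
therefore demonstrate correctness of the computations and recoverability of
planted structure, not performance on real recordings.

## Numerical choices

* The `u x u` inverse-problem system is solved by Cholesky factorization,
  never explicit inversion; the solution is linear in `X` to ~1e-10.
* Band-pass filtering is a 4th-order Butterworth applied forward-backward
  (zero phase, so no lag bias enters the Granger fits). In
  transfer-function form this 8-pole filter is numerically delicate near
  its low band edge; superposition holds to ~1e-5, and the tests assert
  that realistic bound.
* Resampling is Fourier-domain band-limited resampling (spectrum
  truncation/extension) after removing and restoring a linear trend; on a
  slow sinusoid an 11 to 200 to 11 Hz round trip is accurate to well under
  1% away from the edges.
* Granger fits use QR-based least squares on embedded lag matrices; the
  variance ratio uses the same effective sample count in numerator and
  denominator, so the estimator convention cancels.
* Ties in BIC order selection break toward the smaller order.

## A known limitation: per-window GLM conditioning

The coupling GLM is fit on 3 s windows, but the canonical HRF acts as a
~0.1 Hz low-pass with 32 s support, so within any single window every
design column is close to a straight line. The design is therefore
numerically rank ~2 regardless of how many sources there are, and the
per-window coefficients are extremely sensitive to any mismatch between
design and measurement: entries of `sqrt(diag((D'D)^-1))` reach 1e6 on the
default study. Because the coupling strength is the absolute coefficient
taken per window *before* averaging, this amplified noise does not cancel
across windows. Consequences, all reproduced by the test suite and the
acceptance script:

* with noiseless fNIRS generated by the package's own forward model, the
  window-averaged coupling matrix recovers the true weights essentially
  exactly (r = 1.0) — the algebra cancels perfectly when the model holds
  exactly;
* with 10 dB measurement noise the recovery correlation collapses to ~0.25
  and is insensitive to the exact noise level over many orders of
  magnitude, because the error term is the same amplified projection at
  any scale;
* coupling-only (`SC`) features are chance-level on the synthetic study for
  the same reason, so the hybrid's advantage over the causal-only features
  reduces to a near-tie at ceiling accuracy.

Longer GLM windows (tens of seconds) or a trial-level fit would
recondition the design, but would be a different method; the package
implements the windowed procedure as defined and documents the behavior.

## Problem sizes used by the tests and the acceptance script

Module tests run on windows of 300-2000 samples and studies of up to 12
short trials. The acceptance computations use: 10 random 4x10 lead fields
(inverse oracle); 500 replicates of r = 600, p = 2 pairs (null
calibration); one 8-node VAR(2) trial spanning 30 windows (edge-recovery
AUC); an 8-source, 4-channel, 30 s trial (coupling recovery); and the full
default study (60 trials, 1140 window samples) for the classification
ordering, evaluated over five fold-assignment seeds plus one
label-permutation run. These sizes were chosen so the whole study runs
comfortably on a single CPU while leaving every statistical check
well-powered.
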