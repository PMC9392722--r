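---
title: "Methods: effective connectivity from intracranial stimulation"
author: "esconn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: effective connectivity from intracranial stimulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(esconn)
```

# Overview

`esconn` implements an analysis pipeline for mapping effective connectivity
with direct electrical brain stimulation, in two modalities:

* **stimulation with intracranial EEG**: single bipolar current pulses are
  delivered while field potentials are recorded from other electrodes; the
  trial-averaged, stimulation-locked evoked potential (EP) quantifies the
  first-order effect, and nonparametric spectral conditional Granger
  causality over the late response window quantifies second-order (directed,
  network-level) influence between responsive sites;
* **stimulation with concurrent fMRI**: a block design (stimulation ON/OFF)
  drives region-level BOLD responses; a variable-shape spline deconvolution
  quantifies the first-order response, and partial correlations of the
  deconvolution residuals quantify second-order (background) connectivity.

Everything is exercised end-to-end on synthetic data with known ground
truth: the synthetic module is first-class, tested code, and every
downstream guarantee in the test suite is a recovery, calibration or
oracle-equivalence statement against values the generator injected.

# First-order evoked-potential analysis

## Trial screening, averaging, normalization

A stimulation run consists of repeated single pulses (the experimental
protocol delivers 60 charge-balanced biphasic pulses of 0.2 ms per phase at
9 mA — 1.8 µC/phase — at 0.5 Hz). Single trials are screened with two
amplitude rules relative to the per-trial baseline SD computed over
[−100, −10) ms: amplitude above 10 SD at 8 ms (the tail of the stimulus
artifact), or above 50 SD anywhere in [8, 1000] ms, rejects the trial.
Channels in the seizure onset zone or in white matter are excluded; a
channel with zero baseline SD is marked invalid rather than silently
passed. Retained trials are averaged per channel and the mean trace is
normalized by its own baseline SD over [−100, −10) ms, so all amplitudes
are in baseline-SD units.

## Components, range values, latencies

Two components are quantified in half-open peristimulus windows: the early
component in [10, 30) ms (polarity N or P by the sign of the earliest
prominent local extremum) and the late positive component in [70, 200) ms.
The magnitude measure is the *range value* — window maximum minus minimum.
The early window is measured on a zero-phase band-passed trace
(forward–backward 2nd-order Butterworth; the composed response is −6 dB at
2 Hz and 200 Hz) to suppress drift leaking from the late response. Peak
detection uses a prominence rule: a local extremum qualifies if its
prominence exceeds 1 SD (the published protocol states no prominence rule; an
explicit one makes "earliest peak" well defined on noisy traces). Channels
with no qualifying extremum get polarity `absent` and are excluded from
latency statistics. Latency for both windows is measured on the same trace
used for the range in that window, for internal consistency.

## Significance of a response

A response is significant when its range value exceeds the 95th percentile
of the range null estimated from the [−1000, −10) ms baseline. The package
provides two null constructions:

* **surrogate** (default): Gaussian surrogates of the baseline — Fourier
  amplitudes redrawn as complex normals scaled by the baseline amplitude
  spectrum — with range values pooled over windows tiled across every
  surrogate realization;
* **tiled**: ranges of windows slid along the single observed baseline.

The tiled construction is natural but anti-conservative for the late
window: a 990 ms baseline holds fewer than eight independent 130 ms
windows, so its empirical 95th percentile underestimates the marginal
quantile and the false-positive rate is near 11%. The surrogate
construction replaces the single observed baseline with independent
realizations conditional on the baseline spectrum; redrawing the amplitudes
(not only the phases) restores the between-realization power variability
that the tail of the range distribution depends on. Monte-Carlo calibration
on pure-noise channels puts its false-positive rate at 5–7% for both
windows; the residual excess over the nominal 5% comes from estimating the
spectrum from 990 ms of data and is inherent to the baseline length.

## Group statistics

Between-site amplitude contrasts are two-sided t-tests on range values per
ROI with Bonferroni correction over the ROIs tested; latency structure
across the six ROI groups (orbitofrontal OF, lateral prefrontal lPFC,
sensorimotor SM, parietal PL, temporal TL, cingulate CC) is a one-way ANOVA
with Tukey HSD post hoc comparisons. For deliberately under-powered factors
(sex, hemisphere) an effect-size-only mode reports mean differences and
standard errors without hypothesis tests.

# Stimulation-site decoding

Two decoders predict the stimulated amygdala subdivision (medial vs
lateral group) from the responses. The *feature decoder* adds per-channel
features to a gradient-boosted decision-tree classifier in a declared
order — early/late range, early/late latency, categorical ROI, then the
trends — and reports 10-fold cross-validated accuracy per feature count,
with the identical protocol on label-shuffled copies as the empirical
chance level. Classifier hyperparameters follow the published
configuration (tree depth 14, 200 boosting iterations, log-loss, learning
rate 0.03); the backing implementation is `xgboost` with one-hot encoding
for the ROI feature. The *waveform decoder* first reduces the EP time
axis with a neighbor-graph manifold embedding (fuzzy k-NN graph with
smooth-kNN bandwidths, spectral initialization, stochastic cross-entropy
layout optimization; neighbors 15, minimum distance 0.1, Euclidean metric,
fixed seed) and classifies the embedded coordinates, optionally with the
ROI appended. A third map fits the classifier to 2-D embedded points
labelled by latency group and evaluates the decision boundary on a
400 × 400 grid spanning the embedding bounding box with a 5% margin;
per-group accuracy is the fraction of that group's points classified
correctly, following the published evaluation convention.

Cross-validation folds are stratified by label and, by default, grouped by
run: channels of one stimulation run share the stimulus and would leak
across a channel-level split. A `grouping = "none"` mode provides the
channel-level alternative.

# Nonparametric spectral conditional Granger causality

Second-order effective connectivity between iEEG channels is estimated on
the late-response epoch ([70, 200) ms after the pulse) without fitting an
autoregressive model:

1. **Cross-spectral matrix**: multitaper estimate (3 Slepian tapers,
   time-bandwidth 2 by default) averaged over trials and tapers, on a
   zero-padded FFT grid. The default FFT length is at least twice the
   window length: the spectral factor of a lag-limited spectrum is then
   representable on the grid, which lets the factorization below converge
   to machine precision instead of a wrap-around floor.
2. **Wilson spectral factorization**: the iterative minimum-phase
   factorization `S(f) = H(f) Σ H(f)*`. The plain (Newton-speed) update
   can settle into a small two-cycle on rough spectra; the implementation
   detects the stall and switches to a damped update, which breaks the
   cycle and restores convergence to the requested tolerance (default
   1e−9 on the update, with the reconstruction-error invariant checked on
   every factorization). Rank-deficient spectra receive diagonal loading
   of 1e−8 · trace/channels.
3. **Conditional causality**: for source *s* and target *t* given all
   remaining channels, two factorizations are combined — the full system
   and the reduced system without the source. The reduced-model innovation
   process of the target is expressed through the full model (after
   decorrelating the target innovation from the others), and the causality
   spectrum is the log ratio of the reduced innovation variance to its
   component intrinsic to the target. With an empty conditioning set this
   is the pairwise Geweke measure. Because the minimum-phase factor with
   `H(0) = I` is unique, it transforms covariantly under channel
   permutation; the all-pairs routine therefore shares one full-system
   factorization across all pairs and one reduced factorization per
   source.
4. **Significance**: phase-randomized surrogates. Each channel-trial
   record's Fourier phases are rearranged independently (conjugate
   symmetric, so the record stays real and its amplitude spectrum —
   hence autocorrelation — is untouched), destroying systematic
   cross-channel structure; the full pipeline is re-run per surrogate and
   the threshold is the 95th percentile per pair and frequency.
   Randomization is applied per trial before spectra are averaged,
   preserving the trial-level structure of the estimator under the null.
5. **Summary**: causality is evaluated at the frequency bin nearest 8 Hz
   (the measure peaks in the alpha range, reflecting the late component),
   averaged within ROI-group pairs, masked by the surrogate threshold, and
   condensed into per-group in/out degrees (sums of significant inflow and
   outflow).

The estimator's core validation is oracle equivalence: on simulated VAR
systems with known coefficients, the frequency-averaged spectral measure
matches time-domain Geweke causality computed by nested least-squares
regressions (an entirely independent route) within 10%, and on a chain
system x→y→z the conditional skip edge x→z|y is indistinguishable from the
surrogate null while pairwise x→z is not.

# Region-level stimulation-fMRI analysis

## Deconvolution

ROI series (TR = 3 s) are scaled to mean 100; frames with frame-wise
displacement above 0.9 mm and the frame before each, plus the first two
frames of the run, are censored. The block response is estimated by least
squares with a cardinal natural cubic-spline basis — 14 evenly spaced knots
over [−3, 36] s around each block onset, so the coefficients are the
response values at the knots and the shape between knots is the natural
spline interpolant. This is a variable-shape (finite-impulse-response
family) regression: no haemodynamic form is assumed, and on noiseless data
whose response lies in the basis span the fit is exact. The cardinal
construction matters: a generic spline regression basis evaluated at 14
frame lags is rank-deficient against the intercept, whereas the cardinal
basis is full rank by construction. Mean response ("mean beta") per ROI
averages the spline-interpolated shape over 3–30 s after onset; ROIs with
signal dropout propagate `NA`.

## Residual (background) networks

Deconvolution residuals carry the connectivity not locked to the stimulus.
The stated 0.1–1 Hz band exceeds the Nyquist frequency of TR = 3 s data
(0.167 Hz); the only realizable reading is a 0.1 Hz high-pass, which is
what the implementation applies (with a loud warning, and both edges
exposed). Frames of the requested condition (ON/OFF, with a one-TR
haemodynamic shift by default, exposed in the interface) are pooled across
blocks; partial correlations come from the inverse covariance with
Ledoit–Wolf shrinkage toward the scaled identity (the shrinkage weight is
estimated from the data and vanishes as frames accumulate — an ON period
contributes ~10 frames per block against 19 ROIs, so regularization is the
default), then Fisher-z transformed. Condition contrasts are per-edge
two-sided t-tests across runs with Benjamini–Hochberg correction over all
edges. Communities are detected on the positive-weight network with the
Leiden algorithm (modularity objective, resolution 1.0), 200 seeded runs,
followed by consensus clustering: the co-assignment frequency matrix is
thresholded at 0.5 and re-clustered once.

## Run classification

Run-level decoding of the stimulation site uses the per-run table of ROI
mean betas. The 2:1 class imbalance of the emulated design is corrected by
SMOTE (synthetic minority samples interpolated toward nearest minority
neighbors) before fitting a 250-tree random forest; performance is
out-of-bag AUC. Out-of-bag evaluation after oversampling leaks: a tree
whose bootstrap contains a synthetic interpolant of sample *i* has seen
part of *i*. The implementation therefore scores each original sample only
with trees whose bootstrap contained neither the sample nor any synthetic
sample derived from it, which restores an honest null (label-shuffled AUC
near 0.5, with the small pessimistic bias classical for out-of-bag
estimates at a few dozen samples). ROI importance is declared significant
above the label-shuffled mean plus five standard deviations, per variable.
Missing ROI values (electrode dropout) are median-imputed within class with
a missingness indicator column.

# The synthetic-data module

The generator defines the study conditions under which every guarantee is
tested:

* **Evoked potentials**: two Gaussian components per channel — early
  (width 4 ms) at group-specific latencies between 16.6 and 20.8 ms, of
  either polarity, and late positive (width 40 ms) at 129–157 ms —
  on 1/f background noise of unit SD, 60 trials per run, with a
  configurable fraction of artifact trials drawn from the two rejection
  classes (saturation plateaus and large spikes, injected far above the
  50 SD rule so that screening bookkeeping is exact). Lateral-group
  stimulation injects larger early amplitudes (8 vs 4 SD), medial-group
  larger late amplitudes (6 vs 3 SD), matching the qualitative asymmetry
  the protocol reports; amplitudes are in single-trial baseline-SD units.
* **VAR segments**: stationary vector-autoregressions with known
  coefficient and innovation structure (stationarity is enforced via the
  companion spectral radius), giving closed-form spectra, Yule–Walker
  autocovariances and Geweke causalities as oracles.
* **BOLD runs**: block regressor ⊗ double-gamma kernel × per-ROI
  amplitude around a baseline of 100, plus multivariate Gaussian noise
  drawn from the inverse of a ground-truth precision matrix (so the true
  partial correlations are `−P_ij/√(P_ii P_jj)`), plus motion spikes
  co-registered between the series and the FD trace. The double-gamma
  kernel is a fixed shape choice; the deconvolution is shape-free, so any
  smooth kernel exercises it equally.

What the generator does **not** emulate: epileptiform morphology and
interictal activity beyond the two artifact classes, volume conduction and
shared-reference effects between channels, non-Gaussian BOLD noise,
scanner drift, and the spatial (voxel-level) structure of fMRI — the
pipeline is region-level by design. Passing tests therefore demonstrate
correctness of the estimators under the generative assumptions, not
robustness to every pathology of patient recordings.

## Problem sizes and determinism

All randomness flows through explicit integer seeds; a master seed spawns
per-stage seeds deterministically (`derive_seed`), so identical seeds give
bit-identical outputs, including the embedding and every surrogate draw.
The packaged checks run at desk scale, chosen so each statement is decided
by a comfortable margin at single-core laptop cost: oracle equivalence on
100 trials × 2000 samples; null calibrations on 1000 noise channels,
~1500 surrogate-thresholded causality bins, and six repeats of a 28-edge
contrast; latency recovery on 12 simulated stimulation runs (two groups ×
six runs × 24 channels at 2 kHz) and stimulation-site decoding on 20 runs
totalling 720 evoked potentials, close to the scale of the emulated
experimental series. Group-mean latencies are recovered well inside
±0.5 ms at these sizes; single-channel late-component latencies are noisier
(the 40 ms-wide component moves under 1/f noise), which is why latency
statements are made at the group level, as in the source protocol's
figures.

# Known limitations

* The conditional causality routine factorizes one reduced system per
  source; cost grows linearly in channel count and cubically per
  frequency, so whole-grid surrogate thresholds are practical for small
  channel sets (ROI-group level), not hundreds of contacts.
* The surrogate significance null for EPs conditions on the baseline
  spectrum estimated from 990 ms; its false-positive rate is calibrated to
  5–7%, not exactly 5%.
* Partial-correlation networks assume approximately stationary residual
  covariance within a condition; the ON-frame selection uses a fixed
  one-TR haemodynamic shift rather than a deconvolved boundary.
* The trial container format is R serialization with a validated schema,
  chosen for fidelity and zero dependencies; it is not interoperable with
  HDF5 tooling.
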