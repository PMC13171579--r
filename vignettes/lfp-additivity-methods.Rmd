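---
title: "Methods: additivity of multi-site stimulation effects on LFP band power"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: additivity of multi-site stimulation effects on LFP band power}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific question

Deep-brain stimulation for treatment-resistant depression is delivered to
two targets — the subcallosal cingulate (SCC) and the ventral
capsule/ventral striatum (VC/VS) — usually bilaterally, sometimes to both
targets at once. When two stimulation sites are combined, is the network
effect the *sum* of the individual effects, more than the sum (synergy), or
less (antagonism)? This package implements a complete, testable pipeline
for that question on intracranial local field potential (LFP) data: it
measures how each of seven stimulation conditions (`rSCC`, `lSCC`, `rVCVS`,
`lVCVS`, `bSCC`, `bVCVS`, `ALL`) modulates band power across twelve
prefrontal-network regions of interest (ROIs) and four frequency bands, and
classifies each combined-stimulation cell as additive, sub-additive or
super-additive on the additive scale.

Because no public recording of this kind exists, the package ships a
synthetic-data generator whose statistical structure matches the analysis
assumptions exactly, with planted ground truth. Everything downstream of
the generator treats its output as it would treat real recordings.

## Outcome and model

For each stimulation epoch (1 s pre-stimulation, 1 s stimulation, 1 s
post-stimulation), band power is estimated from a bump-wavelet continuous
wavelet transform, averaged over the pre and post windows — excluding the
100 ms flanking stimulation onset and offset — and summarized as the
relative power change

$$\Delta P = \frac{P_{\mathrm{post}} - P_{\mathrm{pre}}}{P_{\mathrm{pre}}}.$$

$\Delta P$ at the trial × channel × band level is modeled with a linear
mixed-effects model: fixed effects are stimulation condition, ROI and band
with all interactions (equivalently, one fixed cell mean per condition ×
ROI × band), and random intercepts for recording channel (nested in ROI
and subject) and for trial nested in dataset nested in subject. Marginal
(population-level) predictions are the fixed-effect cell estimates with
random effects at zero.

The additive-scale interaction of a combined condition $AB$ with
components $A$ and $B$ is

$$\mathrm{Interaction} = \Delta P_{AB} - (\Delta P_A + \Delta P_B),$$

estimated per (ROI, band) from three separate subset models (one per
contrast: bilateral SCC, bilateral VC/VS, multi-target). Inference uses a
cluster bootstrap with 999 resamples: trials are the exchangeable repeated
unit under the random-effect structure, so whole trial clusters are drawn
with replacement within each (subject, dataset) stratum and the model is
re-solved per replicate. Two-sided percentile p-values use the add-one rule
$p = (2\min(n_{\le 0}, n_{\ge 0}) + 1)/(B + 1)$, so the smallest attainable
p is $1/(B+1)$; Benjamini–Hochberg correction is applied within each
model's grid (336 cells for the pooled model, 48 per subset model — the
family choice is ours, made once). A cell is **super-additive** when
$q < 0.05$ and the bootstrap-median interaction has the same sign as the
expected sum $\Delta P_A + \Delta P_B$, **sub-additive** when significant
with the opposite sign, and **additive** otherwise. If the expected sum is
numerically zero (|expected| < 1e-9) a significant interaction is called
super-additive — an effect emerging where none was expected exceeds the
zero sum in magnitude — and the cell is flagged in the report; the
scenarios shipped with the generator never produce this case.

A decision tree (unpruned CART, Gini impurity) then predicts the
interaction class from stimulation-target pair, ROI, band, and the ROI's
mean pre-stimulation power during stimulation of each component target,
with a stratified 70/30 train/test split.

## The estimation engine

The model above is saturated in its fixed effects and has two
random-intercept terms, so the whole fit reduces to sparse indicator
cross-products and a small sparse Cholesky factorization of Henderson's
mixed-model equations. The package fits it with its own REML engine
(`R/lme-engine.R`): the residual variance is profiled out and the two
variance ratios $\gamma = \sigma^2_u/\sigma^2_e$ are optimized numerically
using

$$-2\,\ell_R = (n-p)\left(\log\hat\sigma^2 + 1\right) + \log|D| + \log|C|,$$

where $C$ is the mixed-model-equation coefficient matrix and $D$ the
random-effect covariance in residual units. The engine reproduces
`lme4::lmer` (the test suite compares variance components and cell
predictions directly) at roughly a hundredth of the cost, which is what
makes 999-replicate bootstraps and multi-seed calibration studies practical
on one CPU. During the bootstrap, each replicate re-solves the full
equations — all fixed and random effects — on the resampled clusters, with
the variance ratios held at the full-sample REML estimates; each resampled
cluster receives a fresh random-intercept level. Re-estimating the variance
ratios per replicate changes percentile p-values negligibly in these
balanced designs and would dominate the runtime. Boundary (zero) variance
estimates are accepted and reported as such. Replicates in which a resample
loses every observation of some grid cell are dropped and counted; a run
aborts if more than 5% of replicates fail.

## What the generator emulates

`make_design()` lays out subjects → datasets → trials → channels-in-ROIs
with the seven-condition schedule (defaults: 3 subjects, 2 datasets each,
10 trials per condition, 2 contacts per ROI). `plant_effects()` places true
per-cell effects such that
$\Delta P_{AB} = \Delta P_A + \Delta P_B + \mathrm{interaction}$ holds
*exactly*, and derives the ground-truth class of every cell from the sign
rule. The `mixed` scenario lays the three classes out on a 5-cycle over the
48 (ROI, band) cells, rotated per pair, so the class depends jointly on
ROI, band and pair rather than on any single factor.

Two simulation routes share this effect specification:

* `simulate_power_table()` draws $\Delta P$ directly at the row level with
  the model's exact hierarchical structure (trial intercepts, channel
  intercepts, residual). This is the route for inference-scale studies: a
  default-size table (40,320 rows) simulates in under a second.
* `synthesize_recording()` builds raw multichannel voltages: per band,
  unit-variance 4th-order-Butterworth band-limited Gaussian noise scaled by
  a 1/f-like baseline power, with the post-stimulation second's amplitude
  multiplied by $\sqrt{1 + \Delta P_\mathrm{eff}}$, plus a lead-wide
  common-mode component that bipolar re-referencing must remove.
  Consecutive epochs are separated by a 2 s baseline gap — a desk-scale
  stand-in for the clinical 8 s interphase delay — so low-frequency wavelet
  support cannot carry one epoch's elevation into the next epoch's
  baseline. This route exercises the full preprocessing and spectral chain
  and is used at smaller problem sizes.

Channel intercepts are drawn centered within each (subject, ROI) group: a
channel offset is a deviation from its region's mean response, which makes
the planted cell effect the exact region-level mean at any channel count.
Without centering, the additive-interaction contrast — which has one more
minus sign than plus signs — would inherit each ROI's finite channel-mean
draw as a bias that no trial-level bootstrap can account for.

Noise scales. The default random-effect scales are
`sd_subject_dataset_trial = 0.1`, `sd_channel = 0.1`,
`sd_residual = 0.26`, calibrated once so that the total single-trial
$\Delta P$ standard deviation is approximately 0.3
($\sqrt{0.1^2 + 0.1^2 + 0.26^2} = 0.30$). The raw-signal route uses
intercept scales (0.1, 0.15) with no explicit residual term: residual
variation arises naturally from finite-sample spectral estimation, and
power-scale amplitude modulation requires $1 + \Delta P_\mathrm{eff} > 0$,
which the generator enforces as an error rather than clipping.

What the generator does **not** emulate: oscillatory bursting, 1/f slope
changes, evoked potentials, volume conduction beyond the single
common-mode term, electrode geometry, or stimulation pulse waveforms
(pulse parameters are carried as fixture metadata only; the stimulation
second is never analyzed). Passing tests therefore demonstrate that the
*analysis machinery* is correct and calibrated under the stated model —
not that the model captures every property of clinical recordings.

## Spectral estimation choices

* **Wavelet**: analytic bump wavelet with the conventional parameters
  $\mu = 5$, $\sigma = 0.6$ (passband about $f \times (1 \pm 0.12)$),
  implemented in the FFT domain. The frequency grid is 2–55 Hz,
  log-spaced at 12 voices per octave, nudged off exact band edges so the
  closed band intervals (theta 4–8, alpha 8–12, beta 13–35, gamma
  36–50 Hz) never double-count a grid point.
* **Epoch padding**: the per-epoch FFT transform is circular; at 4 Hz the
  wavelet's time support approaches a second, which would wrap
  post-window energy into the pre-window. Epochs are therefore
  zero-extended on both sides and the central 3 s retained. Zero
  extension attenuates power deterministically near the epoch edges; the
  droop is mirrored between the pre window (left edge) and post window
  (right edge) and cancels in the $\Delta P$ ratio. (Reflection padding
  was rejected: it creates phase-dependent interference with the mirrored
  signal, up to total cancellation at low frequencies.)
* **Averaging**: linear power, averaged over band frequencies and window
  time, half-open windows, with the two 100 ms exclusions. Rows with
  pre-stimulation power at or below 1e-12 a.u. are excluded and counted.
* **Stimulation-period power** is computed and carried but never used in
  inference; the outcome compares post against pre only.

### An intrinsic property of the ΔP ratio at low frequencies

A 0.9 s window of 4–8 Hz band-limited noise carries roughly
$2 \times 0.9 \times 4 \approx 7$ degrees of freedom, so
$\mathbb{E}[P_{\mathrm{post}}/P_{\mathrm{pre}}] =
\mathbb{E}[P_{\mathrm{post}}]\,\mathbb{E}[1/P_{\mathrm{pre}}] \approx
\nu/(\nu - 2)$ exceeds 1 even for stationary noise — a finite-sample
ratio bias of several tenths at theta and up to about +0.2 at the higher
bands (the exact value depends on sampling rate, windowing and epoch
extraction; the test suite measures it from matched null runs) for *any*
estimator of this outcome at these window lengths. The direct table simulator is
free of it (it draws $\Delta P$ symmetrically), and the test suite
verifies null centering per (ROI, band) there; through the raw-signal
route the suite verifies centering at beta (where the time-bandwidth
product supports it) and documents the positive low-band bias explicitly.
Two corollaries are worth knowing when reading results from the signal
route: single-epoch theta $\Delta P$ is shifted upward, and the
interaction contrast — one extra minus sign — is shifted *downward* by
the same amount, i.e. toward apparent sub-additivity at low frequencies.

## Outlier screen

Epochs contaminated by stimulation onset/offset transients show excess
broadband wavelet power in the two 100 ms windows flanking the
stimulation second. The screen scores each epoch by the ratio of mean
broadband power in those windows to the mean over the remaining pre/post
interior, and flags scores above 5 — a threshold calibrated on null
simulations to a sub-percent false-positive rate (clean epochs score
near 1). On injected artifacts of amplitude ≥ 5 × channel RMS the screen
reaches sensitivity ≥ 0.95 at specificity ≥ 0.99. This deterministic rule
plays the filtering role of an image-classifier stage trained on
hand-labeled spectrograms in the original workflow; its scope is
deliberately limited to onset/offset edge energy, and it makes no claim
about other artifact families. The generator's default contamination rate
is 0.097.

## Decision-tree stage and leakage by construction

Feature rows are observation-level: one row per (pair, ROI, band, subject,
dataset, trial repetition), labeled with the *cell's* class. The
pre-stimulation power features are dataset-level ROI × condition means, so
replicate rows of a cell share identical feature vectors across the
stratified split. An unpruned tree therefore reaches 100% train *and* test
accuracy with per-class F1 of 1 whenever the label is a fixed function of
the cell — which is how the pipeline constructs it. The classifier report
prints this caveat verbatim: the perfect score is a property of the
design, not a generalization claim. Categorical features are
integer-coded with stable alphabetical dictionaries (trees are invariant
to monotone recoding); importances are Gini impurity decreases of primary
splits only (no surrogates or competitors), normalized to sum to 1.

## Problem sizes and calibration studies

The shipped property suite runs at sizes chosen for a single desk CPU:
inference-scale simulations use the default design (40,320 rows pooled;
17,280 per subset model) with the bootstrap at 199 resamples in tests
(999 everywhere the analysis is run for results, including the
acceptance script); calibration properties (null false-call rate ≤ 0.08
per pair; mixed-scenario class recovery ≥ 85% at default size, ≥ 95% with
doubled trials) are averaged over 10 seeds. Raw-signal tests use 2-ROI,
500 Hz designs; the 30 kHz acquisition rate is exercised by the
decimation tests (staged zero-phase Chebyshev-I anti-aliasing, 0.8 × the
target Nyquist, 30 kHz → 1 kHz as 6 × 5).

## Known limitations

* The bootstrap resamples trials, not channels or subjects; with 3
  subjects no resampling scheme could support subject-level
  generalization claims, and none are made.
* The variance ratios are held fixed during the bootstrap (see above).
* Low-frequency $\Delta P$ carries the finite-sample ratio bias analyzed
  above; any comparison of theta/alpha cells against zero through the
  signal route should keep it in mind.
* The generator's band-limited-noise signal model makes planted effects
  exactly interpretable as relative band-power changes, at the cost of
  realism in waveform shape; none of the analysis stages exploit waveform
  shape.
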