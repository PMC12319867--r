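---
title: "Quantitative CVR mapping from breath-hold BOLD: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative CVR mapping from breath-hold BOLD: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breathCVR)
```

## The problem

Cerebrovascular reactivity (CVR) is the vascular response to a vasoactive
stimulus, quantified here as the BOLD signal change per unit change in
arterial CO2 (%BOLD/mmHg), together with its hemodynamic delay (s).
Breath-hold tasks are a practical way to drive CO2 up inside a scanner, and
end-tidal CO2 (P~ET~CO2) — the exhalation-peak envelope of the raw
capnograph trace — is the usual stimulus regressor. The catch is task
compliance: a participant who fails to exhale sharply after a hold, or who
breathes through the mouth, leaves no usable end-tidal peak, and the
resulting CVR map loses its quantitative meaning.

This package implements a complete strategy for that situation:

1. grade every breath-hold trial from the CO2 trace itself;
2. build two surrogate regressors that do not require good CO2 data —
   respiration volume per time (RVT) from a respiration belt, and a
   P~ET~CO2 trace predicted from RVT by a 1D fully-convolutional network
   (FCN);
3. rescale either surrogate to mmHg using the measured P~ET~CO2 from as
   little as one high-quality breath-hold block;
4. fit a voxelwise lagged GLM to produce CVR amplitude and delay maps.

Everything is testable without external data through a synthetic
physiology generator and a BOLD phantom with known ground truth.

## Trace processing and quality grading

Raw CO2 is calibrated to mmHg (`voltsToMmHg()`), end-tidal peaks are
detected by topographic prominence with a minimum separation
(`detectEndtidalPeaks()`; defaults 5 mmHg and 2 s), and the P~ET~CO2 trace
is the piecewise-linear envelope through those peaks, constant-extrapolated
at the ends (`interpolateEndtidal()`). Interactive "manual verification"
is replaced by deterministic parameters plus an optional JSON peak-edit
file (`applyPeakEdits()`), so human QC remains possible but results are
reproducible.

RVT follows the per-breath definition: belt excursion from the preceding
trough to the breath maximum, divided by the time to the next maximum,
anchored at the maximum and linearly interpolated
(`computeRvt()`). Breath holds are entered and left through an exhalation,
which produces two consecutive belt minima with no breath maximum between
them; only the pre-hold minimum is retained (`detectRespExtrema()`). The
detector deliberately uses an asymmetric prominence rule: maxima need
substantial prominence (10% of range, rejecting the small drift bump during
a hold), minima only need to clear a noise floor (1%), because the pre-hold
trough that "shoulders" a deeper post-hold trough has almost no topographic
prominence yet is a real breath event — a symmetric rule would silently
delete exactly the trough the alternation fix needs.

Per-trial quality uses the CO2 change `delta = post-hold peak − pre-hold
peak`. A trial is high quality iff its delta exceeds `mean − 1·SD` of the
positive deltas (`qualityThreshold()`, sample SD by default with an `"n"`
switch; a 1e-9 tolerance keeps degenerate all-equal data high). Skipped
trials are their own label and count as trainable (their data are correct;
there is simply no hypercapnic event). Delta pairing defaults to the
literal contract (last peak before the hold start, first after the hold
end); the pipeline uses the delay-robust `window` mode, because capnograph
measurement delays (15–25 s in typical setups) routinely exceed the hold
duration, and strict boundary pairing then selects a pre-hold breath as the
"post-hold" peak. In window mode the post-hold peak is the largest peak
within 30 s after the hold and the pre-hold peak is the one immediately
before it.

P~ET~CO2 is aligned to RVT by an exhaustive search over integer-sample
shifts within ±30 s, negative shifts only (CO2 lags the belt), minimizing
the Pearson correlation (`bestNegativeShift()`); the exhaustive search is
cheap (301 candidates at 10 Hz per second of bound) and exactly optimal
within the bound. All downstream processing runs on a 10 Hz grid with
linear-interpolation resampling — end-tidal and RVT series are already
piecewise-linear envelopes of sparse points, so linear resampling creates
no new extrema and needs no anti-aliasing filter.

## Rescaling surrogates to mmHg

`rescaleMinmax()` linearly maps a surrogate's extrema onto the min/max of
the measured P~ET~CO2 over the earliest run of *k* consecutive
high-quality blocks (k = 1, 2, 3; skipped blocks break runs). Two readings
of "the same minimum and maximum" are possible — match the surrogate's
global extrema (default) or its extrema within the same block span (the
`extrema = "block"` switch); the global reading is the default because the
rescaled trace is used whole for CVR fitting. The rescaling interval is
non-shrinking in k, and using more blocks protects against the documented
failure mode where the first hold causes an unrepresentatively small CO2
rise. RVT keeps its natural anti-correlated polarity; sign handling is
absorbed by the mapping stage's bulk alignment.

## Response functions

End-tidal regressors are convolved with the canonical double-gamma HRF
(gamma shapes 6 and 16, unit scales, 1/6 undershoot ratio, 32 s support);
RVT with the respiration response function
`0.6 t^2.1 e^(−t/1.6) − 0.0023 t^3.54 e^(−t/4.25)` (60 s support). Both
are sampled at the working rate and normalized to unit peak; unit-area
normalization is available for the HRF but is not the default — note that
the RRF integrates to a *negative* net area, so area normalization would
flip its sign. Convolution is causal and truncated to the input length.
Because unit-peak kernels have sum ≈ `fs ×` (kernel area), a convolved
trace's numeric scale is inflated by that gain; every consumer in the
package (phantom generation and GLM fitting) uses the same convolution, so
amplitudes and delays are self-consistent, and none of the recovery
results depend on the normalization choice. The convolution order follows
the processing diagram of the workflow: rescale first, then convolve.

## The FCN predictor

The network maps an N×2 input — `tanh` of z-normalized RVT, and a one-hot
subject identity padded to length N — to an N×1 z-scale P~ET~CO2
prediction. Half of its layers are strided convolutions (stride 2), half
transposed convolutions mirroring the lengths back; inputs are zero-padded
to a multiple of `2^(layers/2)` and cropped, so any input length is
preserved. Training uses batch size 1, Adam at an initial learning rate of
0.01 reduced by ×0.1 after 4 epochs without a new loss minimum, and the
peak-weighted loss `MSE + λ·MSE(peaks)` with peaks auto-detected on the
target trace. The default configuration is 12 layers, 20 epochs, λ = 0.5.

Choices the architecture family leaves open were fixed as follows, and are
all visible in `fcnConfig()`:

* **kernel width 16, channels 16→32→64 (capped)**: wide kernels let six
  downsampling stages cover ≈ 1 minute of context, enough to see a full
  hold and its recovery;
* **instance normalization** (per channel, no learned affine) after every
  hidden layer, plus a global gradient-norm clip of 1. At a fixed initial
  learning rate of 0.01 with batch 1, the plain 12-layer stack sits on the
  edge of divergence — whether it trains at all depends on the seed. With
  instance normalization, training converges reliably across seeds. This
  is deliberately *not* the minimal design; the minimal one is not
  trainable under the prescribed optimizer settings;
* **ReLU activations**, linear output layer;
* unknown test subjects get an all-zero identity column — prediction
  quality barely depends on identity, consistent with the observation
  that subject ID is not critical for this task.

`fcnGridSearch()` runs the 5-fold cross-validated hyperparameter search
(80/20 segment splits, deterministic fold assignment) and ranks
combinations by mean RMSE at the peaks, the quantity that matters for
hypercapnia estimation.

## Lagged-GLM CVR mapping

`mapCvr()` converts the BOLD series to percent signal change per voxel,
aligns the regressor globally to the mean gray-matter signal (±30 s, on
the lag-grid step), and then fits, per voxel, one OLS model per lag in
`{−9, …, +9}` s at 0.3 s steps (61 regressors; ±15 s / 101 in pathology
mode), each with Legendre polynomial nuisance regressors through order 4.
The lag with the highest full-model R² is the voxel's delay (bulk shift
included); the regressor beta at that lag is the CVR amplitude, in
%BOLD/mmHg because the series is percent signal change and the regressor
mmHg. Equal R² across lags is broken toward the smallest |lag| — a
stability choice for flat R² profiles. Voxels whose winning lag falls in
the two outermost grid steps on either side are flagged and, by default,
removed from the delay map; pathology mode keeps them, since genuinely
long delays are the finding of interest there. Delay maps are additionally
normalized to the gray-matter median. The implementation residualizes the
data and the lag family against the nuisance basis once and reduces each
voxel-lag fit to a projection, which makes the phantom-scale problem
(hundreds of voxels × 61 lags) essentially instantaneous; a brute-force
per-lag `lm()` oracle in the test suite confirms bit-level agreement of
the selected lag and betas.

`extremeDelayMask()` binarizes delays ≥ 10 s and keeps face-connected
(6-neighborhood, switchable to 18/26) clusters of ≥ 15 voxels — the
clinical reading used to localize pathologically delayed territories, and
`dice()` compares such masks between regressors.

## Evaluation metrics

`traceMetrics()` (Fisher-z correlation, MAE, RMSE, RMSE at reference
peaks), `mapMetrics()` (gray-matter metrics after excluding voxels above
the truth map's 98th percentile — the truth map, so every compared method
faces the same exclusion set), `maeMap()` (group MAE maps with gray-matter
medians), `spearmanRankMedians()`, `spatialCorrGm()` and `dice()` cover
the comparison protocol. "Normalized correlation" always means
Fisher-z-transformed Pearson correlation. Two empty masks have Dice 1
(perfect agreement on absence), with a warning. Paired t-tests and
pairwise Bonferroni helpers are thin wrappers over `stats::t.test()`.

## The synthetic study

`synthSpec()`/`genPhysio()` emulate the breath-hold protocol: paced
breathing at 3 s in / 3 s out; 8 trials with hold durations drawn from
10–24 s; a 2 s end-exhalation pause before each hold; a deeper post-hold
exhale trough; two deep recovery breaths; a 10% chance a trial is skipped
and replaced by rest. End-tidal values sit at a 38 mmHg baseline, jump by
the per-hold delta at the post-hold exhalation, and relax back with a 20 s
time constant. The capnograph trace lags the belt by a 20 s measurement
delay (between the 16–23.5 s cohort means reported for typical hardware).
Per-hold deltas follow the physiological accumulation of CO2 during
apnea: `delta = 0.41 mmHg/s × hold duration + trial noise`, with marginal
mean ≈ 7 and SD ≈ 3 mmHg; low-quality trials replace the delta with a
0.3–1.2 mmHg remnant (a missed or mouthed exhale), and skipped trials
leave the envelope untouched. CO2 noise defaults to zero — capnography is
effectively noise-free at the mmHg scale — which makes the generator's
per-trial deltas exactly recoverable, so the grading pipeline can be
tested for *identity* with ground truth rather than approximate
agreement. The belt carries small (0.005) white noise.

What the generator does **not** emulate: cardiac and motion contamination
of the belt, drifting capnograph calibration, irregular breathing rhythms,
within-breath CO2 morphology (a stylized `sin^4` exhalation hump is used),
and any BOLD physiology beyond the linear amplitude/delay model. Passing
tests therefore demonstrate the correctness of the algorithms under the
stated model, not robustness to every artifact of real recordings.

`phantomSpec()`/`genPhantom()` build a 12×12×4, 200-volume (TR 1.5 s)
BOLD phantom: per voxel
`y(t) = B·(1 + a_v/100 · x(t − d_v)) + drift + noise`, where `x` is the
HRF-convolved end-tidal trace demeaned over the scan window (so percent
signal change is unbiased), `a_v` ramps over 0.1–0.5 %BOLD/mmHg, `d_v`
over ±6 s quantized to the lag grid, drift is a Legendre polynomial and
noise is white. Problem sizes throughout (8-trial sessions, ~40 training
segments from 20 recordings, 10 held-out recordings, the 12×12×4 phantom)
were chosen as the smallest sets on which the behaviours of interest —
label recovery, held-out prediction, voxelwise parameter recovery — are
stable and clearly resolved.

## Numerical details and degenerate inputs

* Shift searches and the lag family use exhaustive enumeration on integer
  sample / lag-step grids — exactly optimal within their bounds; constant
  traces are rejected with an error.
* `znorm()` uses the population (n) denominator; `qualityThreshold()` the
  sample (n−1) denominator, with the alternative exposed (the two differ
  by 0.42 mmHg on the four-trial toy example, 3.391 vs 3.807).
* Correlations of identical traces are capped at `atanh(1 − 1e-12)`
  rather than returning infinity.
* Rank-deficient voxel fits are flagged invalid instead of erroring the
  whole map; zero-mean voxels are dropped from the mask at the percent
  signal change step.
* All stochastic components (generator, training shuffles, weight
  initialization, fold assignment) are seeded and reproducible; training
  is bitwise-deterministic on one machine for a fixed seed.

## Known limitations

* The FCN is trained and validated on synthetic physiology; nothing here
  claims transfer to real recordings without retraining.
* The lagged GLM models a single regressor plus polynomial drift; motion
  or cardiac confounds must be handled upstream or supplied as additional
  nuisance columns.
* Bulk alignment targets the mean gray-matter signal; in pathology with
  globally delayed perfusion the bulk shift absorbs part of the delay,
  which is why delay maps are reported relative to the gray-matter
  median.
* The quality threshold is per-recording by default; pooling across a
  collection (as done for cohort-level thresholds) is available by
  computing `qualityThreshold()` on pooled deltas explicitly.
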