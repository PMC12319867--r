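# breathCVR

Quantitative cerebrovascular reactivity (CVR) mapping from breath-hold
BOLD fMRI when end-tidal CO2 quality is low.

## The problem

CVR — the BOLD response per unit change in arterial CO2, in %BOLD/mmHg,
with its hemodynamic delay in seconds — is usually mapped by regressing
breath-hold fMRI data on the end-tidal CO2 trace (P<sub>ET</sub>CO2, the
envelope through the exhalation peaks of the capnograph). That only works
when the participant exhales sharply after every hold; in practice nearly
half of recordings contain at least one breath hold with no usable
end-tidal peak.

breathCVR implements a complete workflow for that situation, aimed at
physiologists and fMRI methodologists:

* **Trace processing** — end-tidal peak detection and interpolation,
  respiration-volume-per-time (RVT) from a belt trace with the
  pre-hold-minima alternation rule, bounded negative cross-correlation
  alignment of CO2 to RVT, 10 Hz working grid.
* **Per-trial quality grading** — the CO2 rise `Δ = post-hold peak −
  pre-hold peak`; a trial is high quality iff `Δ > mean − 1·SD` of the
  positive rises.
* **Surrogate regressors** — RVT itself, and P<sub>ET</sub>CO2 predicted
  from RVT by a 1D fully-convolutional network (strided + transposed
  convolutions, batch 1, Adam, peak-weighted MSE loss), both rescaled to
  mmHg via min–max mapping onto the measured trace over the first 1–3
  high-quality breath-hold blocks.
* **Lagged-GLM mapping** — for each voxel, one OLS fit per regressor lag
  (±9 s at 0.3 s steps by default; ±15 s without boundary thresholding in
  pathology mode) with Legendre nuisance polynomials; the R²-maximizing
  lag is the delay, its beta the CVR amplitude:

  `y(t) = β·x(t − ℓ*) + Σ_p γ_p P_p(t) + ε,  ℓ* = argmax_ℓ R²(ℓ)`

* **Evaluation** — Fisher-z correlations, MAE/RMSE (incl. at peaks),
  group MAE maps with gray-matter medians, Spearman rank preservation,
  spatial correlation, extreme-delay cluster masks (≥10 s, ≥15 voxels)
  and Dice overlap.
* **Synthetic study** — a breath-hold physiology generator (paced 3 s
  in / 3 s out breathing, 10–24 s holds, ~7 ± 3 mmHg per-hold CO2 rises,
  capnograph measurement delay, skipped and low-quality trials) and a
  BOLD phantom with known amplitude/delay fields, so the whole pipeline
  is testable without any data download.

## Worked example

```r
library(breathCVR)

# simulate one breath-hold session with a low-quality third trial
sim  <- genPhysio(synthSpec(seed = 3, lowQualityTrials = 3L, skipProbability = 0))
proc <- processPhysio(sim$co2, sim$resp, sim$timing)
proc$threshold
#> [1] 2.860037
proc$labels
#> [1] "high" "high" "low"  "high" "high" "high" "high" "high"

# map CVR on a phantom driven by the same end-tidal trace
ph   <- genPhantom(phantomSpec(), sim$truth$petco2Ideal)
reg  <- convolveTrace(sim$truth$petco2Ideal, hrf(10))
maps <- mapCvr(ph$bold, ph$mask, ph$gmMask, reg, cvrConfig(), TR = 1.5)
maps
#> CvrMaps: 12x12x4 grid, 576 voxels in mask
#>   amplitude (%BOLD/mmHg): median 0.3000
#>   delay (s): GM median -0.00, bulk shift +0.90
max(abs(maps@amplitude - ph$truth$amplitude))
#> [1] 7.537802e-06
max(abs(maps@delay - ph$truth$delay))
#> [1] 2.220446e-15
```

The threshold is the recording's `mean − 1·SD` of positive CO2 rises in
mmHg; the labels grade each trial against it (trial 3's suppressed exhale
is caught). On the noiseless phantom the lagged GLM recovers every voxel's
amplitude to ~1e-5 %BOLD/mmHg and every delay exactly on the 0.3 s lag
grid.

From a shell, the same workflow runs through the bundled script
(installed at `system.file("exec", "breathcvr", package = "breathCVR")`;
put it on your `PATH` or call it by that full path):

```sh
breathcvr simulate --out session --seed 3
breathcvr process-physio --co2 session/co2.tsv --resp session/resp.tsv \
    --timing session/timing.tsv --out session/proc
breathcvr map-cvr --bold session/bold.nii.gz --mask session/mask.nii.gz \
    --gm session/gm_mask.nii.gz --regressor session/petco2_ideal.tsv \
    --tr 1.5 --out session/maps
```

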