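---
title: "Longitudinal CT slice reconstruction: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Longitudinal CT slice reconstruction: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Abdominal CT is routinely acquired anisotropically: in-plane voxels of
about 1 mm but slice increments of 2.5 mm or more. The missing
through-plane resolution degrades organ-boundary delineation and, in
radiotherapy planning, dose calculation. Acquiring thinner slices raises
dose; interpolating them does not, but plain linear interpolation ghosts
and blurs any structure that moves or changes shape between slices.

`slicerecon` reconstructs the `2m - 1` intermediate slices between each
pair of adjacent slices with learned image-to-image regression, and merges
them with the (bit-untouched) originals into a dense volume. Writing `S_1,
…, S_n` for the dense stack, the sparse input is the arithmetic
subsequence `S_1, S_{1+2m}, S_{1+4m}, …` and each gap's targets are the
slices strictly between its two ends. `m` may be a half-integer; only the
integer step `2m` and the target count `2m - 1` enter the arithmetic.
Trailing slices that do not complete a final gap are excluded from both
groups and reported — padding or mirroring would fabricate evaluation
targets. The same grouping, applied to a dense ground-truth volume, yields
the train/test protocol: sparse slices in, held-out targets as truth.

## The parallel architecture

One U-net per target position: `2m - 1` independently parameterized
networks consume the identical two-neighbour input (stacked as two
channels) and each emits its own position's slice. Independence is
structural — no shared parameters, no shared activations — so one
reconstructed slice cannot influence another, and a branch trained alone
is bit-identical to the same branch trained inside the parallel run (each
branch derives its own RNG stream from the training seed). A
single-network variant emitting all `2m - 1` slices as output channels
(`build_multiout()`) is included as the natural comparator.

Each U-net is the standard encoder/decoder with skip connections at
matching resolutions: per level two 3×3 convolutions, each followed by
batch normalization and ReLU; 2×2 max pooling between encoder levels;
nearest-neighbour upsampling plus skip concatenation in the decoder; a
dropout layer in the last decoder block (default rate 0.5); and a final
1×1 linear projection. The full-scale default is 8 encoder blocks
(including the bottleneck) and 7 decoder blocks. Depth auto-reduces when
the image cannot be halved further (each level needs even, ≥ 4 spatial
extents before pooling): a 400×320 slice supports 4 poolings, a 64×64
phantom slice is used with `encoder_blocks = 3`. Channel widths double
per level from `base_channels`, capped at 512.

Training details are deliberately ordinary and fully exposed in
`train_config()`: Adam, mean-absolute-error loss by default (MAE is also
the evaluation criterion; squared error is selectable), batch size 8,
learning rate 1e-4, all randomness (initialisation, shuffling, dropout)
derived from one seed so training is exactly reproducible.

Two numerical choices deserve note:

* **Residual parameterization** (`unet_spec(residual = TRUE)`, the
  default): branch `k` predicts the correction to its position's linear
  interpolation `(1 - k/2m)·left + (k/2m)·right` rather than the slice
  itself, and the final projection is zero-initialised. An untrained
  branch therefore coincides exactly with the linear baseline, and every
  gradient step is spent on what linear interpolation gets wrong —
  boundary motion and shape change. At desk scale (a few hundred Adam
  steps per branch on one CPU) direct slice prediction is still climbing
  through global-brightness learning when the budget ends, while the
  residual form is below the baseline within an epoch or two. Setting
  `residual = FALSE` restores direct prediction.
* **Output clamping**: predictions are clamped to the normalized [0, 1]
  intensity domain at inference; training is done on the unclamped
  linear output.

## Intensity domain

All learning happens in a fixed normalized domain: HU values are clipped
to [−1000, 1000] (soft-tissue window; bone is out of scope) and mapped
affinely to [0, 1]. A fixed window — rather than per-volume min/max —
keeps the train and test domains identical and makes the map exactly
invertible; the window travels with every `normalized_volume` so errors
can always be reported in HU (a normalized difference of `d` is
`2000·d` HU under the default window).

## Organ range-clip

Soft organs occupy narrow intensity sub-ranges (a liver spans a few tens
of HU while the slice spans the full window). The range-clip transform

    f(x) = 0           if x < R_ll
           1           if x > R_lh
           B (x - C)   if R_ll <= x <= R_lh

with `C = R_ll`, `B = 1/(R_lh - R_ll)` stretches an organ's range
`[R_ll, R_lh]` onto [0, 1] — the unique affine map doing so — which
amplifies in-organ contrast by a factor `B` during training.
`estimate_range()` computes the range from labeled training volumes only
(test labels are never needed to *fit* anything), pooling organ voxels
and taking trimmed percentiles (default 0.5/99.5); trimming replaces the
manual removal of foreign-object noise (drainage tubes, staples) that a
human would do on the histogram. For gas-containing organs the air filter
(`air_mask()`, default threshold 0.25 ≙ −500 HU) excludes intra-organ air
first, since air voxels would drag `R_ll` to the bottom of the window.

`f` is lossy outside the organ range — everything clamps to 0 or 1 — so a
range-clip model alone cannot reconstruct a whole slice. Organ-oriented
reconstruction (`reconstruct_organ_oriented()`) therefore merges two
models: the base model predicts everywhere; inside each organ's mask the
inverse-transformed prediction of that organ's range-clip model (fed
f-transformed inputs) replaces it. Voxels outside all masks are bit-equal
to the base prediction, and overlapping organ masks are an error rather
than a write-order accident.

Masks at target positions must come from somewhere: during evaluation the
dense ground-truth labels are used; for pure inference the mask is
linearly interpolated between the two sparse-slice masks (membership
≥ 0.5), an explicitly documented heuristic. The package does not guess an
organ segmenter.

## Evaluation protocol

* **MAE in HU**, per target position, pooled over all gap instances
  (pooled voxels, not per-patient averages — the per-volume variant is a
  matter of slicing the inputs).
* **SSIM per slice** after per-slice min-max normalization (z-score and
  none are selectable). The SSIM itself is the canonical formulation:
  Gaussian window (sigma 1.5, 11 taps), population covariance,
  stabilisation constants `(0.01 R)^2`, `(0.03 R)^2`, border of one
  filter radius cropped. The implementation agrees with the independent
  scikit-image reference to below 1e-6, which the test suite pins; the
  window size is configurable, the default follows the canonical sigma.
  A slice with zero dynamic range cannot be min-max normalized; its SSIM
  is computed on the unnormalized pair and flagged.
* **Improvement percentages**: `100 (ref − new)/ref` for errors,
  `100 (new − ref)/ref` for similarities, rounded to 2 decimals in
  reports.
* **Paired significance**: two-sided Wilcoxon signed-rank on per-slice
  errors (paired t-test behind a flag), with the sign of the median
  difference reported; all-tie inputs are flagged degenerate instead of
  fabricating a p-value.
* **Choosing m**: the threshold rule scans increasing `m` and stops once
  the maximum pixel-wise MAE exceeds `mu`; the last `m` before the stop
  is selected. On non-monotone tables the scan rule (not "largest m
  under the threshold") governs; if even the smallest `m` exceeds `mu`
  it is returned with a warning.

## The phantom generator

Clinical CT with expert organ labels cannot ship with a package, so
`generate_phantom()` builds what the method actually relies on, and
nothing more: a smooth wide-range background field; four compact "organs"
(liver, two kidneys, stomach) as ellipsoids, each holding a narrow
configured intensity sub-range via a smooth radial profile; organ centers
and radii drifting sinusoidally along the longitudinal axis (the
`nonlinearity` dial), so linear interpolation ghosts boundaries; an
optional air pocket inside the stomach, labeled as stomach, giving the
air filter real work; and per-voxel Gaussian noise (default sd 0.005
≙ 10 HU, ordinary abdominal CT noise). With `nonlinearity = 0` and zero
noise every voxel is affine in slice index and linear interpolation is
provably exact — the package's linearity oracle. `generate_dataset()`
jitters organ paths, phases and ranges per volume (seeded) and splits
80/20 at the volume level.

What the phantom does *not* emulate: anatomical texture, partial-volume
effects, scanner physics, pathology. Passing the phantom study therefore
shows that the pipeline's machinery — grouping, training, range-clip,
merging, evaluation — behaves as designed on data with the assumed
statistical structure; it is not evidence about clinical image quality.

## The desk-scale study

`phantom_study()` is the package's self-contained end-to-end experiment,
sized to minutes on one CPU: 30 volumes of 64×64×25 voxels (24 train / 6
test), `targets_per_gap = 3` (m = 2), a reduced U-net (3 levels, 8 base
channels, dropout 0.2), 10 epochs of Adam at learning rate 1e-3, batch 8.
These sizes are the study's fixed conditions, chosen once: the gap step 4
makes linear interpolation meaningfully wrong, and the training budget
(~540 Adam steps per branch) is where the residual-parameterized branches
have converged well below the baseline on held-out validation. It trains
the base parallel model and a liver range-clip model, reconstructs the
held-out volumes by linear interpolation, the parallel model, and
organ-oriented merging, and reports pooled MAE/SSIM per position, organ
tables, improvements and significance. `scripts/acceptance.R` runs
exactly this study plus the worked-example report arithmetic.

## Known limitations

* No DICOM reading (no reader in the supported dependency set); NIfTI
  only.
* The training engine is deliberately minimal (3×3 convolutions, max
  pool, nearest upsampling, batch norm, dropout, Adam); it is sized for
  the phantom scale, and full 400×320 training, while functional, is not
  a performance target here.
* Per-slice MAE pools voxels across gap instances; per-patient averaging
  is left to the caller.
* Organ-oriented inference needs externally supplied (or interpolated)
  masks; the package deliberately contains no segmenter.
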