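---
title: "Image-based blood-pressure estimation with cross-attention fusion: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Image-based blood-pressure estimation with cross-attention fusion: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The estimation problem

Cuffless blood-pressure monitoring aims to read systolic (SBP) and diastolic
(DBP) pressure, in mmHg, from signals that can be acquired continuously and
non-invasively. Classic approaches need two measurement sites to compute a
pulse transit or arrival time; `ppgbp` implements a single-site alternative:
the photoplethysmogram (PPG) and its first and second time derivatives (vPPG
and aPPG, the velocity and acceleration plethysmograms) are rendered as
images, a convolutional backbone turns each image into a grid of spatial
feature tokens, and the three modalities are fused with multi-head
cross-attention (MHCA) before a linear head regresses (SBP, DBP).

The three modalities are complementary: the raw PPG carries the volumetric
pulse, vPPG emphasises slopes (systolic upstroke, dicrotic transition), and
aPPG accentuates curvature features such as the dicrotic notch. Cross-attention
lets the model weight locations in the value modality according to how
query and key locations align, rather than concatenating pooled descriptors.

## Processing pipeline

1. **Band-pass filtering.** A third-order Butterworth band-pass (0.5–8 Hz)
   realised as cascaded second-order sections. Zero-phase (forward–backward)
   application is the default so that waveform morphology stays time-aligned
   with its labels; the single-pass variant is available via
   `filter_spec(zero_phase = FALSE)`. Band edges are the −3 dB points of the
   single-pass design; forward–backward filtering squares the magnitude
   response, which the tests account for. Start-up transients are suppressed
   with odd-reflection padding and steady-state initial conditions per
   section.
2. **Derivatives.** Central differences on the full filtered record (one-sided
   at the edges), the second derivative being the operator applied twice.
   Differentiating before segmentation avoids per-window edge artifacts at
   shared window boundaries.
3. **Segmentation.** 15-second windows with 2/3 overlap (5 s hop). The
   overlap fraction is configurable because the phrase "sliding window of
   66.67%" admits both an overlap and a hop reading; the package treats it as
   overlap, which matches the "overlapping windows" description.
4. **Window labels.** Simulated records carry one (SBP, DBP) pair, copied to
   every window. For records labelled beat-by-beat (e.g. from an arterial
   line via `abp_to_beats()`), a window's label is the arithmetic mean of the
   beats whose systolic peak falls inside it; windows containing no complete
   beat are dropped and logged. The mean was chosen over the median for
   linearity with the per-beat extraction; with 15-s windows the two differ
   negligibly.
5. **Rendering.** Each window's three traces are rasterised independently as
   black polylines on white, with per-window min–max amplitude normalisation
   and no axes or text. A deliberate consequence is invariance to sensor gain
   and offset. The rasteriser is a deterministic pure function of the samples
   — a plotting toolkit would tie test results to library versions and DPI.
   224×224 matches the standard backbone input; desk-scale experiments in
   this package use 96×96.
6. **Backbones.** `"tiny"` (default): three stride-2 3×3 convolutions
   (3→8→16→32 channels) with ReLU, giving 28×28 (224 px) or 12×12 (96 px)
   token grids; fully trainable and fast on a CPU. `"resnet50"`: the standard
   bottleneck architecture with the classifier removed (7×7×2048 tokens at
   224 px), implemented forward-only with batch normalisation as a
   per-channel affine map; trained weights can be loaded from a plain-text
   file, and random initialisation is used otherwise. No pretrained weights
   ship with the package.
7. **Fusion and regression.** PPG tokens form the queries, vPPG the keys and
   aPPG the values (roles are configurable). Linear-plus-ReLU adapters map
   token channels to the model width `d_model` (default 256, 4 heads; the
   desk-scale experiments use 64/4). Scaled dot-product attention with
   max-subtracted softmax runs per head; heads are concatenated and projected
   (`W^O`), and the fused per-query tokens are averaged into one vector that
   a linear head maps to (SBP, DBP).

## Design choices in the attention block

Two points in the fusion design were genuinely open:

* **Token-level attention.** Projecting each modality's single pooled vector
  would make the softmax trivial — with one key the attention weight is 1 and
  the output ignores the query and key modalities entirely. The package
  therefore attends over the spatial token sequence by default
  (`attend_over = "tokens"`), keeping the literal pooled-vector reading
  available as `attend_over = "vector"` for comparison.
* **Head aggregation.** Concatenation-plus-projection and per-head averaging
  are both defensible readings of how multiple heads are combined. The
  canonical path is concat + `W^O` followed by a mean over query tokens
  (`fusion_mode = "concat_project"`); `fusion_mode = "head_mean"` averages
  head outputs first and then projects. Both are implemented and
  oracle-tested; the default is the concatenating form, which is the standard
  transformer construction.

Parameter initialisation is fan-in-scaled uniform with an explicit seed;
there are no positional encodings (attention is permutation-symmetric in the
key/value tokens, which the tests assert).

## The synthetic-data generator

No public generative ground truth exists for PPG-to-BP, so the package ships
a simulator whose purpose is testability, not physiological fidelity. Each
beat of period `T = 60/HR` is a sum of two Gaussians: a systolic component at
`0.3 T` and a dicrotic/diastolic component at `0.65 T`. Blood pressure is
planted into morphology through two links, with `link_strength` scaling both:

* amplitude ratio `A_d/A_s = clip(0.8 − 0.004 (SBP − 120), 0.1, 0.95)`,
* systolic width `σ_s = 0.10 T (1 + 0.005 (DBP − 80))`.

Baseline wander (0.3 a.u. at 0.25 Hz, below the filter passband) and white
noise (SD 0.02 a.u.) are added. Reference pressures are uniform on
[90, 180] (SBP) and [55, 110] (DBP) mmHg, redrawn until the pulse pressure is
at least 20 mmHg; heart rate is uniform on [55, 95] bpm. Each record retains
its generating morphology parameters (`truth`) so tests can assert the link
without re-estimating morphology from noisy samples.

What the simulator does **not** emulate: motion artifacts, beat-to-beat
variability within a record, dicrotic-notch classes, sensor saturation, or
any validated hemodynamic relation. A model that recovers the planted link
from these data demonstrates that the pipeline can learn a morphology–BP
mapping through the image bottleneck — it says nothing about accuracy on
clinical recordings.

## Training protocol

The optimizer is Adam on the joint MSE over (SBP, DBP) — the loss is not
stated in the source setting, and MSE is the standard choice consistent with
reporting RMSE. Defaults mirror the long-horizon setup: learning rate 1e-4,
batch 16, up to 200 epochs, 10% validation split, 5-fold cross-validation,
early stopping, and step-halving of the learning rate after plateaus
(patience 10 and 5 epochs respectively — unspecified upstream, configurable
here). Within each fold, the validation fraction is carved from the training
portion only; the fold's test windows are never seen during training.

Targets are standardised internally (predictions are always returned in
mmHg), and each backbone token channel is standardised per modality using
training-split statistics before the fusion adapters
(`feature_norm = TRUE`). The latter is purely an optimizer-conditioning
device — raw convolutional activations have heterogeneous channel scales,
and without the standardisation a short Adam schedule stalls far from the
attainable loss; the statistics are stored in the model and applied
identically at prediction time. For the CPU-scale experiments the package
uses learning rate 3e-3 over the full 30-epoch schedule with step-halving on
plateaus (patience 6): Adam's per-step displacement is bounded by the
learning rate, so a 1e-4 rate cannot traverse a standardised-target
landscape in a few hundred steps; raising the rate is the appropriate
scaling for the shortened schedule, not a change of method. Rates above
about 1e-2 were less stable across initialisation seeds on validation loss.

Two split units are provided. `split_by = "window"` mirrors per-dataset
training; because consecutive windows overlap by 2/3, window-level splits
leak near-duplicate samples between folds, so `split_by = "subject"` is
recommended whenever records per subject exceed one. The package makes no
claim about which the original protocol used.

The desk-scale recovery experiment (also run by `scripts/acceptance.R`)
uses 40 records × 60 s at 125 Hz (400 windows), 96×96 renderings with a
3-pixel trace (at this resolution a thicker line survives the stride-2
convolutions better than the 2-pixel default), the tiny backbone with frozen
random weights, and `d_model = 64` with 4 heads. The
frozen backbone acts as a fixed random convolutional feature extractor — the
planted link is linearly recoverable from those features, and freezing lets
the 5-fold run finish in minutes while still training the attention stack and
head end-to-end. Backbone gradients are implemented and finite-difference
checked; `freeze = FALSE` trains the convolutions too.

## Evaluation statistics

For errors `e = estimate − reference`: ME (mean), MAE, RMSE, SD (sample
standard deviation, n−1 denominator — unspecified upstream, chosen to match
common device-validation reporting) and `R² = 1 − Σe²/Σ(ref − mean(ref))²`.
The identity `RMSE² = ME² + ((n−1)/n)·SD²` is asserted in the tests with the
matching correction factor. Confidence intervals are percentile bootstrap
(1000 paired resamples, α = 0.05) — the plain percentile form, as nothing
more specific is stated upstream; resamples on which a statistic is undefined
are redrawn with a capped retry count. Bland–Altman agreement reports the
bias and `bias ± 1.96·SD` limits, each with bootstrap intervals. AAMI
compliance is the inclusive check |ME| ≤ 5 and SD ≤ 8 mmHg (threshold check
only; the subject-count requirements of the full protocol are out of scope).
BHS grading computes the percentage of absolute errors within 5/10/15 mmHg
(inclusive) and awards the best grade whose three thresholds are all met:
A = (60, 85, 95), B = (50, 75, 90), C = (40, 65, 85), else D.

## Numerical notes and limitations

* Zero-phase SOS filtering needs `> 3(2·n_sections + 1)` samples; shorter
  inputs raise an input error rather than returning a silently transient
  result.
* The rasteriser resolves ties in row rounding with a 1e-9 epsilon so that
  affine amplitude rescaling cannot flip a pixel through floating-point
  jitter.
* ReLU is non-differentiable at 0; the backward pass uses the 0 subgradient.
  All-zero convolution patches (blank image regions) sit exactly at the
  hinge, which is why gradient tests perturb around generic points.
* Attention softmax uses per-row max subtraction; attention rows sum to 1
  within 1e-5 by test contract, and outputs are convex combinations of value
  rows.
* The `"vector"` attention mode and the `"resnet50"` backbone are
  forward-only paths: gradient training requires `attend_over = "tokens"` and
  the tiny backbone.
* Deterministic seeding: every random draw descends from an explicit seed
  (dataset, splits, shuffling, initialisation, bootstrap), so end-to-end runs
  are bit-reproducible on one machine; identical results across BLAS
  implementations are not guaranteed at the last ulp.
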