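---
title: "MCM-UNet: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MCM-UNet: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Automatic delineation of the prostate on T2-weighted MRI is hard where it
matters most: the gland's boundaries against surrounding soft tissue are
intrinsically low-contrast, and the apex and base (the inferior and superior
extremities, covered by the first and last slices the organ occupies) are
blurrier still. A segmenter trained slice by slice sees, at those
extremities, small cross-sections with weak edges and little context.

`mcmunet` implements a 2D encoder-decoder segmentation network in the nnU-Net
style with two additions aimed at exactly this failure mode, plus the entire
workflow around it: preprocessing, a synthetic phantom generator, the
compound training objective, the optimizer schedule, and surface/overlap
evaluation metrics.

## The network

The backbone is a plain U-Net of `n_stages` resolution stages: two
convolution + instance-normalization + leaky-rectifier blocks per stage,
strided 3x3 convolutions for downsampling, 2x2 transposed convolutions for
upsampling, channels doubling from `base_channels` up to a `max_channels`
cap. A 1x1 segmentation head sits at every decoder scale; the deepest heads
exist to feed the context-modeling blocks, while the deep-supervision loss
uses all heads when there are at most three decoder scales and otherwise
drops the two lowest-resolution ones, with per-scale weights halving at each
downsampling and normalized to sum to one.

### Context-modeling (CM) attention block

At each decoder skip connection (except the full-resolution step) the block
refines the image-level features `f_sf` (an `HW x C` matrix of positions by
channels) using the scale's own class predictions:

1. The head's logits are softmaxed per position into a 2-class distribution
   `D`.
2. For each class `l`, a **region representation** `R_l` is the spatially
   normalized, `D_l`-weighted average of the feature rows; redistributing the
   regions through each position's class distribution gives the class-aware
   map `f_seg = sum_l D_l R_l`.
3. Pixel-to-pixel attention `W = softmax(f_sf f_seg' / C)` (row-wise) scores
   every position against the class-aware map; `R_sf = W f_sf` aggregates the
   image-level features under it.
4. `[R_sf | f_sf]` is compressed back to `C` channels by a learned 1x1
   transform.

Two readings of the published construction were genuinely open and are fixed
here as follows: the normalization in step 1-2 is per-position softmax over
classes plus per-class spatial normalization (the object-contextual-
representation reading); the attention logits are scaled by `1/C` as printed,
with `1/sqrt(C)` available via `attn_scale = "sqrtC"`; the softmax is
row-wise. `n_cm_modules` counts CM insertions starting from the deepest
decoder step; the full-resolution step never carries one, so at most
`n_stages - 2` take effect, and the default of 6 means "every eligible step".

### FIFO memory bank

Image-level features describe one scan; dataset-level context is supplied by
a fixed-capacity, first-in-first-out bank of bottleneck features. At the
deepest stage, the three stored entries most similar to the current feature
map (cosine similarity between spatially average-pooled channel descriptors,
ties broken toward the oldest entry) are concatenated with it and compressed
`4C -> C` by a learned 1x1 transform; until three entries exist the missing
blocks repeat the query. During training, one fused feature per optimizer
step -- the batch mean, stored without gradient history -- is pushed and, at
capacity `m`, the oldest entry is evicted. At inference the bank is frozen,
so prediction is deterministic. Whether the bank should participate at
inference is not externally specified; freezing it is this package's choice,
made so that repeated predictions agree. Gradients flow into the fusion
transform and the query, never into stored entries.

Defaults `n_cm_modules = 6` and `bank_capacity = 64` follow the
hyper-parameter study that found that configuration best; the ablation
switches `use_cm`/`use_mb` reconstruct the backbone-only baseline and the two
single-module variants (`ablation_run()` trains all four under one seed).

## Training objective and schedule

The loss is an equally weighted sum of soft Dice loss and cross-entropy,
applied per deep-supervision scale. The Dice term is
`-(2/K) sum_k sum_i(u v) / (sum_i u + sum_i v)`, summed over both classes and
averaged per batch sample; it lacks a smoothing term as published, so an
epsilon of `1e-5` is added to the denominator only -- enough to keep batches
with an empty class finite without noticeably biasing non-degenerate values
(a perfect prediction scores -1 + 2.5e-6). Cross-entropy clips probabilities
at `1e-7` before the logarithm; this floor affects only the reported value,
the analytic gradient uses the exact fused softmax form. Both epsilons and
the 1:1 weights are exposed in `train_config()`.

Optimization is stochastic gradient descent with Nesterov momentum 0.99
under the polynomial schedule `(1 - epoch/epoch_max)^0.9`, evaluated once
per epoch (no intra-epoch decay). The full-scale defaults are 1000 epochs of
250 iterations at 2D batch size 12. All gradients are computed by
hand-written backward passes through every layer (convolutions via
im2col/GEMM, instance normalization, the CM block, the bank fusion); the
test suite verifies them against central finite differences to 1e-4 and
better.

## Preprocessing

Volumes are resampled to a `[0.66, 0.66, 5]` mm target spacing -- kept
exactly as published, although with a 5 mm slice pitch the grid is of course
anisotropic -- with a third-order (natural cubic spline) kernel in-plane and
nearest-neighbour between slices, reflecting that interpolating across 5 mm
gaps invents anatomy; masks are always nearest-neighbour, and axes with
fewer than four samples fall back to linear interpolation (a cubic spline
needs four knots). Z-score normalization uses whole-volume statistics
(foreground-restricted statistics would need a mask at inference time).
Axial slices are symmetrically padded/cropped to 512 x 512 for the 2D model;
`crop_patch_3d()` provides the 320 x 320 x 16 organ-centred patches of the
3D pipeline (patch ties at `.5` round toward the origin). The reference
network is 2D; no 3D network variant is provided.

## The phantom generator

`generate_phantom()` emulates the features of T2W prostate data that the
method targets, on geometry where ground truth is exact: a bright ellipsoid
(organ intensity 1.0 against 0.3 background) inside an organ-centred
64 x 64 x 12 field of view at `[0.66, 0.66, 5]` mm; semi-axes of
12 x 10 x 18 mm jittered ±15% per seed, matching gland dimensions seen in
clinical acquisition tables; per-slice in-plane Gaussian blur rising from
0.6 px at mid-gland to 2.5 px on the first/last occupied slices (the
apex/base analogue); additive Gaussian noise with sd 0.05 against the 0.7
intensity contrast. The mask is the clean ellipsoid. Everything derives from
one seed.

What the phantom does **not** emulate: multi-zone internal texture, bias
fields, motion or susceptibility artifacts, neighbouring organs with
confusable intensity, inter-scanner variation, or non-ellipsoidal gland
shapes. Passing the end-to-end study therefore demonstrates that the
architecture, gradients, optimizer and evaluation chain work and can learn a
blurred-boundary segmentation task -- not clinical-grade performance, which
the original work established on 2175 clinical scans.

## Evaluation metrics

Boundaries are foreground voxels with a face-adjacent (6-connectivity)
background-or-outside neighbour; the published work does not define the edge
set operationally, so this conventional choice is fixed here and mirrored by
the brute-force oracle in the tests. ASSD sums, over each boundary voxel of
each mask, the Euclidean distance to the other mask's nearest boundary
voxel, divided by the total boundary count; HD95 is the larger of the two
directed 95th percentiles under the linear-interpolation percentile rule
(`quantile(type = 7)`). Both are computed from an exact separable Euclidean
distance transform and reported in voxel units (as in the original tables),
with an optional `spacing` argument for millimetres. Jaccard and DSC are
reported as percentages; `evaluate_cases()` averages per-case values
arithmetically into the aggregate row (a pooled variant that recomputes
overlap from summed voxel counts is available, since the published
summation is ambiguous between the two). Empty predictions score 0% overlap
and are excluded from distance aggregates with a warning; no policy is
stated in the source material, and silently scoring an undefined distance
seemed worse than flagging it.

The inter-annotator agreement statistic (`annotation_cc()`) is the
Pearson-form correlation of two paired per-slice annotation series.

## The scaled-down study

`run_phantom_study()` is the package's desk-scale stand-in for a clinical
training run: 40 phantoms (32 train / 8 held out, split deterministically),
a reduced network (4 stages, base 16 channels, 64 x 64 patches, bank
capacity 16, CM on both eligible scales), and 20 epochs of 50 iterations at
batch size 2 -- the published schedule scaled down, with the batch matching
the smallest batch used in the original experiments. Problem sizes were
chosen so the whole study runs in minutes on one CPU core. Held-out cases
are scored volumetrically with the full metric set. With these defaults the
study reaches a mean held-out DSC above 99% (the acceptance gate in the test
suite is 85%), and `scripts/acceptance.R` re-runs it from scratch for any
seed.

## Numerical and degenerate-input policy

- Attention and class softmaxes subtract the row maximum before
  exponentiation.
- Spatial normalization in the CM block clamps class masses below `1e-12`
  to avoid division by zero when a class receives (numerically) no
  probability anywhere.
- Non-finite activations abort the forward pass naming the stage; a
  non-finite loss aborts training naming epoch and iteration.
- Instance normalization uses variance epsilon `1e-5`.
- Empty-foreground masks raise "no surface" errors in the distance metrics;
  two empty masks make the overlap metrics undefined and raise errors.
- Bank retrieval ties break toward the lower (older) index;
  `max.col`-based argmax in prediction breaks ties toward the first class.
- All randomness (phantom geometry, initialization, batch sampling) is
  governed by explicit seeds, and the RNG state of the calling session is
  restored afterwards.

## Known limitations

- The 2D trainer treats slices independently; no 3D context is used at
  inference beyond per-slice prediction, and no test-time augmentation or
  cross-validation ensembling is provided.
- CPU training limits practical problem sizes; the full-scale default
  configuration (6 stages, 512 x 512) is provided for completeness, and its
  full-resolution attention would be expensive at that scale, which is one
  reason the CM block is never attached to the full-resolution decoder step.
- The memory bank stores dense feature maps; capacities far beyond the
  defaults mainly cost memory and retrieval time.
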