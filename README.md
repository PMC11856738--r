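# mcmunet

Prostate segmentation on T2-weighted MRI is hardest where the gland's
boundaries blur into the surrounding soft tissue — above all at the apex and
base, the first and last slices the organ occupies. `mcmunet` is an R
implementation of **MCM-UNet**, an nnU-Net-style 2D encoder–decoder
segmenter extended with two components aimed at that failure mode, together
with the full workflow needed to train and evaluate it: NIfTI I/O,
resampling and Z-score normalization, 2D/3D patch extraction, a synthetic
prostate-phantom generator, the compound training objective, SGD training
with Nesterov momentum under a polynomial learning-rate policy, and
surface/overlap evaluation metrics. It is written for researchers in medical
image analysis who want an inspectable, dependency-light reference of the
method — every layer's forward and backward pass is explicit R/Rcpp code,
verified against finite differences.

## The model

**Context-modeling (CM) attention.** At each decoder skip connection (except
the full-resolution step), the scale's own deep-supervision logits are
softmaxed into per-position class distributions *D*; for each class *l* a
region representation *R*<sub>*l*</sub> is the spatially normalized,
*D*<sub>*l*</sub>-weighted average of the image-level features
*f*<sub>sf</sub>, redistributed as *f*<sub>seg</sub> = Σ<sub>*l*</sub>
*D*<sub>*l*</sub>·*R*<sub>*l*</sub>. Attention
*W* = softmax(*f*<sub>sf</sub> *f*<sub>seg</sub>ᵀ / *C*) (row-wise) then
aggregates *R*<sub>sf</sub> = *W·f*<sub>sf</sub>, which is concatenated with
*f*<sub>sf</sub> and compressed back to *C* channels — sharpening boundary
pixels by how much they resemble each class's region.

**FIFO memory bank.** A fixed-capacity queue of dataset-level bottleneck
features *f*<sub>dl</sub>. Each training step retrieves the three stored
entries most similar to the current bottleneck feature (cosine similarity of
pooled channel descriptors), fuses them with it through a learned transform
δ(*f*<sub>dl,m</sub> ⊕ *f*<sub>dl,n</sub> ⊕ *f*<sub>dl,h</sub> ⊕
*f*<sub>sf</sub>), pushes the fused feature, and evicts the oldest entry —
injecting cross-image context that helps precisely the apex/base slices.

**Objective and schedule.** *L* = *L*<sub>dice</sub> + *L*<sub>CE</sub>
(1:1), with the soft Dice loss
*L*<sub>dice</sub> = −(2/*K*) Σ<sub>*k*</sub> Σ<sub>*i*</sub>*u*<sub>*ik*</sub>*v*<sub>*ik*</sub> / (Σ<sub>*i*</sub>*u*<sub>*ik*</sub> + Σ<sub>*i*</sub>*v*<sub>*ik*</sub>)
batch-averaged and applied at every deep-supervision scale; SGD with
Nesterov momentum μ = 0.99 and learning rate decaying as
(1 − epoch/epoch_max)<sup>0.9</sup>.

**Metrics.** ASSD (average symmetric surface distance) and HD95 (95th
percentile Hausdorff) in voxel units from an exact Euclidean distance
transform; Jaccard and DSC in percent; per-case and aggregate reporting.

## Worked example

```r
library(mcmunet)

## surface metrics on hand-built masks: two voxels five steps apart
a <- array(0L, c(12, 3, 3)); a[2, 2, 2] <- 1L
b <- array(0L, c(12, 3, 3)); b[7, 2, 2] <- 1L
cat("ASSD:", assd(a, b), " HD95:", hd95(a, b), "\n")
#> ASSD: 5  HD95: 5

## a synthetic prostate phantom: bright ellipsoid, blurred apex/base
ph <- generate_phantom(phantom_spec(seed = 1))
print(ph$volume)
#> <volume> 64 x 64 x 12 voxels, spacing [0.66, 0.66, 5.00] mm, range [0.08486, 1.178]
cat("organ volume fraction:", round(mean(ph$mask$grid), 4), "\n")
#> organ volume fraction: 0.0774

## a small end-to-end study: train a reduced MCM-UNet on 8 phantoms,
## hold 2 out, and score the predictions volumetrically
res <- run_phantom_study(seed = 1, n_cases = 10, n_val = 2,
                         tc = train_config(epochs = 4, iters_per_epoch = 25,
                                           batch_size = 2, seed = 1))
print(res$fit)
#> <mcm_unet_fit> 4 epochs x 25 iterations, final loss -0.7175, final val DSC 47.31%
#> <mcm_unet> 4 stages, base 16 channels, patch 64x64, 2 CM module(s), memory bank on (m = 16), 559,366 parameters
print(res$report)
#> Segmentation metric report (distances in voxels, overlap in %)
#>    case_id assd_voxel hd95_voxel jaccard_pct dsc_pct
#>     val_01      0.419      1.000      91.072  95.328
#>     val_02      0.589      8.081      89.920  94.692
#>  aggregate      0.504      4.540      90.496  95.010
```

After only 100 optimizer steps the held-out phantoms are segmented at ~95%
DSC with sub-voxel mean surface error; the per-epoch `val DSC` in the fit
log is a cheaper 2D slice score on a capped validation subsample, so it runs
lower than the volumetric report. The full-length study
(`run_phantom_study(seed = 1)`: 40 phantoms, 20 epochs × 50 iterations)
reaches a mean held-out DSC above 99%.

The training defaults in `train_config()` carry the full-scale schedule
(1000 epochs × 250 iterations, 2D batch 12, 512 × 512 slices after
resampling to [0.66, 0.66, 5] mm); `mcm_unet_config()` carries the published
architecture defaults (6 CM modules, bank capacity 64) and the ablation
switches `use_cm`/`use_mb` (see `ablation_run()`). A thin command-line
wrapper with `synth`/`train`/`predict`/`evaluate`/`ablate` subcommands is
installed at `inst/cli/mcmunet`.

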