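# vsseg — automatic vestibular schwannoma segmentation on T1-weighted MRI

Vestibular schwannomas (VS) are benign tumors of the vestibulocochlear
nerve. Gamma Knife radiosurgery planning and long-term follow-up both need
the tumor volume contoured on contrast-enhanced T1-weighted MR, which is
slow and operator-dependent to do by hand. `vsseg` implements a fully
automatic volumetric segmentation pipeline for near-isotropic
(~0.8 × 0.8 × 1.0 mm) T1W volumes, aimed at researchers who want a
self-contained, CPU-runnable implementation of the method — including a
synthetic phantom generator so every stage is testable without patient
data.

## The model

The segmentation network is a five-level residual 3D U-Net (channel widths
16/32/64/80/96 top to bottom). Each level is a ResNet block — two
(3×3×3 convolution → normalization → ReLU) units with an additive skip
across the pair — with stride-2 convolutions for downsampling and stride-2
transpose convolutions for upsampling. Two mechanisms target the very
small foreground (a VS can be 0.03 cm³ against a whole head):

- **Supervised spatial attention.** At every decoder level, the upsampled
  features concatenated with the encoder skip pass through a small
  two-convolution gate producing a per-voxel map `A ∈ (0,1)` that rescales
  the features. `A` is itself trained against the ground truth
  downsampled to that resolution, so the gate learns to be an explicit
  tumor-probability map.
- **Deep supervision.** A 1×1×1 convolution + sigmoid head produces a
  segmentation map at every decoder level; each is compared to the
  correspondingly downsampled ground truth.

The training objective is the unweighted sum of soft Dice losses
`L_Dice = 1 − (2Σpt + s)/(Σp + Σt + s)` over all deep-supervision and
attention maps, plus L2 regularization of the parameters with weight
1e-7. Optimization is Adam at learning rate 0.003, halved at epochs 100
and 200 and every 50 epochs thereafter (300 epochs total), on 128×128×96
patches drawn by class-balanced negative/positive cropping with affine,
contrast and Gaussian-noise augmentation. Whole volumes are predicted by
a sliding window (128×128×96, 25% overlap) with weight-normalized
blending, thresholded at 0.5.

Evaluation uses four volumetric metrics: Dice similarity coefficient
(DSC), 95th-percentile Hausdorff distance (HD95, mm), average symmetric
surface distance (ASSD, mm) and relative absolute volume difference
(RAVD), with cohort summaries stratified by tumor volume
(< 0.1, 0.1–6, > 6 cm³).

All network primitives (3D convolution, transpose convolution,
normalization, and their backward passes) are implemented natively in
compiled code (Rcpp/Armadillo with BLAS matrix kernels) — the package has
no deep-learning framework dependency and runs on a single CPU.

## Worked example

Train a small model on synthetic phantoms and evaluate it (a few minutes
on one CPU):

```r
library(vsseg)

pcfg <- phantom_config(grid_shape = c(48, 48, 48),
                       tumor_volume_range = c(0.3, 3),
                       cystic_fraction = 0.2, seed = 42)
make <- function(idx) lapply(idx, function(i) {
  ph <- generate_phantom(pcfg, vsseg:::case_seed_for(pcfg$seed, i))
  list(image = ph$image, mask = ph$mask)
})
tr <- make(1:20); va <- make(21:23); te <- make(24:28)

ncfg <- network_config(channels = c(8, 16, 24), dropout_rate = 0, seed = 10)
tcfg <- train_config(patch_size = c(32, 32, 32), total_epochs = 16,
                     pos_neg_ratio = 0.6, augmentation = NULL,
                     samples_per_volume_per_epoch = 1, val_interval = 4,
                     seed = 3)
icfg <- inference_config(window_size = c(32, 32, 32))
fit <- train(tr, va, ncfg, tcfg, icfg = icfg)

pairs <- lapply(te, function(pr) {
  prob <- sliding_window_predict(fit$model, pr$image, icfg)
  list(pred = binarize(prob, 0.5), gt = pr$mask)
})
evaluate_cohort(pairs)
#> <cohort_report> 5 cases, 5 detected (0 missed)
#>   dsc      mean 0.998 +/- 0.002  median 0.999 (0.995-1.000)  n=5
#>   hd95_mm  mean 0.000 +/- 0.000  median 0.000 (0.000-0.000)  n=5
#>   assd_mm  mean 0.010 +/- 0.013  median 0.003 (0.001-0.017)  n=5
#>   ravd     mean 0.001 +/- 0.002  median 0.000 (0.000-0.001)  n=5
```

`dsc` near 1 and sub-voxel surface distances mean the thresholded
prediction reproduces the phantom tumor almost voxel-for-voxel; `ravd`
0.001 means the automatic volume differs from the truth by about 0.1%.
(Real
patient MRI is far harder than these phantoms; the example demonstrates
the pipeline, not clinical performance.)

A command-line wrapper with `simulate | train | predict | evaluate`
subcommands ships at `inst/cli/vsseg.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","vsseg.R",package="vsseg"))')" \
  simulate --n 10 --seed 7 --out cohort/
```

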