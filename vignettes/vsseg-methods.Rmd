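---
title: "vsseg: model, phantoms, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{vsseg: model, phantoms, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the method it implements:
the segmentation model and its assumptions, what the synthetic phantoms
do and do not emulate, the numerical choices, and the places where the
design was genuinely open and a decision had to be made.

## The segmentation problem

Vestibular schwannomas are small, contrast-enhancing tumors — in the
population this method targets, between 0.03 and about 18 cm³, with a
median well under 1 cm³ — sitting in a whole-head T1-weighted MR volume
of roughly 256×256×208 voxels at 0.8×0.8×1.0 mm. The foreground is
therefore often a fraction of a percent of the voxels. Everything in the
architecture and loss is shaped by that imbalance.

## Model

The network is a U-Net over five resolution levels with channel widths
16/32/64/80/96 (`network_config()` defaults). Each level is a residual
block: two (3×3×3 convolution → normalization → ReLU) units with an
additive identity skip across the pair. Downsampling between encoder
levels is a stride-2 3×3×3 convolution; upsampling is a stride-2
transpose convolution, after which the features are concatenated with the
encoder skip of that level, passed through the spatial-attention gate,
and reduced by another residual block.

**Spatial attention.** The gate sees the concatenated features (2C
channels), applies a 3×3×3 convolution to C channels with ReLU, then a
1×1×1 convolution to one channel with sigmoid, and multiplies the
features voxel-wise by the resulting map. Because the map is itself
supervised with a Dice loss against the downsampled ground truth, it is
an explicit low-resolution tumor-probability field rather than a free
latent gate. The channel widths and kernel sizes of the two gate
convolutions are not dictated by the architecture description; C then 1
with a 3×3×3 then 1×1×1 kernel was chosen for parameter economy.

**Deep supervision.** Every decoder level gets a 1×1×1 convolution +
sigmoid head. The top-level head is the final segmentation map and always
exists; disabling deep supervision removes only the lower-level heads.
The bottleneck has neither head nor attention gate — supervision applies
to the decoder levels.

**Residual projection.** When a block changes channel count, the skip
path is a 1×1×1 convolution (standard ResNet practice; the block diagram
leaves this implicit).

**Normalization.** Statistics are computed per channel over the spatial
grid of the single volume being processed ("instance" statistics). The
original recipe is batch normalization at batch size 1, where train-time
batch statistics *are* instance statistics; using the same at evaluation
keeps training and inference consistent and makes inference
deterministic, at the cost of not reproducing running-average behaviour.
This is the one deliberate departure from a literal batch-norm layer, and
the config records it (`norm = "instance"`).

**Dropout.** One spatial (whole-channel) dropout at rate 0.3 after the
first unit of each residual block. The recipe states only the rate; the
placement is ours.

## Loss

All supervised maps use the soft Dice loss
\(1 - (2\sum pt + s)/(\sum p + \sum t + s)\) with \(s = 10^{-5}\) in both
numerator and denominator, so an empty-target patch (a negative crop)
against an empty prediction gives loss near 0 instead of 0/0. The total
is the unweighted sum over deep-supervision maps and attention maps plus
\(10^{-7} \sum \theta^2\). The plain (non-squared-denominator) Dice
variant is used.

Supervision targets at coarse levels come from repeated 2×2×2
max-pooling (`downsample_targets()`), not strided subsampling: a 0.03 cm³
tumor is ~47 voxels at full resolution and would simply vanish from a
stride-8 target, while max-pooling guarantees every nonempty tumor stays
nonempty at every scale.

## Training

Adam starts at 0.003 and is halved at epochs 100, 200, 250 for a
300-epoch run (`lr_at_epoch()`; epochs are 0-based). Patches
(128×128×96 by default) are drawn by negative/positive cropping: with
probability `pos_neg_ratio` (default 0.5 — the recipe says only that the
crop balances classes) the patch centre is a uniformly drawn tumor voxel,
otherwise a uniform background voxel. Augmentation defaults — rotation
±10°, scale 0.9–1.1, translation ±5 voxels, gamma 0.8–1.2, noise sd up to
0.1, each with probability 0.5 — are ours; the recipe names the transform
families without ranges. The same affine draw is applied to image
(trilinear) and mask (nearest). An "epoch" draws
`samples_per_volume_per_epoch` patches per training volume; the iteration
count per epoch is not specified anywhere, so it is exposed rather than
hard-coded. Checkpoint selection uses mean validation DSC computed by
full sliding-window inference binarized at 0.5 ("best performance on the
validation set" with the metric unnamed — mean DSC is the natural
reading).

## Inference

Sliding windows of 128×128×96 with 25% overlap; stride is
`round(window × 0.75)` and the last window per axis is clamped to the
boundary, so coverage is complete and no window leaves the volume.
Overlapping predictions are averaged with weights that normalize to one
at every voxel; uniform weights are the default (no weighted blending is
described), with a Gaussian option. The threshold is strictly greater
than 0.5, so a map exactly at 0.5 binarizes to empty — the tie rule is
documented rather than left to floating-point accident. No
connected-component post-processing is applied by default
(`largest_component()` exists but is opt-in), because detection behaviour
of the raw thresholded output is part of what is evaluated.

## Metrics

Border voxels are foreground voxels with a background 6-neighbour
(out-of-grid counts as background). Distances are Euclidean in mm between
voxel centres, scaled per axis by the spacing — not sub-voxel mesh
distances, matching the voxel-level definition of the border. HD95 takes
the 95th percentile (linear interpolation between order statistics) of
each directed border-distance set and combines the two directions with
`max`; the prose definition does not fix the symmetric combination, and
this common convention is the one oracle-tested in the suite. ASSD pools
both directed sets and takes one mean. RAVD uses the absolute difference
per case. An empty prediction is a non-detection: DSC 0, RAVD 1, surface
distances undefined (`NA`), and `evaluate_cohort()` excludes such cases
from the distance summaries while reporting the detection count — the
same accounting used when ablated models miss a tumor.

Internally the directed distances come from an exact anisotropic
Euclidean distance transform (separable parabola sweeps), which the test
suite checks to 1e-9 mm against an independent all-pairs brute-force
reference on dozens of random mask pairs with random spacings.

## Synthetic phantoms

`generate_phantom()` builds: a smooth ellipsoidal "head" (intensity 1
inside, 0.05 outside, smooth edge), a multiplicative low-frequency bias
field (random low-order cosine modes, amplitude 0.2), one tumor, and
additive Gaussian noise (sd 0.05 in background units). The tumor is an
anisotropic ellipsoid (per-axis factors log-uniform within ±25%) with a
smooth quadratic-harmonic radial lobulation (±12%), placed uniformly
off-centre inside the head, at `enhancement_contrast` (default 2.0)
times the local background; the ellipsoid scale is iteratively corrected
so the voxelized volume matches the drawn volume within a few percent.
Cystic variants (default probability 0.2) put a hypointense core (0.4 ×
background) inside the mask, mimicking mixed cystic tumors whose
enhancement is inhomogeneous.

Tumor volumes are drawn **log-uniformly** from `tumor_volume_range`
(default 0.03–17.75 cm³). A log-uniform draw over that range has median
\(\sqrt{0.03 \times 17.75} \approx 0.73\) cm³, matching the strongly
right-skewed clinical distribution (median 0.75 cm³ against a range
maximum of 17.75), where a uniform draw would make small tumors — the
clinically interesting hard case — vanishingly rare.

What the phantoms deliberately do **not** emulate: anatomy (no brain
structures, skull, vessels), Rician noise statistics, partial-volume
effects at the tumor rim, multiple lesions, post-surgical appearance.
Passing the phantom-based learning tests shows the architecture, loss,
optimization and inference plumbing work end to end and that the model
can learn a bright lobulated lesion on a structured background; it says
nothing quantitative about performance on patient MRI.

Per-case seeds are a stable integer hash of (master seed, case index), so
a cohort can be extended without reshuffling existing cases, and every
case is bit-reproducible.

## CPU-scale problem sizes

The package runs entirely on CPU with hand-written compiled kernels
(im2col + BLAS GEMM convolutions with analytic backward passes). The
bundled experiments are sized accordingly and the choices are the
package's own test profile: the overfitting check uses one 48³ phantom,
a 3-level 8/16/24-channel model, 32³ patches and 150 iterations; the
generalization check trains the same model on 20 phantoms (48³, volumes
0.3–3 cm³, 20% cystic, no augmentation — train and test phantoms come
from the same distribution, so augmentation buys nothing at this scale)
for 320 iterations with 3 validation phantoms for checkpoint selection,
and evaluates on 5 held-out phantoms. The full-size five-level
configuration is exercised for its forward contract on a complete
128×128×96 patch; full-scale training of it is a GPU-sized job and is
not attempted here.

## Degenerate inputs and numerical edges

- Constant volumes cannot be z-normalized (explicit error, not a silent
  division by zero).
- Dice smoothing handles empty-vs-empty patches; `dsc()` on two empty
  masks is an error rather than a silently perfect score.
- Surface distances require both masks nonempty; empty predictions are
  routed to the non-detection accounting instead.
- Resampling that would produce an empty grid errors; nearest-neighbour
  resampling never invents values outside the input's value set.
- Training aborts with the offending step when the loss becomes
  non-finite.
- `window_starts()` clamps the final window per axis, and blend weights
  are renormalized per voxel, so corners and clamped windows average
  correctly.

## Known limitations

Single-channel T1W input only (no T2W); no DICOM import, bias-field
correction, skull stripping or registration; instance rather than
running-statistics normalization (see above); no test-time augmentation
or ensembling; training is single-threaded single-volume-batch — faithful
to the recipe's batch size of 1, but slow beyond toy scales on a CPU.
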