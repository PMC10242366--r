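---
title: "Models and methods behind spineseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind spineseg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

spineseg segments paired sagittal T2w/T1w lumbar-spine MR slices into
twelve classes with a family of U-Net variants, ensembles of those
variants, and a threshold-optimized labeling criterion. This vignette
documents the model, the parameters that matter, the synthetic phantom
world the tests run in, and the design decisions taken where the method
left genuine freedom.

## The segmentation model

Every network is an encoder–decoder with four levels plus a bottleneck.
The encoder applies a convolutional block then 2×2 max-pooling per level;
the decoder mirrors it with 2×2 transposed convolutions, and level *n* of
the decoder consumes `D[n] = concat(S[n], transposed_conv(T[n+1]))`, where
`S[n]` is the fusion signal and `T[n+1]` the decoder output one level
deeper. The classification block is a 1×1 convolution to K channels
followed by a per-pixel softmax, so each output pixel carries a normalized
score vector.

Three interchangeable convolutional blocks exist:

* **U** — two 3×3 convolutions, each followed by batch normalization and an
  activation (the original U-Net block). Channel width is `m` at level 1
  and doubles per level.
* **V** — two (levels 1–2) or three (levels 3–5) 3×3 convolutions with
  activations, following the VGG16 layout; used only in the encoder, the
  decoder falls back to U blocks. Weights are always estimated from
  scratch — no transfer learning.
* **Q** — a dense block: three units of batch-norm → activation →
  convolution with kernels 5×5, 3×3 and 1×1, all 64 channels, where unit 2
  sees `concat(input, out1)` and unit 3 sees `concat(input, out1, out2)`.
  Width is fixed at 64 at every level regardless of `m`.

Fusion signals come in three flavours: plain skip connections
(`S[n] = C[n]`), attention gates (a learned sigmoid mask from a 1×1-conv /
add / ReLU / 1×1-conv / sigmoid cascade that multiplies the encoder
features, so gating can only attenuate), and deep supervision. DS.v1
computes `S[n] = conv1x1(C[n]) + up(S[n+1])` with `S[5] = conv1x1(C[5])`;
DS.v2 first computes intermediate signals
`prevS[n] = conv1x1(C[n]) + up(prevS[n+1])` bottom-up, then
`S[1] = prevS[1]` and
`S[n] = conv1x1(C[n]) + up(prevS[n+1]) + maxpool(S[n-1])`, the pooled term
flowing down from the shallower level; DS.v3 aggregates decoder outputs
into the classification input via `Z[n] = conv1x1(T[n]) + up(Z[n+1])`.
A multi-kernel input block (parallel 1/3/5/7 convolutions concatenated)
can precede the encoder. Thirteen registered combinations of these pieces
form the topology registry, including the FCN8 baseline (VGG16-style
backbone with score fusion at strides 32/16/8).

## Parameters that matter

* `m` (base channels, default 64): network capacity. All registry
  networks accept any extent divisible by 16 (32 for FCN8); desk-scale
  tests use `m = 8`.
* `D`/`S` (patch size / stride, defaults 256/192 px): the overlap
  structure. Starts advance by `S` and a final start is clamped to
  `dim − D` when `S` does not tile the image; this guarantees coverage
  without padding and yields 1/2/4-fold overlap at clinical sizes. The
  desk profile 64/48 preserves exactly that structure.
* Optimizers and learning rates are part of each topology's identity
  (Adadelta 1.0 for U1, RMSprop 0.001 for UAD, Adam 0.00033 elsewhere),
  with categorical cross-entropy loss, 300 epochs at clinical scale, and
  the checkpoint chosen by the highest validation pixel accuracy, not the
  final epoch.
* Augmentation (training only): rotation ±20°, zoom 0.5–1.5, shifts up to
  10% of each extent, horizontal flip with probability 1/2 — one shared
  geometric transform per sample, bilinear for the image and
  nearest-neighbour for the mask so the one-hot structure survives.
* Threshold tuning grid: 0.05–0.95 in 0.05 steps, per target class,
  maximizing one-vs-rest IoU on validation slices; background is never
  thresholded (threshold 0) and ties return the lowest grid value.

## Splits

Patient-level, never slice-level: 20% of patients (floor) form a fixed
test set shared by all folds; the remaining 80% are dealt round-robin into
three validation thirds, each fold training on the other two (≈53% train /
27% validation / 20% test of patients). No pixel of one patient can appear
on both sides of any boundary.

## The phantom world

`phantom_config()` describes the synthetic cohort the tests and the
acceptance script run in: per patient, 8–14 square slices (sizes drawn
from a configurable list; desk default 128 px) whose mask is a parametric
sagittal cartoon — a column of rounded vertebral bodies, thin disc bands
between them, a spinal-cavity band, small rare nerve-root blobs inside the
cavity (well under 1% of pixels, mirroring the thin structure that is
hardest in the clinical task), and fat/muscle/subcutaneous context
classes. Both channels render the same mask with different per-class mean
intensities plus Gaussian noise (default sigma 0.08 on a [0, 1] intensity
scale — strong enough to be visible, weak enough that classes remain
separable); two class pairs share their T2w mean and differ only in T1w,
so the two-channel input genuinely matters. All (T2w, T1w) mean pairs are
distinct, hence a nearest-class-mean rule is exact on noiseless phantoms —
the separability sanity check.

What a green phantom test does **not** establish: phantoms have no
anatomical variability, no pathology, no multi-center intensity drift, no
partial-volume boundaries; scores achieved on them say nothing about
clinical accuracy, only that the pipeline's machinery (patching,
optimization, ensembling, labeling, evaluation) is correct and can learn.

## Numerical choices

* The network core is written in Rcpp/RcppArmadillo (im2col convolutions
  with a small tape-based autodiff), since no deep-learning framework is
  available to R here; gradients are verified against central finite
  differences to ~1e-11 relative error.
* Z-score normalization uses the population standard deviation; constant
  channels (zero variance) map to zeros rather than NaNs.
* Upsampling inside deep supervision and attention gates is
  nearest-neighbour ×2; decoder upsampling is a learned 2×2 stride-2
  transposed convolution. Weight init is He-uniform; PReLU slopes start at
  0.25. These are fixed so a seed reproduces runs bit-identically.
* The geometric ensemble mean is not normalization-preserving, so member
  scores are floored at 1e-12 and the result is renormalized per pixel;
  a class scored zero by any member stays (essentially) zero.
* MAP ties break toward the lowest class index; the threshold cascade
  accepts with `score >= threshold`.
* A class absent from both prediction and ground truth is a vacuous 0/0:
  its metrics are reported as 1 and it is excluded from the means; the
  headline mean IoU averages only the eleven target classes.

## Open design decisions taken

* Per-class threshold tuning is independent one-vs-rest per class; a joint
  search over the full cascade (19^11 combinations) is infeasible and the
  per-class formulation matches how the thresholds are applied.
* Deep-supervision 1×1 convolutions emit `m` channels at every level in
  all three variants; the multi-kernel paths are `m/4` wide each; the
  attention gate's intermediate width is half its encoder features; the
  stacking meta-learner is a 64-unit dense layer applied per pixel (a 1×1
  convolution — the only shape-consistent reading of a dense layer on an
  image tensor). None of these widths is pinned by the method description.
* Dense (Q) blocks cannot be combined with DS.v1/DS.v2 fusion (the fixed
  64-channel width conflicts with the m-channel signal sums and no
  registered configuration pairs them); UDD2 uses DS.v2 *as* the fusion
  path alongside DS.v3.
* FCN8 exposes no 64-channel pre-classification tensor, so tensor-input
  (T) stacking rejects FCN members; score-input (N) stacking accepts them.
* Validation "accuracy" for checkpoint selection is per-pixel categorical
  accuracy over validation patches.
* Stacking-head training accepts the same augmentation protocol as member
  training (`augment =`); without it the frozen members' merged tensors
  are precomputed once, which is exactly equivalent and much faster.
* Masks are persisted as single-channel integer NIfTI volumes; one-hot
  tensors live only in memory (12× smaller on disk). The package ships a
  minimal NIfTI-1 codec (no R NIfTI reader is available in this
  environment), cross-checked against nibabel in the tests.
* Ensemble ablation (leave-one-out deltas) is implemented for the
  averaging modes, where removal is exact recomputation; ablating a
  stacking ensemble would require retraining the head per subset and is
  out of scope.

## Known limitations

* CPU-only: clinical-scale training (300 epochs, m = 64, 256-px patches)
  is out of reach; the package is exercised at desk scale.
* 2D only, four levels only — mirroring the method; no 3D context.
* The phantom generator emulates geometry and contrast, not MR physics.
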