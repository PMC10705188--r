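---
title: "Volumetric GAN synthesis of CT tumor patches: models, metrics and design choices"
author: "ctGAN3D"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Volumetric GAN synthesis of CT tumor patches}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Pancreatic ductal adenocarcinoma (PDAC) is difficult to detect on CT:
tumors are often iso-attenuating or hypodense against pancreatic tissue and
lack well-defined margins, and clinical cohorts are small. One response is
to synthesize volumetric CT patches of tumor and pancreas tissue with a
generative adversarial network and to use the synthetic volumes to enlarge
and rebalance classifier training sets. ctGAN3D implements that whole
workflow: Hounsfield-unit (HU) preprocessing, a GAN whose generator is a 3D
U-Net, three tumor-into-tissue blending methods, image-quality and
diversity metrics, and a 3D CNN tumor-versus-healthy classifier protocol —
plus a seeded phantom generator so everything is exercisable without
clinical data.

# Preprocessing

CT intensities are Hounsfield units (water 0 HU, air −1000 HU). Abdominal
scans span roughly −408 to 1298 HU; the diagnostically relevant soft-tissue
window is much narrower. The chain applied to a scan plus its tumor and
pancreas masks is:

1. **Isotropic resampling** to 1 mm spacing (trilinear for intensities,
   nearest-neighbor for masks) on the voxel-center grid, so a voxel spans
   the same physical distance on every axis.
2. **Metal-artifact suppression**: implanted markers produce extreme HU
   values; every voxel strictly above 200 HU is replaced by the mean HU
   over the pancreas mask, computed *before* any replacement (computing it
   after would be circular). Only the strictly-above set changes.
3. **Window normalization**: clip to [−100, 170] HU and map affinely onto
   [−1, 1]. The [−1, 1] range (rather than [0, 1]) matches the generator's
   tanh output activation. The window endpoints map to ±1 and the midpoint
   (35 HU) to 0.
4. **Patch extraction**: a cube centered on the mask centroid (tumor mask
   for 32³ tumor patches, pancreas mask for 64³ pancreas cubes; crops are
   half-open intervals, 0-based in the C sense, 1-based in R). Cubes
   overrunning the volume edge are padded with the window minimum (−1).
5. **Rotation augmentation**: one copy per (axis, angle) pair with angles
   12°, 24°, 36°, 48°, 72° about each of the three axes — 15 copies per
   patch — using trilinear interpolation and −1 fill.

# The GAN

The generator is a 3D U-Net: an encoder of stride-2 3×3×3 convolutions
with ReLU (default depth 4, base 32 channels, doubling per level), a
mirrored decoder of stride-2 transposed 3×3×3 convolutions, skip
connections concatenating each encoder level onto the matching decoder
level, and a final 3×3×3 single-channel convolution with tanh. The network
is fully convolutional, so one architecture serves both the 32³ tumor and
64³ pancreas models.

The generator input is not prescribed by the architecture alone; here it
is a single-channel i.i.d. standard-normal noise grid of the same spatial
size as the output, which keeps the network side-agnostic and makes the
latent draw explicit in the logs.

The discriminator has three blocks of (2×2×2 convolution, stride 1) →
(max-pool 2) → (batch normalization), a flatten, and one fully connected
sigmoid unit. A ReLU follows each convolution — the classifier twin of
this architecture uses one, and without it the stack is nearly linear and
trains poorly.

Losses are the classic min-max cross-entropy pair: the discriminator
maximizes `mean(log D(x)) + mean(log(1 − D(G(z))))` and the generator
minimizes `mean(log(1 − D(G(z))))` (the saturating form, the default). A
non-saturating variant (−mean log D(G(z))) is available behind a config
flag because the saturating loss can stall at small scale. Probabilities
are clamped 1e-7 from the boundaries before logs. Optimization is Adam
with β₁ = 0.5, β₂ = 0.999 — the conventional GAN-stability setting — with
one discriminator step then one generator step per minibatch.

Training runs for a configured number of epochs (2000 at paper scale) and
records generator weights every `checkpointInterval` epochs (20 at paper
scale). GAN collapse is diagnosed from the generator loss curve:
`selectCheckpoint()` smooths the per-epoch loss with a centered 5-epoch
moving average and flags the first checkpoint whose smoothed loss exceeds
the first-quartile smoothed loss times a spike factor (default 3), applied
on the loss magnitude so negative-valued saturating-loss curves are
handled symmetrically; the checkpoint before the first spike is selected,
or the final one if no spike exists. The quartile-times-factor rule
presumes a roughly stationary baseline; it is a heuristic formalization of
"the epoch before the loss drastically increased", and the factor and
window are tunable.

## The network engine

No deep-learning framework is used: the package carries a compact
volumetric network engine written in vectorized R. Activations are
(voxels × channels × batch) arrays; convolutions are im2col gathers
followed by BLAS matrix products; transposed convolutions and input
gradients reuse the same gather geometry through a precomputed sparse
scatter operator; max-pooling, batch normalization, dense layers, dropout
and Adam complete the set. Every layer's backward pass is verified against
central finite differences in the test suite. The engine is deliberately
simple — single-threaded, no autograd graph — and is the reason the
package scales its default experiments down (below).

# Blending

Tumor and pancreas volumes are synthesized separately, so composing them
requires a blending step. Three methods are implemented:

* **Blend I — copy-paste.** The tumor object is extracted by thresholding
  (strictly above the threshold, restricted to the largest 6-connected
  component); inside the placed mask the output takes tumor voxels,
  outside it is bit-identical to the background.
* **Blend II — seamless gradient-domain blending.** The inserted region is
  obtained by iteratively minimizing a 3D gradient-matching (Poisson-style)
  loss: the blend's spatial gradients are pulled toward the tumor's while
  the mask rim is pinned to the background values (Dirichlet constraint).
  Gradient descent with an adaptive step (halved on any increase) gives
  monotone loss descent.
* **Blend III — style refinement.** The stage-1 result is further
  optimized under a weighted sum of content loss (activation distance to
  the stage-1 result), style loss (Gram-matrix distance to the background
  over the first three blocks of the seeded untrained feature extractor),
  the gradient-matching loss, and a total-variation penalty.

The reference two-stage blending approach is a 2D technique; this package
implements a native 3D extension (3D gradients, 3D Gram features) rather
than slice-wise application, since inter-slice coherence is the point of
volumetric synthesis. The default insertion offset centers the tumor in
the background cube; the default threshold is Otsu's threshold on the
tumor histogram, recorded on the result. Default loss weights (gradient 1,
style 1e4, content 1, TV 1e-3) are config values, logged with each run;
they follow the convention of two-stage blending tools, and only monotone
start-to-end descent is contractual.

# Metrics

* **Fréchet distance.** Two feature distributions summarized as Gaussians
  (μ, C) are compared by d² = ‖μ₁−μ₂‖² + Tr(C₁ + C₂ − 2(C₁C₂)^{1/2}).
  The matrix square root matters: without it the distance of a
  distribution to itself is not zero, which is the property the metric is
  used for. A form omitting the square root is kept behind a
  `printedForm` debug flag. Numerically the trace term is computed from
  the eigenvalues of C₁^{1/2} C₂ C₁^{1/2}, with near-zero eigenvalues
  zapped relative to the spectral radius (rank-deficient covariances from
  small batches otherwise leak noise through the square root); agreement
  with an independent eigendecomposition square-root oracle is tested to
  1e-8.
* **F3D.** The Fréchet distance over features from a cold-started,
  untrained 3D CNN with four convolutional blocks seeded at 42. Global
  average pooling over the final 512 channels yields a 512-length feature
  for any input side ≥ 16 (a flattened layer would be 512 only for one
  specific side; pooling resolves that while preserving the length-512
  contract). The extractor's weights are fixed at construction and never
  updated.
* **Slice FID / PSNR.** Center slices on the sagittal, axial and coronal
  planes. The FID backend is a seeded untrained 2D CNN analogous to the
  F3D extractor — fully offline and deterministic; FID magnitudes are only
  comparable within one backend, so reports name it. PSNR uses
  10·log₁₀(R²/MSE) with R = 2 on the normalized domain; the sets are
  unpaired in origin, so a seeded random bijective pairing (logged) is the
  default, and zero-MSE pairs are capped at 99 dB.
* **MMD².** Unbiased Gaussian-RBF estimator with the median-heuristic
  bandwidth over pooled samples, on F3D extractor features by default. If
  all points coincide the bandwidth degenerates and the value is defined
  as 0.
* **MS-SSIM diversity.** Mean multi-scale SSIM over randomly sampled
  distinct pairs, on the three center slices, averaged. Standard MS-SSIM
  is 2D with five scales; a 32–64 px slice supports fewer (each scale
  needs ≥ 11 px, the SSIM window), so the canonical weights are truncated
  and renormalized. A single-scale volumetric SSIM (`ssim3d`) is provided
  separately and labeled as the non-standard variant.

# Classifier protocol

The classifier is four Conv3D(3³, same) → MaxPool(2) → BatchNorm blocks
with 64/128/256/512 filters, flatten, dense 512, dropout, and a 2-neuron
sigmoid output; the tumor score is the second neuron, trained with binary
cross-entropy on that output (the 2-neuron sigmoid head is kept as
described rather than the more usual single logit). A published parameter
count of 1,351,873 is not reconstructible from those widths — the conv
layers alone exceed it — so the architecture follows the textual
description and the actual count is reported, not targeted.

The protocol: per-class 20% hold-out with round-half-up (which is the
unique rounding that sends a 174/254 cohort to a 35/51 test and 139/203
training split); synthetic volumes never enter the test set. Training-set
assembly offers mode I (real only) and mode II (real + requested synthetic
counts; 114 tumors and 50 healthy cubes balance both classes at 253 at
paper scale). Augmentation draws one random rotation per volume (axis
uniform, angle uniform over {5°, 10°, 20°, 40°}, sign uniform). Grid
search covers batch sizes {8, 12, 16} × learning rates {1e-3, 1e-4, 1e-5}
under stratified 3-fold cross-validation — stratified by class and, within
class, by provenance, so the synthetic fraction is constant across folds —
and the best point by mean validation accuracy is refit on all data.
ROC and PR curves come from a threshold sweep over the unique scores with
trapezoidal AUCs; the ROC-AUC is tested to equal the Mann–Whitney
pair-counting statistic exactly, including ties.

# Phantoms

The phantom generator emulates the *statistical regime* of the clinical
data, not anatomy: a correlated Gaussian field (white noise smoothed with
a Gaussian kernel of width `textureCorrelationLength`, rescaled to the
requested standard deviation) models tissue texture with one smoothness
knob; the tumor is a random-semi-axis ellipsoid with smooth boundary
perturbation (tumor margins are ill-defined in the real data, so an exact
ellipsoid would be too easy); the pancreas is a larger enclosing region;
metal artifacts are voxels above 200 HU placed uniformly inside the
pancreas so `suppressMetal()` has a nontrivial target. Defaults — 40 HU
background mean, 25 HU texture sd, +30 HU pancreas offset, −40 HU
hypodense tumor offset, correlation length 3 voxels, artifact intensities
uniform in (800, 1298) HU — were chosen once as plausible soft-tissue
values; the source data characterize only the overall HU range, so these
are stated, not fitted. Everything is seeded, with per-item seeds derived
from the config seed.

What passing tests on phantoms do and do not show: they verify the
machinery — contracts, determinism, separations (a trained generator's
output is closer to held-out phantoms than pure noise is; a hypodense
lesion is learnable) — but say nothing about anatomical realism, scanner
noise physics, or clinical effect sizes. Results on real cohorts require
the real data.

# Problem sizes

The package defaults describe the paper-scale experiment (32³/64³ patches,
2000 epochs, 64–512 classifier channels). The test suite and the
acceptance script run the same code at smoke scale, the package's chosen
verification sizes: 16³ phantom patches, U-Net depth 2 with 4 base
channels, 200-epoch GAN smoke training on n = 32 patches, a separable
n = 120 cohort with a 4/8/12/16-channel classifier under 3-fold CV, and
500-volume synthesis from a small generator. These sizes make every
property checkable in minutes on one CPU while exercising identical code
paths.

# Degenerate inputs and numerical choices

* Probabilities are clamped at 1e-7 before logs; non-finite training or
  blending losses abort with the offending epoch/iteration.
* "Above 200 HU" is a strict inequality; a voxel exactly at the threshold
  is untouched.
* An empty pancreas mask makes the replacement value undefined and errors;
  an empty tumor mask after thresholding errors rather than silently
  no-oping a blend.
* Masks too thin to erode fall back to the un-eroded mask for the
  optimization region.
* Pooling ties break toward the first index; crops round the centroid to
  the nearest voxel; rotation interpolation clamps overshoot back into
  [−1, 1].
* Seeds: every stochastic function takes an explicit seed and restores the
  caller's RNG state; the pipeline derives per-stage seeds from one global
  seed so stages are independently reproducible.

# Known limitations

* The engine is single-threaded R; paper-scale training (64³, 512
  channels, 2000 epochs) is supported by the code but not practical here —
  the design target is correctness and reproducibility at verification
  scale.
* The slice-FID backend is untrained; its magnitudes are not comparable
  with pretrained-backbone FID values reported elsewhere.
* The checkpoint-selection spike rule is a heuristic; curves that drift
  slowly upward without a sharp spike are returned at the final
  checkpoint.
* Phantoms are statistical stand-ins; no beam-hardening or anatomy beyond
  threshold-exceeding marker voxels.
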