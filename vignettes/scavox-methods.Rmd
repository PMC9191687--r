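---
title: "Attention-based patch-wise segmentation of white-matter lesions: models and methods"
author: "scavox"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attention-based patch-wise segmentation of white-matter lesions: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Multiple-sclerosis lesions appear as small, irregular hyperintensities in
FLAIR MRI, scattered through the white matter. Two properties make their
automatic segmentation hard: extreme class imbalance (lesion voxels are a
fraction of a percent of a scan) and ambiguity of lesion boundaries, to the
point that two expert raters routinely disagree on the same scan. `scavox`
implements a complete patch-based volumetric CNN pipeline for this problem —
preprocessing, lesion-biased patch sampling, a residual network with
spatial–channel attention, Focal Tversky training, tiled whole-volume
inference, and lesion-wise evaluation — together with a synthetic phantom
generator so every stage is testable without any external dataset.

## Preprocessing

Each input modality is assumed skull-stripped (zero background). The network
consumes a 2-channel representation per modality:

* **Channel 1 — enhanced intensity.** Intensities are rescaled to [0, 1]
  (making the CLAHE clip limit unit-free), contrast-enhanced with CLAHE
  applied slice-wise on axial planes (CLAHE is inherently 2-D; default
  8×8 tiles, normalized clip limit 0.01, i.e. no histogram bin may exceed 1%
  of a tile's voxels), then standardised to zero mean and unit *population*
  variance over the normalisation region. The default region is the nonzero
  voxels, which for skull-stripped data is the brain; a brain mask or the
  whole volume can be selected instead. With a single CLAHE tile the slice
  receives one clipped-equalization map without interpolation.
* **Channel 2 — Laplacian edges.** The discrete Laplacian of the enhanced
  image, by default the 3-D 6-neighbour stencil (a per-slice 4-neighbour
  variant is available). Boundaries use edge replication so a constant
  volume yields an exactly zero edge map; with zero padding the volume
  border would light up spuriously, which contradicts the intended
  "no contrast, no edges" behaviour.

Edges are computed from the same modality that feeds the channel-1 path.
When both FLAIR and T1-w are used, each path gets its own enhanced+edge
pair; tying the FLAIR path's edge channel to the T1 image instead would be
a defensible alternative reading, but per-modality edges keep the two paths
symmetric and self-contained.

## Patch sampling

Training patches (default $80^3$, configurable; the test suite uses $16^3$)
are drawn with a controlled class bias: exactly `round(n * lesion_fraction)`
of `n` requested centers land on lesion voxels (default fraction 0.6), the
rest on non-lesion voxels, each uniformly within its class and with
replacement. The exact-count implementation of the ~60% bias is
deterministic and testable, unlike a Bernoulli per-draw scheme. Windows are
clamped to lie fully inside the volume rather than zero-padded, keeping
intensity statistics natural near the brain edge. Coordinates are 1-based
with closed windows `[origin, origin + size - 1]` — the idiomatic indexing
for R arrays; the half-open 0-based formulation is equivalent.

Inference uses a disjoint tile grid from the volume origin, zero-padding up
to the next multiple of the tile size; recorded origins make stitching an
exact inverse. An overlap-averaging mode was considered and deliberately
left out: plain disjoint tiling is the documented inference procedure, and
the round-trip identity (tile → stitch) is part of the test contract.

## Network

The single-path model is a VoxResNet-style trunk with six residual modules
("SCA-VoxRes"), multi-scale feature fusion and a pointwise segmentation
head:

```
conv(2→32)+BN+ReLU → conv(32→32)+ReLU            [tap 1: 32 ch, full res]
stride-2 conv(32→64)+BN+ReLU → 2 × SCA-VoxRes    [tap 2: 64 ch, 1/2 res]
stride-2 conv(64→64)+BN+ReLU → 2 × SCA-VoxRes    [tap 3: 64 ch, 1/4 res]
stride-2 conv(64→64)+BN+ReLU → 2 × SCA-VoxRes    [tap 4: 64 ch, 1/8 res]
```

The four taps are brought to full resolution (a 1×1×1 projection for tap 1;
one, two and three kernel-2/stride-2 deconvolutions for taps 2–4) and
concatenated into a 224-channel fused map (32+64+64+64); a 1×1×1 convolution
with voxelwise softmax produces the two class probabilities. Counting trunk
convolutions (17), the tap projection (1), the six deconvolutions and the
head gives exactly 25 convolution/deconvolution layers. The 1×1×1
convolutions inside spatial attention are attention arithmetic, not trunk
layers, and are excluded from the count — under any convention that includes
them no layout reaches the canonical 25. Published layer indices for the tap
positions cannot be reconciled with a single counting convention, so the
taps are fixed at the natural scale boundaries shown above, which satisfies
every hard architectural constraint (6 residual modules, 3 strided
convolutions, 25 layers, 224 fused channels). Four BN layers sit outside the
residual modules (after the first stem convolution and each strided
convolution); the second stem convolution — the full-resolution tap — is
plain ReLU.

**SCA-VoxRes module.** `F + SCA(ReLU(BN(conv(ReLU(BN(conv(F)))))))` — a
two-convolution residual transform gated by the attention block before the
skip addition.

**Spatial attention.** Three 1×1×1 convolutions map the input `F` to maps
`A`, `B`, `C`; with `N = D·H·W` grid cells the affinity
`E = rowsoftmax(B Aᵀ) ∈ ℝ^{N×N}` is row-stochastic, and the output is
`O_j = ω Σ_i E_ij C_i + F_j` with a learnable scalar `ω` initialised to 0,
so every attention block starts as the identity — the standard
stabilisation for this attention family. Because `E` is quadratic in `N`,
grids larger than `attention_pool_max` (default 4096 cells) are
average-pooled before the affinity is formed and the aggregated context is
nearest-neighbour upsampled before the ω-weighted residual add; whenever
`N ≤ 4096` (all unit-test regimes) the computation is exactly the affinity
formulation above.

**Channel attention.** Global average pooling followed by a two-layer
bottleneck `C → C/r → C` (ReLU, then sigmoid; reduction `r = 8`) yields a
per-channel gate in (0, 1) that rescales the map. The two fully connected
layers carry biases; ReLU+sigmoid is the cited attention family's standard
pairing.

The SCA block composes spatial attention first, then channel attention
(configurable). An `attention_on = FALSE` flag bypasses both, giving the
attention-free VoxRes ablation baseline; the tests verify that with the
flag off the output is independent of every attention parameter.

**Two-path fusion.** For FLAIR + T1-w, two independent base models (no
weight sharing) each produce a 224-channel map; decision-level fusion
concatenates them to 448 channels and a single 1×1×1 convolution + softmax
classifies.

The network, its reverse-mode differentiation and the Adam optimizer are
implemented in R with Rcpp kernels for the convolution unfold/fold
(im2col/col2im backed by BLAS matrix products): a compact tape engine
purpose-built for this fixed family of architectures. Every op's gradient is
checked against central differences in the test suite, including a
spot-check through the full 25-layer model.

## Loss

Per class `c`, the Tversky index weighs false negatives by `α` and false
positives by `β`:

$$TI_c = \frac{\sum_i p_{ic} g_{ic} + \varepsilon}
{\sum_i p_{ic} g_{ic} + \alpha \sum_i (1-p_{ic}) g_{ic}
 + \beta \sum_i p_{ic} (1-g_{ic}) + \varepsilon}$$

and the Focal Tversky loss is $\sum_c (1 - TI_c)^\gamma$ with defaults
`α = 0.7, β = 0.3, γ = 4/3, ε = 1e-5`. With `α > β` the loss favours
recall — the right asymmetry when missing a small lesion is worse than
slightly overdrawing one — and `γ > 1` amplifies hard (low-TI) cases such as
small lesions. The sum runs over both classes by default (`classes`
restricts it to the lesion class). Setting `γ = 1` recovers the plain
Tversky loss and `α = β = 0.5` the soft Dice loss; both identities are
asserted numerically in the tests.

## Training and inference

Adam (β₁ = 0.9, β₂ = 0.999, ε = 1e-8) at an initial rate of 1e-4 with
per-epoch exponential decay (default factor 0.95 — the decay rate is not
pinned by convention, so it is exposed in `train_config()`); 100 epochs by
default. A fixed validation patch set is scored after every epoch and the
weights are checkpointed whenever the validation loss improves
(`best_epoch = argmin` val loss). When a scan has two rater masks, the
training target is their logical-or by default (union of the two experts'
knowledge); intersection and single-rater targets are exposed because
evaluation is often reported per rater. Inference thresholds the stitched
lesion-class probability at 0.5 (configurable). A non-finite loss aborts
with a diagnostic rather than silently continuing.

## Evaluation

Lesions are the 18-connected components of a binary mask: face and edge
neighbours connect, pure corner contacts do not. The four metrics per
prediction `R` / ground-truth `A` pair:

* `DSC = 2|A∩R| / (|A|+|R|)` (1 when both masks are empty);
* `LTPR` — fraction of ground-truth lesions overlapped by `R` in ≥ 1 voxel
  (1 when `A` has no lesions);
* `LFPR` — fraction of predicted lesions with zero overlap with `A`
  (0 when `R` has no lesions);
* `AVD = ||R|−|A|| / |A|` (an error for empty `A`: undefined).

The ≥ 1-voxel overlap rule is the lesion-detection convention of the
challenge lineage these metrics come from; the empty-mask conventions make
all metrics except AVD total functions. Fast labelling is an Rcpp BFS;
a pure-R flood fill serves as the independent oracle in the property tests
(200 random mask pairs per run), and a corner-touch fixture separates 18-
from 26-connectivity.

## The phantom

The generator emulates a skull-stripped brain scan: an ellipsoidal support
(semi-axes 0.45 × extent) carrying a smooth Gaussian-filtered tissue field
(mean 100, sd 10 in arbitrary units, smoothness 6 voxels), `n_lesions`
superellipsoid blobs with randomized semi-axes (default 3–6 voxels) and
exponent in [1.6, 2.8] — irregular, like real lesions, and a sharper test of
component logic than spheres — placed with a ≥ 2-voxel separation shell so
the true component count equals `n_lesions` exactly; additive Gaussian noise
(sd 5). FLAIR gets +40 inside lesions, T1-w −20, giving the two-path model
genuinely complementary contrast. Two rater masks derive from the truth by
independently flipping each lesion-boundary voxel with probability
`rater_disagreement` (default 0.1), emulating expert disagreement
concentrated at boundaries. Phantoms are bit-reproducible given a seed.

What the phantom does **not** emulate: MR physics (bias fields, partial
volume, acquisition artefacts), anatomy (gyri, ventricles, the
periventricular predilection of real MS lesions), longitudinal correlation
between time-points, or realistic lesion-intensity overlap with normal
tissue. Tests passing on phantoms therefore demonstrate that the pipeline's
machinery is correct — sampling fractions, architecture contracts, gradient
flow, stitching, metric definitions — not that the trained model reaches any
particular accuracy on clinical data.

## Numerical choices and test-scale parameters

* He-normal weight initialisation; BN momentum 0.1, eps 1e-5; `ω = 0` at
  start; biases start at 0.
* Population (1/n) variance in z-normalisation, so a two-voxel region
  `{1, 3}` maps exactly to `{−1, +1}`.
* Degenerate inputs: constant volumes pass CLAHE unchanged (nothing to
  equalise) and raise an error in z-normalisation (zero variance); CLAHE
  re-zeros the background when a brain mask is attached, so background stays
  background.
* Ties in thresholding: the mask uses strictly `p > threshold`, so an
  exactly-0.5 probability (e.g. an untrained zero-weight head) yields an
  empty mask.
* Test problem sizes are chosen to exercise every code path at desk scale:
  $16^3$ patches, $24^3$–$48^3$ phantoms for unit tests, a $96^3$ phantom
  for the sampling-bias check, and a $32^3$ phantom for the end-to-end
  overfit check. That check trains the full single-path network for 200 Adam
  steps (10 epochs × 20 patches of $16^3$, batch 1) and requires DSC ≥ 0.8
  from tiled inference on the training phantom. Its learning rate is 2e-3 —
  a 200-step overfitting demonstration needs a faster rate than the 1e-4
  default used for full-scale training; 2e-3 is the largest rate at which
  this configuration optimises stably.

## Known limitations

* Batch statistics in BN are computed per patch (batch-of-one training);
  gradient accumulation across a batch shares an optimizer step but not
  normalisation statistics.
* The spatial-attention pooling fallback changes the operator for grids
  above `attention_pool_max`; results at full $80^3$ patch scale therefore
  use pooled affinities at the two finest attention scales.
* Training is single-threaded CPU R/BLAS; the implementation favours
  transparency and testability over throughput and is not intended for
  full-dataset training runs.
* No data augmentation (none is part of the documented procedure).
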