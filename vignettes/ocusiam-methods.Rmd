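---
title: "Siamese attention metric learning for ocular ultrasound: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Siamese attention metric learning for ocular ultrasound: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(ocusiam)
```

## The problem

On B-scan ocular ultrasound, two common posterior-segment findings look
deceptively similar: **vitreous opacity (VO)** presents as *discrete*
echogenic (bright) spots floating in the dark vitreous cavity, while
**posterior vitreous detachment (PVD)** presents as a *continuous*
echogenic membrane or arc in front of the retina. Telling them apart
matters clinically — PVD can precede retinal tears — and the visual
difference is one of lesion *topology* (many small blobs versus one
connected curve) rather than of gross intensity. Labeled clinical
datasets of such scans are small, which is the regime where metric
learning with aggressive weight sharing outperforms plain classifiers.

`ocusiam` implements that approach as a complete, testable pipeline:
a **siamese convolutional branch** with a **channel + spatial attention
block** embeds each image into a feature space, a **contrastive loss**
on image pairs shapes the space so that same-class images lie close and
different-class images lie at least a margin apart, and a
**k-nearest-neighbour vote** over a gallery of training embeddings
classifies new images.

## The model

### Preprocessing

Scans from a fixed device place the fundus in the same region of every
frame, so a fixed rectangular window — x in `[100, 400)`, y in
`[50, 300)` in top-left-origin pixel coordinates, i.e. a 300 × 250
window — removes the dark surround. The pipeline order is fixed:
**crop → resize (bilinear, to the network input side) → normalize**.
Normalization is channel-wise standardization
\(x' = (x - \mu)/\sigma\); the default is the constant shortcut
\(\mu = \sigma = 0.5\) per channel, which maps `[0, 1]` intensities
onto `[-1, 1]` without re-estimating statistics before every run. A
dataset-estimated mode is available, and errors on constant channels.
Grayscale input is replicated to three channels so the same backbones
serve both.

Traditional augmentation (random crop, rotation, vertical/horizontal
flip, color jitter) is applied in that fixed order, each transform
drawing its parameters from configured ranges under an explicit seed;
flips are deterministic when enabled, so a flip-only spec is an
involution.

### Branch networks and the attention block

Four branch architectures are available (`branch_config()`): `vgg16`
(13 3 × 3 convolutions in 5 stages, head FC(4096) → FC(512) → FC(100)),
`alexnet`, `resnet18`, and `tiny`. The attention block sits after the
last convolutional stage in every case. For `resnet18` the published
layout ends with attention followed by FC(512) → FC(100) without naming
a pooling step; we insert the standard global average pool between
attention and the head, which is the conventional ResNet head shape and
the only one consistent with an FC(512) input width of 512.

The attention block is the sequential channel-then-spatial design used
in convolutional attention modules. For a feature map
\(F \in \mathbb{R}^{C \times H \times W}\):

* **Channel gate.** Spatial average- and max-pooling produce two
  C-vectors; both pass through the *same* two-layer MLP (hidden width
  \(\max(\lfloor C/r \rfloor, 1)\), rectified; reduction ratio
  \(r = 16\) by default) and are fused by element-wise addition and a
  sigmoid:
  \(M_c(F) = \sigma(\mathrm{MLP}(\mathrm{AvgPool}(F)) +
  \mathrm{MLP}(\mathrm{MaxPool}(F)))\in\mathbb{R}^{C\times1\times1}\).
* **Spatial gate.** Channel-wise average and maximum planes are stacked
  into a 2-channel descriptor and convolved with one odd kernel
  (default 7 × 7, symmetric padding):
  \(M_s(F) = \sigma(f^{7\times7}([\mathrm{AvgPool}(F);
  \mathrm{MaxPool}(F)]))\in\mathbb{R}^{1\times H\times W}\).

They apply sequentially — \(F' = M_c(F) \odot F\), then
\(F'' = M_s(F') \odot F'\) — so the output never exceeds the input in
magnitude (every gate weight is strictly inside (0, 1)). Either gate
can be disabled, which is what the ablation harness exploits. We use
exactly one block per branch, matching the published per-branch layer
tables; a config hook allows inserting it elsewhere if a variant calls
for more.

### Contrastive pair training

A pair of images \((x_1, x_2)\) with match label \(y\) (1 = same
class) is embedded by the *same* parameter set — weight sharing is
exact because there is only one branch object — and scored by the
Euclidean distance \(d = \lVert e_1 - e_2 \rVert_2\). The loss over a
batch of N pairs is

\[
L = \frac{1}{2N} \sum_{n=1}^{N}
    \left[ y\,d^2 + (1-y)\,\max(\textit{margin} - d,\, 0)^2 \right].
\]

The margin defaults to 1.0, a common choice for unnormalized embedding
spaces; it is exposed in `loss_config()`. Pair sampling draws an exact
positive fraction (default 0.5 — pure uniform sampling would
under-represent positives on balanced two-class data) with no
self-pairs, and one pair per training image per epoch by default.

The reference protocol is Adam at learning rate 1e-5, 50 pairs per
batch, 50 epochs; those are the `train_config()` defaults, and "batch
size" counts pairs. Because this stack runs on CPU without a deep
learning framework, all layers and their backward passes are
implemented in the package (im2col convolution so that the forward pass
is one matrix product per layer); analytic gradients are validated
against central finite differences in the test suite and agree to
~1e-8 relative error.

### KNN over the embedding gallery

Every training image is embedded once into a gallery. A query is
embedded and assigned the majority label among its k nearest gallery
entries under Euclidean distance, k = 2 by default. Two tie rules are
fixed and documented because the method leaves them open: distance ties
are broken by gallery insertion order (so permuting the gallery never
changes a decision), and a split vote falls back to the label of the
single nearest neighbour. At k = 2 in a two-class problem the vote
either is unanimous or splits 1–1, so k = 2 decides exactly like k = 1
whenever its neighbours disagree — consistent with published sweeps in
which small even k values all score identically. At inference a single
image passes through the shared branch once; duplicating its embedding
(as a literal reading of the paired-inference description would do)
cannot change any Euclidean ranking, so the non-duplicated embedding is
used.

### Metrics

With a designated positive class (default PVD; the choice is arbitrary
and recorded in every report):
accuracy \((TP+TN)/\mathrm{total}\), precision \(TP/(TP+FP)\), recall
\(TP/(TP+FN)\), and F1 the harmonic mean of the latter two.
Division-by-zero cases report 0 with a `degenerate` flag rather than
raising, so harness tables stay rectangular. Because the reference
protocol does not say whether its figures are per-class or
macro-averaged, both are emitted.

## The synthetic data generator

The clinical dataset this class of method is trained on is not
publicly available, so the package ships a generator
(`synthetic_spec()`, `generate_dataset()`) whose defaults emulate the
documented regime: 220 images per class, balanced exactly, 512 × 512 so
the standard crop window applies unchanged. Each image is a dark field
with a brighter elliptical fundus region; the VO class receives 3–6
disjoint Gaussian-profile blobs inside the ellipse, the PVD class one
continuous thickened arc along the posterior ellipse boundary (a
`continuity` parameter can render partial detachments), and
multiplicative uniform speckle (amplitude 0.15 by default) is applied
last. Everything is a pure function of (spec, class, seed).

What it deliberately does **not** emulate: ultrasound physics (no
point-spread function, attenuation, or shadowing), anatomical
variability, probe-angle diversity, or the intensity statistics of real
speckle. Consequently, passing end-to-end tests on synthetic data shows
that the pipeline *learns a solvable two-class contrast of exactly the
intended morphology* (discrete blobs vs. a continuous arc) — it does
not certify clinical performance. By construction, with noise 0 the two
classes are separable even by a connected-component count, and a test
asserts that, so a failure of the learned pipeline is attributable to
the pipeline rather than to an unlearnable fixture.

## Numerical choices and problem sizes

* **Initialization**: He-scaled normal weights, zero biases, seeded;
  two builds with the same (config, seed) are identical.
* **Zero-distance subgradient**: at \(d = 0\) the distance is not
  differentiable; the gradient is taken as 0 there.
* **Batch-norm** (resnet18 only): per-channel spatial statistics in
  training, running statistics (momentum 0.1) at evaluation; running
  statistics ride along in checkpoints.
* **Determinism**: every stochastic operation funnels through one
  seeded-RNG helper that restores the caller's RNG state; derived
  per-epoch and per-image seeds keep independent streams inside 32-bit
  range. Run-twice byte-identity of images, manifests, pair lists,
  checkpoints and reports is asserted in the tests.
* **Desk scale**: the `tiny` architecture (3 conv stages of width
  8/16/32, 64 × 64 input, head 128 → 32 → 16) exists so training runs
  complete in seconds on one CPU; it is a configuration choice, not a
  claim about the reference model. Tiny-scale runs use learning rate
  1e-3 — at the full-scale default of 1e-5 the tiny network moves too
  little within a few epochs to demonstrate learning; the full-scale
  default remains 1e-5. Test and acceptance runs use noiseless
  generator settings at sizes 48–96 with up to 30 images per class,
  and the gradient check probes sampled coordinates of every parameter
  tensor (the full tiny branch has ~2.8e5 parameters; exhaustive
  per-coordinate differencing is not informative beyond the sampled
  probe given the observed ~1e-8 agreement).

## Known limitations

* No pretrained ImageNet weights ship with the package; `pretrained =
  TRUE` requires a locally supplied checkpoint and otherwise errors
  with a pointer to random initialization. Results at full VGG16 scale
  therefore depend on the user's weights and data.
* Training the full 224 × 224 architectures in pure R is orders of
  magnitude slower than framework-based training; the package is
  designed for method study, reproduction of the pipeline's structure,
  and desk-scale experiments, not for GPU-scale training runs.
* Binary classification only; the manifest layer enforces exactly two
  classes.
* DICOM ingestion and generative (GAN-based) augmentation are out of
  scope.
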