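---
title: "Grading maize haploid fertility restoration: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grading maize haploid fertility restoration: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The grading problem

Spontaneous haploid genome doubling is scored in the field on two organs:
anther emergence on the tassel and seed setting on the ear, each graded
into six ordinal levels. Level 0 is special — it marks the complete
absence of the trait (no anthers, no kernels) and is a categorically
distinct phenotype rather than merely the low end of a continuum. The
package casts grading as 6-way image classification of a single organ
photographed against a dark background.

## Network

The classifier is an Inception-ResNet convolutional network with a global
attention mechanism (GAM):

Stem → A-block stack → Reduction-A → B-block stack → Reduction-B → GAM →
global average pool → dropout → 6-way linear head → softmax.

Assumptions baked into the architecture: the organ is roughly centred and
fills a substantial part of the frame; grade-relevant evidence (kernels,
anthers) is a *texture/coverage* property rather than a fine geometric
one, so aggressive spatial reduction with channel expansion is
appropriate; and multi-scale branches plus residual connections keep
gradients healthy at depth.

### Stem stride schedule

The composition Conv3 ×3, Maxpool, ERF fixes the layer sequence but not
the strides. The package uses the unique simple schedule that maps a
299-pixel input to the printed `256 × 35 × 35` output:
conv 3×3 stride 2 valid (299→149), stride 1 valid (149→147), stride 1
same (147→147), max-pool 3×3 stride 2 valid (147→73), then ERF with
1×1 (73), 3×3 stride 1 valid (73→71), 3×3 stride 2 valid (71→35).

### ERF is stride/padding polymorphic

The same 1×1→3×3→3×3 submodule appears in three contexts with
incompatible shape contracts. Inside residual blocks it runs stride 1
with same padding (shape preserved); in the stem both 3×3 convolutions
are valid with the last at stride 2; in the reductions the middle
convolution is same-padded and the final one is valid stride 2
(35→17, 17→8). The constructor therefore takes per-convolution strides
and paddings.

### Normalisation and biases

Every convolution is followed by batch normalisation and (except fusion
convolutions) a ReLU. Under batch normalisation the convolution bias is
redundant and omitted; attention-gate convolutions, which have no batch
norm, carry biases. Batch-norm momentum is 0.1 and epsilon `1e-5`;
affine scale/shift pairs are trainable (and counted by the auditor),
running statistics are not. The fusion 1×1 convolution in each residual
block is linear (batch norm, no ReLU) so that the residual sum, not the
branch output, passes through the nonlinearity — this also makes the
"zero the fusion weights ⇒ block is the identity on non-negative input"
invariant hold to machine precision.

### Attention

The channel gate permutes `C × H × W` to put channels last and applies a
two-layer perceptron `c → c/rate → c` (ReLU between) at every position —
algebraically two 1×1 convolutions, which is how it is implemented —
followed by a sigmoid. The spatial gate is a 7×7 convolution pair
`c → c/rate → c` with same padding, ReLU between, then a sigmoid. Gates
are applied progressively (the spatial gate sees the channel-refined
map) and multiply element-wise, so the output equals
`x ⊗ channel ⊗ spatial` and never exceeds the input in magnitude. With
all gate parameters zero both sigmoids are 0.5 everywhere and the stage
scales features by exactly 0.25 — a useful structural test. The
compression rate defaults to 16.

### Reference configuration

Block counts and branch widths are freely stackable; the frozen
reference (`inst/configs/irgam_reference.yaml`) uses five A-blocks and
ten B-blocks with stem 32/32/64 + ERF 80/192/256 (→256 channels),
A-branches 32, 32→32, ERF 32/48/64, Reduction-A 384 + ERF 192/224/256 +
pool (→896), B-branches 176 and 144→148→184, Reduction-B
256→384, 256→256, ERF 256/256/256 + pool (→1792). The published global
constraint on the full model is its float32 size, 137.15 MB; with the
other widths fixed to the standard Inception-ResNet regime, the B-block
widths are the free knobs and were set once so the analytic parameter
count lands on that size (35,952,822 parameters × 4 bytes / 1024²).
"MB" throughout means MiB; the auditor reproduces the 491.32 MB
VGG-11(BN) reference count (128,796,422 parameters) exactly, which
pins down the convention.

## Training

Cross-entropy loss (probabilities clamped at `1e-12` before the log),
Adam with `β₁ = 0.9`, `β₂ = 0.999`, `ε = 1e-8` (the optimizer's
canonical defaults), and a cosine-annealed learning rate over **one**
cycle spanning the whole run (`T_max` = total iterations, no warm
restarts), from `lr_max = 1e-4` to `lr_min = 1e-6`; batch size 16,
300 epochs in the full-scale recipe. He initialisation is the default;
Xavier, orthogonal and plain normal are selectable for initialisation
studies. All randomness (weights, shuffling, dropout, augmentation)
flows from one seed, and a run is bit-reproducible on one device.

Softmax arg-max ties break toward the **lower** grade — when the
evidence is truly ambiguous the conservative call is the weaker
fertility level.

Augmentation produces exactly three variants per image: additive
Gaussian pixel noise (σ = 0.04 on the [0,1] scale), a brightness rescale
(factor drawn from {0.8, 1.2}), and a Gaussian blur (σ = 1.5 px). The
magnitudes are package choices (held in `train_config()` and
overridable); variants are *added to* the training pool, not substituted
for the originals. Inputs reach the network on the symmetric [−1, 1]
scale (`2x − 1`), the convention matching a zero-centred first layer;
the preprocessing step records this so a mean/sd standardisation could
be swapped in. Non-square photographs are center-cropped before the
bilinear resize.

## Metrics

Per class (one-vs-rest): precision `TP/(TP+FP)`, recall `TP/(TP+FN)`,
`F1 = 2PR/(P+R)`; accuracy is the confusion-matrix trace over the total.
Macro averages are unweighted class means (macro-F1 is the mean of
per-class F1, not the F1 of macro precision/recall); support-weighted
averaging is available as an option. A class with zero denominator
contributes 0 with a warning rather than propagating NaN. The fuzzy
accuracy tolerates `|pred − true| ≤ 1` when both levels are ≥ 1; any
confusion involving level 0 stays an error. It is bounded below by the
strict accuracy by construction.

## Grad-CAM

Channel weights are the spatial means of ∂(class logit)/∂A at a chosen
stage; the map is `ReLU(Σ w_c A_c)`, bilinearly upsampled to the input
and min-max normalised per image, with guards: an identically-zero raw
map returns all zeros (not NaN), a constant positive map returns all
ones. The default stage is the attention output — the last
full-convolutional-resolution representation, where the gating the
network actually uses is visible; any stage is selectable by tag, which
matters for very small configurations whose post-attention map is only a
few pixels wide. The localization score is the fraction of heatmap mass
inside the generator's object mask; a uniform map scores exactly the
mask's area fraction, so "better than uniform" is `score > area
fraction`.

## Synthetic scenes

The generator emulates the *structure* of the photographs, not their
appearance: a dark noisy background; for ears a central cob ellipse
(semi-axes ≈ 0.40 and 0.15 of the frame, jittered) carrying bright
kernel disks placed on an overlapping jittered grid; for tassels a stalk
with 6–9 lateral branches carrying bright anther dots. The grading trait
is the realized pixel coverage of the organ region (kernels/cob,
anthers/branch envelope), measured on the emitted mask, and the label is
recomputed from that coverage — so labels are correct by construction
and round-trip through `assign_level()`. Default level bands are {0},
(0, 0.1], (0.1, 0.3], (0.3, 0.5], (0.5, 0.7], (0.7, 1]: the real
breeding criteria live in grading standards not reproduced here, so the
bands are configurable and recorded with every dataset. One global seed
streams per-sample seeds through a counter so datasets are reproducible
while samples stay independent.

What this does **not** emulate: lighting and camera variation, occlusion,
husks and silks, kernel colour genetics, background clutter, or the
ordinal blurriness of real adjacent levels. Passing the synthetic
acceptance checks therefore demonstrates that the architecture,
gradients, training loop and attention behave correctly — not that the
reported field accuracies transfer; those require the real photographs
and GPU-scale training, which are out of scope here.

## Problem sizes used by the tests

The suite trains a reduced-width configuration (one block per stack,
stem 8/8/16 + ERF 16/24/32, attention rate 4) at 139- or 75-pixel inputs
on 60 easy synthetic scenes for 20 epochs with `lr_max = 3e-3` — enough
for the well-separated default bands to be graded essentially perfectly
in about a minute of CPU time, which is the scale at which structural
claims (shape fidelity, residual identities, gradient correctness,
attention bounds, better-than-uniform localization, ablation wiring,
bit-reproducibility) are meaningfully exercised. The 299-pixel shape
checks and the 137.15 MB audit run on the full reference configuration.

## Known limitations

* CPU-only, double precision, single device; no mixed precision or
  distribution. Full-scale (299 px × 300 epochs × thousands of images)
  training is out of reach here by design.
* The B-stack widths are constrained only by the global parameter-size
  target; other width assignments hitting the same size would be equally
  admissible.
* Grad-CAM on very small feature maps is coarse; choose an earlier stage
  for finer maps.
* The synthetic task is far easier than field photographs; its accuracy
  ceilings say nothing about real-data performance.
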