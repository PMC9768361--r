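---
title: "Mucosal recovery mapping: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mucosal recovery mapping: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(mucorec)
```

## The problem

After endoscopic submucosal dissection (ESD) of an early gastric cancer, the
resected mucosa is pinned, fixed, photographed, and cut into parallel strips
at 2.0–3.0 mm intervals; each strip becomes a glass slide and a whole-slide
image (WSI). A *mucosal recovery map* projects every section's microscopic
findings — cancerous regions (CR) and intestinal metaplasia (IR) against
normal mucosa (NR) — back onto the macroscopic specimen photograph, linking
what the endoscopist saw to what the pathologist measured. Done by hand this
takes an expert on the order of an hour per case. `mucorec` implements the
computational pipeline: tile WSIs into patches, segment each patch with a
convolutional network, reassemble patch predictions into WSI-level
annotations, and place each section's annotation back on the specimen photo.

## Pipeline stages and their models

### Annotation codec (`rgb_mask_to_classmap`, `classmap_to_rgb`)

Annotations are three-color RGB masks: red = cancerous (class 1),
blue = intestinal metaplasia (class 2), green = normal (class 0). Decoding
assigns each pixel the nearest scheme color in RGB space within a
`tolerance` (0–255 scale). Hand-drawn masks have anti-aliased edges; pixels
matching no scheme color within tolerance are conservatively assigned to
class 0 and tallied in a warning, so unknown tissue is never silently
promoted to a lesion class. Pixel values are quantized to 8 bits before
matching, which makes render–decode round trips exact even at tolerance 0.
Class 0 is deliberately the background/majority class so that the
oversampling logic below has a natural reference stratum. We assume CR and
IR annotations are mutually exclusive (the mask format cannot express
overlap).

### Tiling (`tile_slide`, `is_blank`, `stitch_classmaps`, `oversample`)

Slides are split into `tile_size × tile_size` patches (512 px at 10×
magnification, ~1 micron/pixel, for full-scale work) on a stride grid.
Slides rarely divide evenly, so the right/bottom edges are zero-padded to
the next full tile and stitching crops the padding back off; this keeps
every tensor uniformly sized. Coordinates are 0-based `(x, y)` =
(column, row) at tile top-left corners, half-open.

Blank patches carry no tissue and are flagged by an HSV-saturation
detector: stained tissue is strongly colored, slide glass is near-white and
scanner dropouts near-black, both with saturation ≈ 0. A pixel counts as
tissue when its saturation exceeds 0.07 (on [0, 1]); a tile is blank when
its tissue fraction is below 0.05. Both thresholds are configurable; the
defaults are ordinary H&E practice. Filtering is exposed as a flag for both
training and testing splits rather than hard-wired.

Stitching with `stride == tile_size` is an exact partition. With
overlapping strides, per-pixel class probabilities are averaged over all
covering tiles before the argmax; exact ties break to the lowest class
index (deterministic, and conservative because class 0 is normal).

Lesion tiles are far rarer than normal tiles. `oversample` balances
*class-presence strata* (normal-only / CR / IR / CR+IR) by duplicating
minority-stratum tiles with replacement until all strata match the majority
count. Oversampling is patch-level because pixel-level duplication is not
meaningful for segmentation; it never removes tiles, and it is
deterministic given its seed.

### Segmentation network (`network_config`, `build_network`)

The segmentation model is a U-Net whose encoder is ResNet-34: a 7×7
stride-2 stem, 3×3 stride-2 max-pool, then four residual stages of 3, 4, 6
and 3 blocks (total downsampling 32×, hence the input-size divisibility
constraint). Each residual block is two 3×3 convolution + batch-norm + ReLU
units with the block input added back through an identity (or 1×1
projected) shortcut. The decoder has five stages; each upsamples 2×
(nearest-neighbor + 3×3 convolutions, avoiding transposed-convolution
checkerboard artifacts) and the first four concatenate the matching encoder
skip. A squeeze-and-excitation (SE) block — global average pool, C→C/r ReLU
layer, C/r→C logistic layer, channel-wise rescaling by the resulting gates
— recalibrates each decoder stage output (reduction ratio r = 16 at full
width). The head is a 1×1 convolution and per-pixel softmax over the three
classes, which are mutually exclusive by the annotation model.

Where exactly SE blocks belong inside a U-Net is genuinely open; we default
to one per decoder stage output (recalibration applied throughout the
reconstruction path) and expose `se_placement` = decoder / encoder / bridge
/ none so the choice is an ablation parameter rather than a hidden
assumption. `none` is the plain U-Net baseline used in comparisons.

Weights use seeded He initialization, with two deliberate refinements for
training from scratch:

* the final batch-norm gain of every residual branch starts at zero, so
  each block begins as (a projection of) the identity — *residual-branch
  zero-initialization*, a standard deep-residual-network technique. In our
  controlled comparison it roughly halved the optimizer steps needed to
  reach a given accuracy on the synthetic task;
* the excitation output bias starts at +2, so SE gates begin near
  passthrough (`sigmoid(2) ≈ 0.88`) rather than randomly attenuating
  channels. Randomly initialized gates act as strong multiplicative noise
  on the decoder and, in our comparisons, cost the SE network most of its
  early-training accuracy (held-out MIoU 0.62 vs 0.94 under otherwise
  identical 5-epoch runs); gates still differentiate freely from the
  near-passthrough start. (A fully neutral variant — zeroed excitation
  weights, constant gates 0.5 — was also tested and rejected: it blocks
  gradient flow into the first excitation layer.)

Both choices affect only optimization speed, not the converged model class.
Previously trained weights (including externally pretrained encoders) can
be restored from checkpoints; nothing in the package requires a download.

### Loss (`combined_loss`)

Training minimizes the sum of two parts, reported separately:

* **Soft Jaccard distance** `1 − mean_i (p_i y_i + s)/(p_i + y_i − p_i y_i + s)`,
  the per-pixel soft intersection-over-union deficit averaged over pixels
  and class channels. The smoothing constant `s` (default 1) resolves the
  0/0 of empty-vs-empty pixels as perfect overlap — the standard
  soft-Jaccard convention — and keeps the loss differentiable at the
  corners.
* **Cross-entropy** `−(1/N) Σ_i Σ_k y_ik log max(p_ik, clip)` with
  `clip = 1e-7` so hard-zero predictions stay finite. Normalizing by pixel
  count makes the two parts comparable across patch and batch sizes.

Both parts take softmax probabilities `p` and one-hot references `y`; the
total is exactly additive, and gradients are analytic (verified against
finite differences in the test suite).

### Training (`train_config`, `augment`, `train_network`)

The recipe is Adam at learning rate 3e-4, batch size 4, 50 epochs for
full-scale work, with online augmentation per draw: a rotation drawn
uniformly from [0°, 359°] about the patch center (bilinear for the image,
nearest-neighbor for the class map so no fractional classes appear),
integer translations up to 50 px in each axis with reflection padding, and
horizontal/vertical flips at probability 1/2 each. The augmentation order
is rotate → shift → flip. "Shift" is implemented as translation (not crop):
that is the reading consistent with a vertical-and-horizontal shift range.
No early stopping is used; the final model is the last epoch. An optional
held-out fraction (default 0.1) provides epoch-level MIoU monitoring only.
Class weighting is deliberately absent — imbalance is handled by
oversampling, not by the loss.

### Evaluation (`miou`, `dice`, `evaluation_report`)

Per-class IoU is intersection over union of predicted and reference pixel
sets; Dice is `2|A∩B|/(|A|+|B|)`; the two are linked exactly by
`Dice = 2·IoU/(1+IoU)`. Classes absent from both maps are excluded from
class means (avoiding 0/0 and matching common practice). For sets of
patches we report both the pooled score (one confusion matrix over all
pixels — the canonical dataset-level MIoU) and per-patch mean ± sd;
`evaluation_report` additionally aggregates per slide when a grouping is
given, since "±" can reasonably mean either grouping.

### Section mapping (`section_layout`, `refine_layout`, `build_recovery_map`)

Each section is placed on the specimen photo by a rigid similarity
transform: slide pixel `(x, y)` → `anchor + scale · R(rotation) · (x, y)`,
rasterized by inverse mapping with nearest-neighbor sampling so class
labels stay exact. Full deformable registration of strips is a separate
research problem; for the nearly rigid geometry of ESD strips we use rigid
placement from a layout manifest plus a normalized cross-correlation
refinement: an exhaustive integer-translation search (default ±15 px) over
a coarse rotation grid (default ±4° in 1° steps), scoring the Pearson
correlation between the transformed section luminance and the underlying
photo. The refined layout never scores below the initial one; featureless
strips (flat correlation surface) or peaks below 0.2 return the initial
layout flagged low-confidence. The module boundary accepts any drop-in
aligner producing `section_layout`s.

Strips are composited in cut order; where transformed strips overlap, the
lower section index wins (deterministic; physical strips are nearly
disjoint) and the overlap area is logged. Lesion areas are reported in
pixels, and in mm² when a microns-per-pixel resolution is supplied;
without it the summary warns and reports pixels only.

## The synthetic data generator

No public WSI cohort accompanies this problem, so every stage is exercised
on synthetic data with the statistical structure the pipeline assumes:

* **Textures.** Each class is a base stain color plus Poisson-scattered
  darker "nuclei" spots plus Gaussian noise (sd 0.02). Normal mucosa is
  pale pink with sparse nuclei (density 0.002 px⁻¹); cancerous tissue is a
  dark basophilic purple with dense nuclei (0.030 px⁻¹) — hyperchromasia
  and high nuclear density being exactly what makes carcinoma stand out on
  H&E; intestinal metaplasia is shifted toward blue (density 0.010 px⁻¹).
  The three classes are pairwise separated in mean hue *and* spot density
  by construction, margins a small network can learn within a few hundred
  optimizer steps — which is what desk-scale tests require.
* **Lesions.** Smooth connected blobs: ellipses with sinusoidal boundary
  perturbation (amplitudes up to 0.12 of the radius), the shape of
  hand-drawn annotations. Blobs are placed without overlap by rejection;
  infeasible layouts raise an error (or are redrawn, in
  `generate_patch_dataset`).
* **Cases.** A virtual specimen (oval tissue pad on white glass) is cut
  into parallel strips at a 2–3 mm interval and each strip is drawn onto a
  cork-colored board photo at its true position with per-section jitter
  (default ±10 px translation, ±3° rotation) — exactly the perturbation the
  layout refinement must undo. Both the jittered *true* layouts (used to
  render the photo and the ground-truth recovery map) and the clean
  *nominal* layouts (the manifest a user would supply) are returned, so the
  whole mapping stage has an internal oracle. Cases are generated at
  50 microns/pixel — the thumbnail scale at which recovery maps are
  actually assembled — so a 2.5 mm strip is ~50 px wide.

What the generator does *not* emulate: real H&E stain variability and
artifacts (folds, pen marks, bubbles), scanner color profiles, nuclear
morphology, and true tissue deformation during processing (the jitter is
rigid). Passing tests therefore demonstrate that the pipeline's mechanics —
geometry, losses, optimization, bookkeeping, registration — are correct,
not that the shipped defaults reach clinical-grade accuracy on real slides;
that requires real annotated WSIs and the full-scale configuration.

## Study conditions for desk-scale runs

Tests and the acceptance script use a reduced preset
(`reduced_network_config`): the full ResNet-34 block layout at base width
16, decoder channels (64, 32, 16, 16, 8), SE reduction 8, 128 px inputs.
The segmentation comparison trains on 200 synthetic patches (held-out 50)
for 5 epochs at the full-scale optimizer settings, then scores pooled MIoU
and Dice for the SE network against an identically seeded and trained
plain U-Net; the end-to-end experiment uses a 6-section case. One
augmentation parameter scales with the input: the translation range
(0–50 px, calibrated to 512 px tiles) becomes 0–12 px on 128 px patches —
the same fraction of the field of view; rotation is scale-free and stays
at the full circle. These sizes
were chosen as the smallest at which the comparison design is meaningful;
the absolute scores of the full-scale configuration on real data are not
reproducible from synthetic patches and are out of scope here.

## Numerical choices, degenerate inputs, known limitations

* Softmax/argmax ties break to the lowest class index everywhere (stitching,
  prediction), i.e. toward "normal" — deterministic and conservative.
* Batch normalization uses batch statistics in training and running
  statistics (momentum 0.1) in evaluation; evaluation is therefore
  batch-size independent and bit-reproducible.
* The cross-entropy clip (1e-7) and the Jaccard smoothing constant (1) are
  the only loss constants; both are arguments, not magic numbers.
* Empty slides, stride > tile size, non-3-channel masks, duplicate section
  indices, and channel counts indivisible by the SE ratio all raise
  immediate errors rather than propagating silently.
* Training runs on one CPU; there is no GPU path. The CNN engine is a
  self-contained implementation (im2col + GEMM convolutions with analytic
  backward passes) sized for desk-scale experiments and full-scale
  inference, not for training multi-gigapixel cohorts.
* Fixation shrinkage between the pre- and post-fixation photographs is not
  corrected; the recovery map is built on the post-sectioning photo.
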