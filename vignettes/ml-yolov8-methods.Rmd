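---
title: "ML-YOLOv8 in R: model, losses, calibration and synthetic data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ML-YOLOv8 in R: model, losses, calibration and synthetic data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Chinese giant salamanders (*Andrias davidianus*) guard their egg piles in
dark artificial caves, and their parental-care behaviors — tail fanning,
agitating, shaking, egg eating, entering and exiting the cave — predict
hatching success. Monitoring them by hand from infrared footage is slow
and subjective, which motivates a single-stage object detector that
localises the animal and classifies the behavior in one pass. `mlyolo`
implements such a detector: the YOLOv8s architecture plus three
modifications (together, ML-YOLOv8) aimed at low-light, cluttered cave
scenes:

1. **C2f-MSConv** — a multi-scale grouped convolution (MSConv) replacing
   part of the C2f feature extractor;
2. **SPPF-LSKA** — large separable kernel attention inside the spatial
   pyramid pooling layer;
3. **WIoU** — the Wise-IoU bounding-box regression loss in place of CIoU.

Everything runs on the CPU: the package carries its own small
reverse-mode layer engine (Rcpp/Armadillo im2col-GEMM convolutions with
hand-written backward passes, batch normalisation, SiLU, max-pooling,
nearest upsampling) and builds all blocks and the full detector as
graphs over those primitives, so parameter counting, FLOPs accounting,
forward inference and training all share one code path.

## Model

The backbone/neck is the standard 22-layer YOLOv8 layout at the "s"
scale (depth multiple 0.33, width multiple 0.50, channel cap 1024): a
stride-2 convolution stem, C2f blocks at four stages, SPPF at stride 32,
then an FPN–PAN neck fusing strides 8/16/32. The anchor-free head emits,
per scale, `num_classes` classification logits and a discretized
box-distribution branch (`reg_max = 16` bins per box side, decoded by
softmax expectation). Decoding plus per-class greedy NMS (confidence
0.25, IoU 0.45, ties broken by original index) yields detections.

**MSConv.** The input channels are split into four groups (the first
`channels %% 4` groups take the extra channel when indivisible — a
deterministic, order-stable rule) and convolved with 1×1, 3×3, 5×5 and
7×7 kernels, dense within each group; a 1×1 Conv-BN-SiLU fuses the
scales. Dense (rather than depthwise) branch convolutions were chosen
because only they land on the published parameter budget (below).
Inside C2f, MSConv substitutes the *second* 3×3 convolution of each
bottleneck.

**LSKA.** A K×K attention kernel is factorised into a cascade
1×(2d−1), (2d−1)×1 depthwise, then 1×⌈K/d⌉ and ⌈K/d⌉×1 depthwise with
dilation d, then a 1×1 pointwise channel mixer; the result gates the
input elementwise. ⌈K/d⌉ must be odd, because every stride-1 block in
the package honours a "same"-padding contract (spatial dims preserved)
that requires symmetric padding. In SPPF the attention sits after the
pooling concatenation and before the fusion convolution, so it sees all
pooled scales at once.

**WIoU (v1).** For predicted box *B* and target *T*,

\[ L_{IoU} = 1 - \frac{|B \cap T|}{|B \cup T|}, \qquad
   R_{WIoU} = \exp\!\frac{(x_b-x_t)^2 + (y_b-y_t)^2}{(W^2+H^2)^*}, \qquad
   L_{WIoU} = R_{WIoU} \, L_{IoU}, \]

where (W, H) is the size of the smallest box enclosing both and the
asterisk marks that it is excluded from gradient computation. The
package implements analytic gradients honouring this detachment, and
the test suite verifies them against finite differences of an
enclosure-frozen oracle — and verifies that the *non*-detached gradient
differs whenever the enclosure depends on the prediction. The equations
above are the v1 form, so v1 is the default; the v3 focusing variant
(outlier-degree reweighting) is available behind
`wiou_loss(..., focusing = TRUE)` but is not used anywhere else, since
only v1 is unambiguously specified.

## Architecture-budget calibration

Three published budget figures anchor the implementation: baseline
11.16 M parameters, 10.61 M with C2f-MSConv, 11.68 M with SPPF-LSKA
added (the WIoU swap changes no parameters). Three choices are
under-determined by prose alone and were fixed by exhaustive
calibration (`calibrate_placements()`), never revisited afterwards:

* **Head class count.** At 6 classes the baseline counts 11,137,906
  trainable parameters (11.13 M); at the framework-default 80 classes it
  counts 11,166,544 → 11.16 M, matching the table exactly (the printed
  figures are truncated, not rounded, so `params_millions()` floors at
  the second decimal). Budget reproduction therefore uses
  `budget_config()`, which sets 80 classes; behavior detection uses the
  6-class head.
* **MSConv placements.** Only "some" C2f sites are replaced. Enumerating
  all 256 subsets of the eight C2f sites finds two that hit 10.61 M;
  the one whose FLOPs sit closest to the published column is
  {6, 8, 12, 15, 18, 21} (10,614,608 parameters).
* **LSKA (K, d).** Neither is published. Over K ∈ {7, 11, 23, 35},
  d ∈ 2..5 (odd-kernel-feasible combinations only), two settings hit
  11.68 M; K = 11, d = 4 is kept (11,688,784 parameters), matching the
  common K = 11 setting of the attention design this block follows.

FLOPs are counted as 2 × multiply–accumulates over convolution layers
only, batch 1 — the convention under which public YOLOv8s lands near
28.6 GFLOPs at 640². Under it this implementation reports 28.6 / 27.6 /
28.4 GFLOPs for the three ablation architectures, each within 0.3 of
the published column; the parameter counts match exactly. Elementwise
ops, pooling and the box decode are excluded; including them would be a
different (also defensible) convention, but the parameter budgets, not
FLOPs, are what pin the architecture down.

## Training

`fit()` is plain SGD with momentum. Defaults mirror the published
protocol (640² input, batch 16, 300 epochs, lr 0.01, momentum 0.937,
weight decay 0.0005 on convolution weights only); all are overridable
for desk-scale runs. Target assignment is a simple center prior: grid
cells whose centre falls in the inner half of a ground-truth box are
positives at every scale, contested cells go to the smaller box, and a
box that captures no cell anywhere falls back to its nearest cell at
the best-matching stride. The published work does not specify its
assigner; this one is deliberately minimal plumbing, and none of the
quantitative claims reproduced here depend on it. The composite loss is
`7.5 · L_box + 0.5 · L_cls + 1.5 · L_dfl` (box term CIoU or WIoU per
config; binary cross-entropy classification; distribution-focal
cross-entropy on the two bins bracketing each target distance). A
simple 4-image mosaic augmentation exists behind `mosaic = TRUE` with a
configurable disable-near-end epoch count, default off.

Numerical choices: batch-norm eps 1e-3 and momentum 0.03; a 1e-7 guard
on the IoU union and on W²+H² (degenerate-target protection; the
worked loss examples are far from it); not-yet-separated predicted
boxes are nudged to a minimum 1e-3 pixel extent before the IoU loss;
DFL targets are clamped to [0, reg_max−1−0.01]. Training, evaluation
and data generation are deterministic given seeds (private RNG streams
for rendering; a seeded shuffle for epochs), and checkpoints embed the
config plus all parameters and normalisation buffers, restoring
bit-exactly.

## Synthetic data

The real footage is private, so `generate_dataset()` fabricates the
six-class dataset at the published scale: per-class image counts
600/700/500/700/250/250 and a per-class-stratified 8:2 train/test split
(floor on train, remainder to test; the published split is "random
8:2" — stratification is this package's choice so the two 250-image
classes stay represented in test). Each class is a distinct parametric
silhouette whose pose encodes the class (body-plus-fan, S-curve, cross,
ring-with-egg, half-disc at the cave mouth, tapered tail bar), drawn
bright on a dark noisy rock-textured background, with optional blur /
low-light / shadow degradations that never move labels. Boxes are
extracted from the exact silhouette pixel support and written in YOLO
txt format at 6 decimals (write∘read is the identity at that
precision).

What this emulates: class-by-pose separability, low light, clutter,
class imbalance, tight boxes. What it does not: deformable animal
texture, occlusion by eggs, motion blur of real keyframes,
inter-class visual similarity. Passing the smoke test therefore shows
the pipeline can learn pose-distinct classes end to end; it says
nothing about accuracy on real salamander footage, and the published
mAP values are out of reach by construction (private data, GPU-scale
training).

## Desk-scale smoke profile

The engine is CPU-bound R/Rcpp, so the end-to-end check trains a
reduced-width model rather than the 11.7 M-parameter full scale: width
multiple 0.125, 96×96 input, all three modifications enabled, 16
train + 4 test images per class drawn from the generated preset
dataset, batch 8, lr 0.01, 25 epochs, seed 7. In the recorded pilot at
this profile the held-out mAP50 passed 0.5 before epoch 10 (0.65 at
epoch 10, 0.88 at 20, 0.98 at 60) with monotonically decreasing loss;
the acceptance threshold mAP50 > 0.5 is fixed from that pilot. The
budget checks (parameters, GFLOPs) always run at the full "s" scale —
they need no training.

## Known limitations

* Single-threaded CPU inference; a 640² forward pass of the full model
  takes seconds, so real-time use is out of scope.
* The assigner is a center prior, not task-aligned assignment; relative
  loss weighting between scales therefore differs from the reference
  training recipe.
* mAP follows all-point interpolation (the mAP50-95 convention); the
  published ablation table's header reads "mAP@50-90" in one place and
  "mAP50-95" elsewhere — treated as a typographical slip, and
  0.50:0.05:0.95 is used throughout.
* GFLOPs match the published column to ±0.3, not to the printed digit;
  see the calibration section.
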