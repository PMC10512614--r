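---
title: "Staging human oocytes from microscopy images: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Staging human oocytes from microscopy images: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

During ICSI, embryologists stage each retrieved oocyte by its meiotic
maturity before deciding whether to inject it. The stage is read off two
subcellular landmarks in the light-microscope image: a **germinal vesicle
(GV)** marks prophase I (PI, immature), an extruded **first polar body
(FPB)** — sometimes fragmented (FFPB) — marks metaphase II (MII, ready
for fertilization), and the absence of both marks metaphase I (MI).
`oostage` implements a fully automatic two-stage reading of this call:

1. a **semantic segmentation network** extracts binary GV and FPB(+FFPB)
   masks from the grayscale image;
2. a compact **fire-block classification network** receives the two mask
   channels as its input tensor and outputs MI/MII/PI probabilities.

Everything around the two networks — the stratified repeated random
subsampling (SRRS) validation, class-balanced batches, the genetic
refinement of the classifier's filter counts, the analytic FLOPs
accounting, and the full per-class quality-coefficient suite — is part of
the package and individually testable.

Because the underlying clinical image collection is not distributable,
the package ships a **synthetic oocyte phantom generator** that plays the
role of the dataset: every stage of the pipeline can be trained and
evaluated end-to-end on phantoms with exact ground truth.

## The phantom generator

`generate_phantom()` composes an oocyte from concentric ellipses: a
cytoplasm disc inside a zona pellucida (ZP) annulus with the
perivitelline space (PVS) between them. Class-conditional structure
follows the biology strictly:

* **PI** carries a GV disc inside the cytoplasm (area ≈ 11 % of the
  oocyte surface);
* **MII** carries an FPB disc in the PVS (total area ≈ 12 %), replaced by
  2–4 smaller fragments (the FFPB) with probability `frag_prob = 0.15`;
* **MI** carries neither.

Those area fractions are the published morphometric proportions; the
fragmentation rate is a package choice (fragmentation is the less common
presentation, and a modest rate keeps the plain-FPB channel informative
on its own, with the FFPB channel adding a measurable increment — the
same ordering the clinical single-channel scores show).

Two families of **class-independent** content make the raw image honest:

* structural regions (ZP, PVS, clear cytoplasm) and incidental clutter
  (granularity fields, SER clusters, dark cytoplasm, extra polar-body-like
  blobs, cumulus remnants) appear with the same probability in every
  class, so none of their mask channels carries label information;
* the rendered image contains **distractors sharing the landmark
  intensities** — dark vacuoles at the GV gray level, bright refractile
  inclusions at the FPB gray level, and a correlated cytoplasmic texture
  field with darkish and brightish patches at many scales — all present
  with the same statistics in every class. Single pixels are therefore
  ambiguous; resolving a landmark requires its scale, uniformity and
  position together. This emulates the documented failure modes of
  clinical material (granularity in the PVS read as FPB, vacuolated
  cytoplasm read as GV).

The image is rendered at 8 bits with multiplicative brightness jitter
(±10 %), Gaussian blur (σ = 1.5 px) and additive noise (σ = 6 intensity
levels). Masks are exact and never blurred: the ground truth is the
label geometry, not the rendering. Default side is 256 px (desk scale);
any side ≥ 32 px renders the same geometry proportionally.

What the phantoms do **not** model: real texture statistics, optics
(defocus fields, illumination gradients), degenerated oocytes,
multi-oocyte scenes and needle artifacts. Passing phantoms therefore
demonstrates that the machinery is correct and that the two-landmark
signal suffices under controlled conditions — not clinical performance.

## Data path

Records larger than the working resolution are downscaled to
550 × 550 px with nearest-neighbor interpolation (masks stay binary);
smaller records are zero-padded symmetrically (the fixed-shape network
input needs a rule for small images; padding preserves centering and
areas, where stretching would distort the FPB/GV area cues). Tensors
stack the selected channels **in canonical order** regardless of the
order they were requested in; the image channel is scaled to [0, 1].

Augmentation expands each base tensor on a deterministic 12-angle
rotation grid (360/12·(i−1) degrees, center pivot, nearest-neighbor for
masks, bilinear for the image) crossed with 5 random integer
translations; "shifted in the range of 40 px" is implemented as frame
expansion 550 → 590 with per-axis offsets drawn uniformly from 0–40 px,
the only reading consistent with the 590 px input. The grid is cached on
disk; rebuilding with the same seed is a byte-identical no-op.

## Sampling

`srrs_split()` draws, per repetition, fixed per-class validation and
test sets without replacement; the remainder trains. The default plan is
the published one (validation 5/5/5; test 9/58/24), which on the
44/663/59 clinical composition leaves 30/600/30 for training. Training
batches hold exactly 28 representatives per class (batch 84), drawn
with replacement for classes smaller than their quota, and every epoch
re-draws the batch under a deterministically derived epoch seed.

## The classifier family and its refinement

The classifier is generated from a 6-gene **chromosome** of filter
counts (stem 3×3/stride-2 conv; 1×1 conv; fire-block squeeze; fire 3×3
branch; fire 1×1 branch; the two head 1×1 convs share the last gene),
with 0–4 fire blocks. The published refined structure is
`[32, 16, 8, 28, 28, 4]` with one block. The printed layer table has two
internally inconsistent activation rows; the package inserts a 3×3
stride-2 maxpool after the stem (making the printed 294→146→72 chain
propagate) and pads the fire 3×3 branch so both branches concatenate,
with the block pool padded one pixel on the bottom/right (72 → 36).
Dropout before the head is available as a toggle, default off, matching
the final printed table rather than the prose.

FLOPs are counted analytically: output elements × kernel area × input
channels per convolution, MAC = 1 by default (MAC = 2 selectable). The
count is exactly monotone in every gene, in the input side and in block
count, which is the property the refinement relies on.

The genetic search minimizes `OF = 1 − Acc + ΣF / F_max` (F_max = 768)
with one elite copied unchanged per generation; the elite's recorded
score is reused rather than re-evaluated, so the generation-best OF is
non-increasing even under noisy evaluators. Operators are a package
choice (unspecified in the source protocol): tournament selection of
size 2, uniform per-gene crossover, and per-gene ±2k mutation (k ≤ 3,
small steps preferred) clipped to the even grid in [2, 128].

Training uses cross-entropy with Adam (default learning rate 10⁻³;
sweeps use 5·10⁻³ — with only a few dozen gradient steps per run the
larger step is what makes sparse single-channel inputs train reliably).
Weights are He-initialized under a derived seed; all randomness in the
package flows through one `derive_seed()` hierarchy so every artifact is
reproducible from the configuration alone.

## The segmenter

The published pipeline uses a large pretrained encoder–decoder for this
step. The package's backend is a lightweight encoder–decoder trained
from scratch: three stride-2 stages (so the bottleneck's receptive field
covers most of the oocyte — FPB-versus-inclusion is a positional
distinction), nearest-neighbor upsampling, one skip connection, and a
1×1 three-class head. Segmentation always works on an oocyte crop, as
in the source protocol: training crops come from the ground-truth
region support (the stand-in for manual boxes), inference locates the
cell automatically by intensity thresholding against the dark
background (`detect_bbox()`), and predicted masks are pasted back into
the full frame. Inputs are bilinearly resized crops, standardized
to zero mean and unit variance (making the network invariant to the
global brightness changes the augmentation injects) and replicated to
3 channels. Augmentation is uniform random rotation plus ±40 %
brightness jitter. The pixel loss is class-weighted by inverse frequency
by default: with ~6 % foreground and no pretrained features, the
unweighted loss collapses to all-background.

Snapshot selection is lexicographic: highest **detection ratio** (a
region counts as detected when ≥ 100 of its pixels are predicted
correctly, evaluated at source geometry), ties broken by mean IoU, then
by earliest epoch. Prediction decodes per-pixel argmax and restores
source geometry with nearest-neighbor resampling; the two masks are
disjoint by construction. In the pipeline hand-off, predicted connected
components smaller than the same 100 px threshold are suppressed: the
classifier is trained on manual masks where "absent" means exactly zero
pixels, so a 30 px false blob would otherwise flip an MI call, and a
region below the detection threshold is by definition not a detection.
`predict_masks()` itself defaults to the raw argmax.

## Quality coefficients

All coefficients derive from one-vs-rest confusion tallies of a single
multiclass assignment, class-averaged per SRRS repetition and then
averaged across repetitions (unweighted both times). TPR, PPV, FDR and
f1 are standard; PPV + FDR = 1 whenever a class has any positive calls.
The per-class accuracy exists in three conventions because the printed
defining formula (Tp/(Tp+Tn)) is not self-consistent with the published
result tables:

* `"standard"` — binary accuracy (Tp+Tn)/n; the default, consistent with
  the published headline table;
* `"balanced"` — per-class recall, so the class mean is balanced
  accuracy with chance level 1/3; this is the convention under which the
  published single-channel scores sit (a floor of 0.33 and a GV score of
  0.66 = 2/3), and it is what the feature-selection threshold of 0.55 is
  compared against;
* `"literal"` — the printed formula, kept for auditability.

Degenerate denominators yield 0 and set a `degenerate` flag rather than
propagating NaN; the IoU of two empty masks is 1 (needed for MI
phantoms, whose GV/FPB targets are empty by definition).

## Experiment drivers and problem sizes

`depth_sweep()`, `feature_phase1()` and `feature_phase2()` reproduce the
three refinement phases on phantoms. Phase 1 trains one single-channel
network per canonical channel and selects those with mean validation
accuracy (balanced convention) strictly above 0.55; phase 2 adds each
remaining channel to the FPB + GV base. Sweeps use balanced class counts
to isolate channel informativeness from imbalance effects, and train
each SRRS repetition with an independently derived seed, averaging four
repetitions — single-run scores of borderline channels have high
initialization variance that repetition averaging smooths. The swept
structure is the *pre-refinement* width (`sweep_chromosome()`,
64/32/16/32/32/16): the input sweeps historically precede the genetic
filter-count refinement, and the refined structure's 4-filter head
trains unreliably on sparse single-mask inputs at sweep budgets.

One sweep behavior deserves emphasis. On phantoms, the raw-image
channel itself scores **above** the 0.55 threshold (typically
0.55–0.65), joining FPB and GV in the phase-1 selection, whereas the
clinical counterpart of that experiment scored the raw image at chance
level. This is a fidelity limit of the phantom, not a defect of the
selection machinery: an ellipse phantom whose landmarks are segmentable
at desk scale necessarily renders them at contrasts a classifier can
also exploit, while real microscopy texture defeats a from-scratch CNN
given only image-level labels. All twelve clutter and structural
channels do sit at the 1/3 chance floor, and degrading the landmark
rendering until the image channel drops below threshold also destroys
the segmentation stage, so the package keeps the generator honest and
documents the discrepancy instead.

The package's reference experiment (`pipeline_config()` defaults, also
what `scripts/acceptance.R` runs) uses 300 phantoms (100 per class) at
128 px, a 70/10/20 per-class train/validation/test split, a 15-epoch
classifier and a 45-epoch segmenter at 64 px input — sizes chosen so the
full two-stage experiment runs in a few minutes on one CPU core while
still exercising every mechanism at meaningful scale. On these
conditions the ground-truth-mask classifier reaches perfect held-out
accuracy and the two-stage pipeline stays within a few points of it,
reproducing the qualitative pattern of the published evaluation (manual
masks ≥ predicted masks).

## Known limitations

* The convolutional engine is CPU-only and desk-scale by design; it is
  not a general deep-learning framework.
* The segmentation backend is not the published pretrained model;
  absolute IoU values are not comparable to the published ones, only the
  selection machinery and the qualitative behavior are.
* Phantom results bound what the machinery can do under controlled
  conditions; no claim transfers to clinical images without the original
  dataset. In particular, the phantom raw-image channel is genuinely
  class-informative (see above), unlike its clinical counterpart.
* Patient-level grouping is not modeled (records are independent), and
  k-fold cross-validation is out of scope — SRRS is the only validation
  scheme provided.
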