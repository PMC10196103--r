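---
title: "Methods: multi-tissue sellar segmentation and QST classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-tissue sellar segmentation and QST classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(sellarqst)
```

## The problem

Craniopharyngiomas (CPs) are histologically benign but locally aggressive
tumours of the sellar and suprasellar region. The QST taxonomy classifies
them by site of origin — Q (infrasellar/subdiaphragmatic, growing inside an
enlarged pituitary fossa), S (subarachnoidal, arising from the cisternal
segment of the pituitary stalk), and T (pars tuberalis, invading the third
ventricle) — and the subtype informs the choice between endoscopic
endonasal and transcranial approaches. The subtype is confirmed only
intraoperatively; the goal of this package is preoperative, image-based
prediction from a single contrast-enhanced sagittal T1 series.

The pipeline has four stages: (1) seven-class segmentation of the sellar
region (background, tumour, pituitary gland+stalk, sphenoid sinus with its
bony wall, brain, suprasellar cistern, lateral ventricles); (2) extraction
of 34 clinical shape/volume/position features from the label map; (3)
subtype diagnosis by either a nine-item clinical scale or a multimodal
neural classifier; (4) evaluation by per-class Dice and one-vs-rest
sensitivity/specificity/Youden statistics under stratified five-fold
cross-validation.

## Coordinate conventions

All arrays are held in a canonical orientation: axis 1 is the sagittal
stack running left to right, axis 2 runs posterior to anterior, axis 3
inferior to superior ("RAS" voxel order). NIfTI files whose headers carry a
valid qform/sform are reoriented on reading; files without orientation
codes are assumed canonical, since the source convention is then
unknowable. The default spacing, `c(6, 0.45, 0.45)` mm, reflects a 3 T
sagittal acquisition with 6 mm slice thickness and 0.45 mm in-plane pixels;
the strong anisotropy is why segmentation and classification operate on 2D
sagittal slices rather than 3D volumes.

## The synthetic phantom

No patient data ship with the package, so every stage is exercised on a
parametric sellar phantom (`phantom_spec()`, `generate_phantom()`). A
sphenoid-sinus block anchors the scene; its most superior voxel (ties
towards anterior, then the lowest sagittal index) is the tuberculum sellae
surrogate, and the horizontal and coronal planes through it define
"intrasellar" and "anterior to the tuberculum". The brain is a fixed large
ellipsoid, the lateral ventricles and pituitary are ellipsoids whose
voxel counts are set exactly by thresholding the ellipsoid's quadratic form
at the requested volume — so requested volumes are met even when the
tumour compresses them, mimicking how the gland moulds around a mass. The
tumour is built per SI level as an ellipse whose anteroposterior half-width
follows a triangular profile peaking at `widest_level_fraction` of the SI
span (0 = widest inferiorly, a "positive pyramid"; 1 = widest superiorly,
an "inverted pyramid") and pinched to 25% at the ends. Rigid integer
shifts along the AP and SI axes are solved from cumulative voxel
histograms so that the requested `anterior_fraction` and
`intrasellar_fraction` of tumour volume land on the proper side of the
tuberculum planes. Overlaps resolve by priority tumour > pituitary >
cistern > ventricle > sinus > brain, so the cistern can be partly or fully
effaced — which is radiologically legitimate. Intensities are per-class
means plus i.i.d. Gaussian noise (default SD 0.05 on a roughly 0–1 scale).

The three archetypes encode the subtype morphology: Q has a near-invisible
pituitary (0.01 cm^3^), AP 3.0 cm < SI 4.2 cm, an anterior position and
35% intrasellar volume; S has a visible gland, AP/SI = 1.4, 20% of its
volume anterior to the tuberculum, its widest level at 0.25 and no
ventricular dilation; T has a visible gland, 2.5-fold dilated ventricles,
a posterior position, its widest level at 0.75 and almost no intrasellar
volume. Cohorts (`generate_cohort()`) draw subtypes from a mixture
defaulting to 21.8/16.5/61.7% — the prevalence of a 133-patient surgical
series — and jitter each parameter within bounds chosen once so that every
sample stays on its own archetype's side of the scale cutoffs (extents
±7%, pituitary volume ±25–60%, fractions ±25–30%, widest level ±0.1,
centre offsets ±2–2.5 mm). What the phantom does *not* emulate: realistic
MRI contrast and bias fields, anatomical variability beyond parameter
jitter, deformation of neighbouring structures, or ambiguous borderline
tumours. Passing the recovery suites therefore demonstrates that the
pipeline is internally consistent and learnable at desk scale, not that it
attains any particular accuracy on patients.

## The 34 clinical features

For the six foreground tissues: axis-aligned bounding-box extents along
LR/AP/SI (18 features, cm; inclusive of the bounding voxel, so a single
voxel has one voxel-edge of extent) and volumes (6 features, cm^3^).
Tumour position relative to the brain, per axis, as the centroid offset
normalized by the brain's extent (3), and relative to the tuberculum
landmark normalized by the tumour's own extent (3). Then the widest-level
fraction (1), the tumour volume inferior to the tuberculum plane ("in the
pituitary fossa", 1), the tumour volume strictly anterior to the
tuberculum (1), and the AP/SI aspect ratio (1). Extents are bounding boxes
rather than principal-axis lengths — the simplest choice consistent with
calliper-style radiological measurement — and all are measured in 3D, not
on a single slice. The LR position components are reported as absolute
offsets: sagittal handedness carries no diagnostic meaning, and this keeps
the whole vector invariant to a left–right mirror, which the test suite
asserts. Absent tissues yield zero extents/volumes; features whose
*reference* is missing (no sinus for the landmark, no brain) are `NA` with
a `missing` attribute rather than silently zeroed, because absence itself
is diagnostic — a Q-type pituitary is typically invisible.

## The clinical scale

Nine binarized items award fixed points to each subtype; each subtype's
points sum to 16, the diagnosis is the argmax, and ties resolve T > S > Q
(T carries the gravest surgical implications). The printed cutoffs are
strict inequalities: AP diameter < 3.5 cm (Q, 3 points), SI diameter >
3.5 cm (Q, 2), fossa volume < 2.1 cm^3^ (T, 4), anterior volume >
0.8 cm^3^ (S, 3), aspect ratio > 1.1 (S, 4); boundary values score
nothing. The qualitative items need operational definitions, which are
package defaults and configurable via `scale_thresholds()`: "pituitary
clearly seen" at >= 0.1 cm^3^ (an order of magnitude above the Q-type
glands near 0.01 cm^3^ and well below visible ones near 0.45–0.49 cm^3^);
"ventricular dilatation" at a ventricle/brain volume ratio >= 0.02 (about
twice the phantom's normal ratio); anterior/posterior position with a
±0.05 dead zone on the brain-normalized AP offset so a centred tumour
scores neither, since the scale awards anterior points to Q and S and
posterior points to T and a forced binary would double-award ambiguous
cases; widest level inferior below 0.5, superior at or above. An
indeterminate (missing) item scores 0 for every type, and an anterior
tumour awards both Q(3) and S(2) — the scale's columns are read
independently. `find_cutoff()` implements the generic single-threshold
maximum-AUC search (all midpoints, both directions, ties to the lower
threshold) used to calibrate such cutoffs on data.

## The segmentation network

A 2D encoder–decoder on sagittal slices. Each encoder level applies one
3x3 convolution + ReLU and halves resolution by 2x2 max pooling; the
decoder mirrors it with nearest upsampling, skip concatenation, one 3x3
convolution + ReLU, and a 1x1 head emitting 7-channel class scores, with
deep supervision at every decoder level (weights halving per coarser
level, normalized). The distinctive element is the feature-swapping layer
between encoder and decoder: for every configured pair of levels (i, j),
level i's features are nearest-downsampled to level j's grid, projected by
a bias-free 1x1 convolution and added into level j, and symmetrically
level j's features are bilinearly upsampled, projected and added into
level i. All exchanges read the *input* pyramid, so the operation is
simultaneous, shape-preserving, and linear: an empty specification is the
identity, and zeroing the projections reproduces the plain backbone bit
for bit — both asserted in tests. The motivation is class imbalance: the
pituitary and cistern are orders of magnitude smaller than the brain, and
repeated downsampling destroys their localization unless coarse semantic
context and fine positional detail are exchanged explicitly. By default
every level pair is swapped.

The loss is an equally weighted sum of per-pixel cross-entropy and soft
Dice (over all 7 channels, epsilon 1e-6), optimized by Adam (learning rate
3e-3, beta 0.9/0.999). The desk-scale default — depth 3, width 8, 64x64
slices, batch 8, 30 epochs — trains in a few CPU-minutes on ~200 phantom
slices and reaches held-out tumour Dice above 0.9; these problem sizes are
the package's defaults so that the complete property suite runs on a
laptop. Backpropagation is hand-derived and verified against central
finite differences to ~1e-8 relative error; the 3x3 convolutions run
through compiled im2col/col2im kernels. Training is bit-reproducible given
the seed. Prediction block-averages each sagittal slice to the network
size, argmaxes the class scores, and nearest-upsamples back to the input
grid.

## The classification network

The image branch consumes an 8-channel 64x64 stack — the intensity slice
with the largest tumour area plus its one-hot 7-class segmentation,
background channel included — through two conv/pool stages, one residual
block, a 1x1 projection and global average pooling into 32 depth features.
Whether raw image and one-hot map should be stacked as channels or fed
through separate branches is genuinely open; stacking was chosen as the
simpler design and is isolated behind `prepare_inputs()`. The 32 depth
features are concatenated with the 34 clinical features (fused dimension
66, enforced at build time) into a dense discriminator (hidden width 32,
zero-initialized output layer so the untrained network is exactly
uniform) trained with three-class cross-entropy. Clinical features are
imputed (missing to training-fold means) and z-scored per training fold;
evaluation is stratified five-fold cross-validation with out-of-fold
predictions aggregated into one report.

## Numerical choices and degenerate inputs

Dice of two empty masks is 1 by default (a class legitimately absent from
both maps, e.g. an effaced cistern, should not be penalized) and
configurable via `empty_value`. Max-tumour-slice ties resolve to the
smallest index; the widest-level search ties to the lowest level, and a
single-level tumour returns 0.5 (neither pyramid orientation). The
landmark tie chain is superior, then anterior, then lowest sagittal index.
Stratified folds deal each class's shuffled indices cyclically over the
folds, least-loaded first, so per-class and global fold sizes both differ
by at most one. Phantom voxelization keeps requested in-plane tumour
extents within about one in-plane voxel; along the 6 mm sagittal axis a
one-slice discrepancy is unavoidable and tolerated in tests.

## Known limitations

The segmentation and classification networks are desk-scale stand-ins
with the same interfaces and training machinery as their full-scale
counterparts; no pretrained backbone weights are used, and full-scale
accuracy on clinical data is out of scope. The phantom's intensity model
is piecewise-constant plus noise, far easier to segment than real MRI.
The tuberculum surrogate assumes the sphenoid sinus is labelled; maps
without it fall back to flagged-missing fossa/anterior features. The
hypothalamus is not part of the label schema.
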