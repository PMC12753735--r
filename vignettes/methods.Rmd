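---
title: "Methods: segmentation-first blood cell classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segmentation-first blood cell classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The pipeline

`hemosmear` implements a segmentation-first pipeline for peripheral blood
smear microscopy. A smear frame passes through four stages:

1. **Preprocessing** — bilinear resizing, rescaling of byte intensities to
   the unit interval, contrast-limited adaptive histogram equalization
   (CLAHE), and affine augmentation during training.
2. **Semantic segmentation** — a U-Net encoder--decoder produces a
   per-pixel foreground probability; thresholding at `tau` gives a binary
   cell mask.
3. **Instance separation and ROI extraction** — a marker-controlled
   compact watershed on the Euclidean distance transform splits touching
   cells; implausible regions are filtered; each kept region becomes a
   background-zeroed single-cell crop.
4. **Classification** — a lightweight CNN (four 3x3 valid conv + 2x2
   max-pool stages, 653,129 trainable parameters) assigns each crop to one
   of nine classes (erythrocyte, erythroblast, neutrophil, basophil,
   eosinophil, lymphocyte, monocyte, immature granulocyte, platelet) under
   stratified 5-fold cross-validation.

Rationale for the order: pixelwise segmentation removes background and
stain debris before classification, so the classifier solves a fine-grained
single-cell problem instead of scene parsing; the watershed resolves the
overlapping cells that a binary mask necessarily merges.

## Preprocessing choices

**Resize convention.** Bilinear resizing is separable linear interpolation
with half-pixel-centred sampling: output centre `(i + 0.5)/H_out` maps to
source coordinate `x = (i + 0.5) * H_in/H_out - 0.5`, and the intensity is
`(1 - a) I(x1) + a I(x2)` with `a` the fractional part of `x`, applied
along rows then columns. The convention is stated because the worked
interpolation example in the tests depends on it; any convex-combination
resampler keeps intensities inside the source range, which is asserted as
a property.

**Rescaling.** Byte images are divided by 255 exactly. Images carry an
explicit scale flag (`"byte"` or `"unit"`) and `normalize_unit()` refuses
unit-scaled input: double division by 255 is a silent and common bug in
image pipelines, so it is a hard error here.

**CLAHE.** Per-tile histogram equalization with histogram clipping and
bilinear inter-tile blending (delegated to `EBImage::clahe`). The clip
limit defaults to 2 and the tile grid to 8x8 — the widely used defaults,
since neither is dictated by the method itself; both are exposed in
configuration. Equalization is applied on a luma channel by default, with
RGB channels rescaled proportionally, to avoid hue shifts; a per-RGB-channel
mode is available (`clahe_params(channels = "rgb")`). A constant image is
returned unchanged: there is no contrast to redistribute, which also makes
the operator idempotent on constants.

**Augmentation.** Seven operators sampled uniformly from closed intervals:
rotation in [-20, 20] degrees, width/height shift in [-0.05, 0.05] of the
frame, shear in [0, 0.05], per-axis zoom factors in [1.00, 1.05] (a zoom
range of 0 to 0.05), and a fair-coin horizontal flip. The zoom interval
deserves a note: a "zoom range of 0.05" pins the factors to [1, 1.05], and
that reading is used here. The operators compose into a single affine map
about the image centre in the order rotation, shear, zoom, shift, then
flip; the composition order is a package choice since the operators are
listed but not ordered by the underlying method. Resampling is
inverse-mapped nearest-neighbour with clamp-to-edge lookup, which doubles
as the fill rule for exposed pixels. Vertical flip is not part of the
sampled strategy (it can be emulated by setting a 180-degree rotation with
a horizontal flip); augmentation is applied to training folds only, never
to validation or test data — the standard leakage precaution. Masks are
transformed jointly with their images during segmentation training.

## The segmentation network

The U-Net follows the classical layout: four encoder blocks of paired
same-padded 3x3 convolutions (ReLU) with 2x2 max pooling, filter ladder
64-128-256-512, a 1024-filter bottleneck pair, a mirrored decoder using
parameter-free 2x nearest upsampling with skip concatenations, and a 1x1
sigmoid head. Same padding and parameter-free upsampling are forced by the
reference layer table's constant spatial dimensions and zero-parameter
upsampling rows; `build_unet()` reproduces that table row for row
(e.g. 1,792 parameters for the first convolution, 9,438,208 for the second
bottleneck convolution, 65 for the head), and `count_trainable_params()`
audits the closed form `kh*kw*c_in*c_out + c_out` per layer.

**Training policy.** He-initialized weights; Adam with learning rate 1e-3,
beta1 0.9, beta2 0.999, epsilon 1e-7; pixelwise binary cross-entropy on
logits (numerically stable form); batch size 16 by default; early stopping
on validation loss with patience 10 and restoration of the best epoch's
weights; learning-rate halving after 5 stagnant epochs with a floor of
1e-5; L2 penalty 1e-4 on convolution kernels. Validation loss is the
monitored quantity — a package decision, since "early stopping" alone does
not name a monitor.

**Engine.** No deep-learning framework is part of the package's R
dependency set; the networks run on a compact CNN engine written for this
package in C++ (RcppArmadillo): im2col convolution forward/backward, 2x2
max-pooling with argmax bookkeeping, 2x nearest upsampling, dense layers,
dropout masks drawn from R's RNG. All computation is double precision and
deterministic given a seed, which is what makes the end-to-end
reproducibility contract (same config + seed, identical metrics)
testable. Gradients are verified against central finite differences in the
test suite at tolerances around 1e-10.

## Synthetic smears: what they emulate and what they do not

The generator exists so every stage is testable without any external
download. It emulates, per frame: round-ish cells of nine classes with
class-specific radius ranges, body colours, nucleus lobe counts and
granular texture; partial overlap between cells (a designated subset of
cells is placed with a relaxed centre-distance constraint, so the achieved
overlap fraction tracks the target within +/-0.1); a multiplicative
illumination gradient across the frame; and additive Gaussian pixel noise.
Ground truth is exact: an instance map recording, per pixel, the topmost
sprite that produced it, plus per-instance class labels.

The default study conditions are: 128x128 frames, one cell per class,
overlap fraction 0.25, illumination gradient 0.15 (15% relative change
across the frame), and noise SD 4 on the byte scale — values chosen once
as a plausible desk-scale surrogate for stained smear frames. Placement
is rejection sampling with a cap of 100 attempts per cell (bounded
runtime, explicit failure naming the class that could not be placed);
larger cells are placed first, which makes packing reliable, and each cell
is occluded by at most one later cell so every visible instance remains
8-connected.

The class morphology table (radii, colours, lobe counts, granularity) is a
**fixture, not hematology**: values were picked to make the nine classes
pairwise distinguishable by size, colour and nucleus count, in rough
qualitative agreement with Wright-Giemsa appearance, and are documented as
such. Consequently, passing the synthetic experiments demonstrates that
the implementation learns, separates and classifies under controlled
conditions; it does not demonstrate clinical performance on real smears,
which vary in staining, focus, cell texture and morphology far beyond this
generator. Reference results on the real nine-class image collection
(97.10% mean classification accuracy; 98.23% segmentation accuracy, 95.97%
IoU, 97.92% Dice) require that dataset and GPU-scale training, and are out
of scope for the package's own experiments.

## Watershed separation

The binary mask is cleaned by one opening and one closing with a 3x3 box
element (the iteration count is configurable, 1 by default from the stated
1-2 range) and a single hole-filling pass. The Euclidean distance
transform assigns each foreground pixel its distance to the nearest
background pixel. Sure-foreground markers are local maxima of the distance
map under a 7x7 footprint, at or above 0.325 of the map's maximum — the
midpoint of the stated 0.30-0.35 band — thinned so accepted peaks are at
least `min_peak_distance = 7` px apart (greedy, strongest first; ties by
linear pixel index). Two readings of "minimum inter-peak distance 7 px"
are possible — a 7x7 suppression window (Chebyshev radius 3) or a true
7-px separation; the package enforces the true separation, which is what
prevents the saddle points on the neck between two overlapping cells from
seeding spurious regions. Sure-background is the complement of the mask
dilated three times; markers are labelled by 8-connectivity with the
background given its own label.

Flooding runs on the **negated distance map** (peaks become basins) with
compactness 0.001: a candidate pixel's priority is the surface value plus
0.001 times its Euclidean distance from the seeding marker's centroid.
Growth is 8-connected and restricted to the mask; the pop order is
deterministic (priority, then linear index, then push sequence), so tie
pixels are resolved reproducibly. Components that received no marker
(their distance peak fell below the global threshold — typically very
small cells) are labelled as their own regions rather than left
unassigned, and the area filter then judges them. The implementation is
checked against an independent brute-force oracle that computes, per
marker, the minimax path cost to every pixel and assigns the argmin;
agreement is exact away from tie pixels.

**Region filters.** Kept regions must have area in [80, 6000] px,
circularity `4*pi*A/P^2 >= 0.40`, and (by default) no contact with the
image border; every removed region carries its reason codes. Filters are
applied after watershed splitting, on final regions, because they are
post-processing of the separation result. Circularity is
estimator-sensitive: the package uses a weighted chain-code perimeter
(0.980 per axial step, 1.406 per diagonal step along the traced
8-connected boundary), calibrated so rasterized discs of radius >= 10
score in [0.9, 1.0]; an ideal continuous square scores pi/4, and the
rasterized estimate sits near 0.9. A `dense` profile (distance threshold
0.25, min peak distance 9) is available for heavily overlapping material.

ROI extraction multiplies the image by the region mask (background pixels
become exactly zero), crops at the bounding box, pads to a square and
resizes to the classifier input. Instance label maps are written as 16-bit
single-channel TIFF, which round-trips ids up to 65,535 losslessly.

## The classifier

The lightweight CNN input is 64x64x3. That size is forced analytically by
the reference shape ladder — a valid 3x3 convolution maps 64 to 62 and the
conv/pool ladder ends at 2x2x256, flattening to 1024 — and overrides the
general 224x224 preprocessing default; ROIs are resized to 64x64 at
classifier ingress. Dropout rates are not dictated by the reference table:
0.25 after pools 2-4 and 0.5 before the output layer are used, exposed in
configuration. The optimizer and loss are likewise unstated for the
classifier; Adam 1e-3 with categorical cross-entropy mirrors the
segmentation policy. Folds are stratified by default (per-class proportions
preserved within one sample; within each fold the remainder splits
train:validation 75:25); an exact 5-fold partition of 10,124 samples gives
test folds of 2,024-2,025, so a printed test-fold size of 2,048 cannot
arise from an exact partition and the package implements the exact one.
Per-fold models are re-initialized from `seed + fold` for reproducibility.

## Evaluation

Confusion matrices use rows = actual, columns = predicted. Multiclass
precision/recall/F1 are macro averages over one-vs-rest counts (the
averaging scheme is a package decision; macro is reported because the
class balance is near-uniform, making macro and micro nearly equal).
Undefined metrics (zero denominators) are reported as `NA` with a flag,
never as 0. Pixel-level segmentation metrics pool pixels over the
evaluation set (micro), matching single aggregate numbers. IoU and Dice
follow set arithmetic with the empty-vs-empty pair defined as perfect
agreement (1.0); the identity `Dice = 2*IoU/(1 + IoU)` is asserted to
1e-12 as an invariant. ROC AUC is computed per class one-vs-rest by
trapezoidal integration with tied scores grouped (equivalent to the
Mann-Whitney statistic counting ties 1/2); micro pools all decisions,
macro averages defined classes only, warning when a class is absent from
the truth. Cross-fold aggregation is the unweighted mean and SD over fold
rows, formatted to two decimals.

## Grad-CAM

Heatmaps are gradient-weighted class activation maps: channel weights are
spatial averages of the gradients of the target class logit with respect
to a convolutional layer's post-activation feature maps; the rectified
weighted sum is divided by its maximum and bilinearly upsampled to the
input size. The default layer is the last (fourth) convolution — the usual
choice and the one with the largest receptive field; max-normalization is
used rather than min-max so that an all-zero degenerate map passes through
unchanged (with a warning) instead of dividing by zero. The map is
invariant to positive rescaling of the target logit by construction, and
that invariance is asserted as a test. Qualitative claims about which
cytological feature a heatmap highlights are treated as illustrative only;
they are not testable without expert annotations.

## Problem sizes in the package's own experiments

The packaged experiments are sized for a desk machine: segmentation trains
a width-scaled U-Net (ladder divided by 4: 16-32-64-128, bottleneck 256)
on 200 synthetic 128x128 smears with batch size 4 for up to 5 epochs,
evaluating pooled foreground IoU on a held-back subset; the watershed
property uses 200 seeded disc pairs with 20-40% mask overlap; the
classifier trains at full reference width on 100 ROIs per class for up to
10 epochs and is evaluated on a stratified held-out fold. The width scale,
batch size and epoch caps for these scaled runs are the package's own
desk-scale choices; the reference training policy values remain the
defaults of `training_policy()`.

## Known limitations

- The synthetic generator does not model staining variability, defocus,
  debris, red-cell rouleaux, or intra-class morphological variation;
  results on it are upper bounds of convenience, not clinical evidence.
- The watershed inherits the usual failure modes of distance-transform
  markers: elongated distance ridges can seed duplicate markers, and cells
  smaller than the global threshold would lose their markers entirely were
  they not rescued by the unreached-component rule.
- Ground-truth masks for U-Net training on real data are assumed to be
  supplied by the user (the package trains on synthetic masks by default);
  how reference masks for the real collection were produced is not
  specified by the underlying method, and the gap is documented rather
  than hidden.
- The CNN engine is CPU-bound and double precision; it is sized for the
  package's experiments, not for training the full-width U-Net at
  256x256 on tens of thousands of images.
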