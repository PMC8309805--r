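---
title: "mammocad: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mammocad: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Microcalcifications (MCs) are calcium deposits of roughly 0.1-0.7 mm that
appear as bright spots on a mammogram and are among the earliest signs of
breast cancer. Two properties carry the diagnostic signal: the individual
spots themselves, and — more importantly — their *spatial distribution*.
Clustered and segmental (ductal, linear) distributions suggest malignancy;
regional and diffuse/scattered distributions are typically benign. mammocad
implements a complete computer-aided detection (CAD) pipeline around that
signal: preprocessing of DICOM mammograms, offline dataset augmentation,
MC candidate detection with a physical size filter, and benign/malignant
classification with a fully connected depthwise-separable convolutional
neural network (FC-DSCNN) alongside a standard-convolution baseline
(DCNN).

Because clinical mammograms are not redistributable, the package also ships
a phantom generator that renders MC-like spots in the four distribution
archetypes on breast-like backgrounds. Every stage of the pipeline is
developed and measured against those phantoms.

# The phantom model

`phantom_spec()` / `generate_phantom()` render an image in `[0, 1]`:

* **Background**: a constant level (default 0.3) plus a low-frequency
  texture field — white noise on a coarse grid (one node per ~24 px),
  bilinearly upsampled — mimicking parenchymal intensity variation. The
  texture amplitude `texture_sd` defaults to `noise_sd`, so a noise-free
  spec renders an exactly constant background, which keeps degenerate
  test cases exact.
* **Spots**: each MC is a radially decaying Gaussian profile truncated at
  its nominal radius, with `sigma = r / sqrt(2 log 2)` so the *half-peak
  radius equals the nominal radius*: thresholding at half the peak
  contrast and converting the area to an equivalent-circle diameter
  recovers the annotated diameter to within a pixel. Overlapping spots
  combine by maximum, so every annotated center is a local intensity
  maximum in the noise-free image. Diameters are drawn uniformly from
  `diameter_range_mm`, constrained to the physical 0.1-0.7 mm MC band;
  specs whose smallest spot would fall below half a pixel are rejected as
  sub-resolution.
* **Noise**: additive i.i.d. Gaussian noise (default sd 0.03 of the
  dynamic range), then clipping to `[0, 1]`.

Archetype geometry (the source material shows the four patterns but never
parameterizes them, so these are package choices, all configurable):

* *clustered* — centers inside a disk of radius `cluster_radius_mm`
  (default 2.5 mm, capped at 5 mm);
* *segmental* — centers along a random line segment (default 15 mm) with
  perpendicular Gaussian jitter of sd `segment_jitter_mm` (default
  0.3 mm). The jitter deliberately stays below one spot diameter:
  segmental calcifications track a duct, and with larger jitter the
  pattern degrades into a loose band that is visually indistinguishable
  from a regional scatter — which would misrepresent the class it is
  supposed to model;
* *regional* — uniform over a square of side `region_size_mm` (default
  20 mm);
* *diffuse* — uniform over the whole field (minus a margin).

Spot centers are placed by rejection sampling with a minimum
center-to-center distance (`min_separation_mm`, default one largest
diameter plus one pixel) so individual MCs remain countable by the
detector. Labels follow the clinical rule: clustered/segmental = 1
(malignant), regional/diffuse/none = 0 (benign). `generate_dataset()`
derives one deterministic seed per image from a master seed, so datasets
are reproducible bit for bit.

**What the phantoms do not model**: X-ray physics, anatomy (ducts,
vessels, pectoral muscle), masses or architectural distortion, scanner
characteristics, and the intensity statistics of real parenchyma. Passing
the package's tests therefore demonstrates that the pipeline is correct
and that the networks can learn spatial-distribution signal of this kind —
it does not certify clinical performance.

# Preprocessing

`dicom_to_png()` follows the standard acquisition recipe: decode the DICOM
pixel array, preserve the stored integer values exactly (no window/level,
no rescale), write a PNG, and append one patient row (ID, age, view,
source file) to a cumulative CSV. The DICOM reader handles uncompressed
little-endian monochrome objects (explicit or implicit VR), which covers
mammography exports; everything else errors with the offending file named.
PNGs up to 8 bits use the png package; deeper images go through a minimal
16-bit grayscale PNG encoder because the installed writer is 8-bit only —
reading back via `png::readPNG` (an independent decoder) keeps the
round-trip honest, and one test validates the package's DICOM writer
against pydicom.

`resize_image()` uses center-aligned bilinear interpolation (the
INTER_LINEAR convention: source coordinate `(dst + 0.5) * scale - 0.5`,
clamped). The native pipeline target is 320 x 240. The source material
claims aspect-ratio preservation while resizing 4096 x 2047 (~2:1) to
320 x 240 (4:3); since its own algorithm listing fixes the output size,
the package resizes directly to the target without padding.

Channel conversions implement the two published formulas: the average
method `G = (r + g + b) / 3` and the weighted method
`NG = r Pr + g Pg + b Pb` with weights summing to 1. The weights are
never specified at the source; the default is the BT.601 luma convention
(0.299, 0.587, 0.114) that mainstream imaging libraries apply, and
uniform weights reduce the weighted method to the average method exactly.
`gray_to_rgb()` replicates a single plane three times — the network input
is H x W x 3 even for grayscale mammograms.

Shapes are reported height x width (x channels), row-major, matching the
published layer tables.

# Augmentation

Offline inflation rotates each image at 45, 90, 180 and 360 degrees and
keeps the original: five outputs per input, so 425 benign + 152 malignant
originals become 2125 + 760 = 2885 images, and class proportions are
invariant. Notes on the two deliberate quirks:

* the 360-degree copy duplicates the original; it is retained because the
  published arithmetic (577 x 5 = 2885) requires it;
* cropping and flips are also mentioned as offline augmentations at the
  source, but the five-image count leaves no room for them; flips exist
  in `augment_plan()` but default to off.

Rotation fits the full rotated extent into the frame (no corner
cropping, zero fill) and resizes back to the target size. Multiples of
90 degrees take exact index-permutation paths, so the identities tested
(360 = identity, 180 an involution, 90 = permutation oracle) hold without
interpolation error; only genuinely oblique angles interpolate.

On-the-fly training augmentation (random small rotations, shifts, flips)
is implemented in the trainer behind `online_augment`. It is off by
default: at the scaled-down 24 x 32 input used in the package's own
study, resampling 1-2 px spots through oblique rotations smears away the
very signal being classified (measured: training collapses to chance),
so the offline protocol is the supported default at desk scale.

# Candidate detection and ROI extraction

The source pipeline relied on radiologist-labeled ROIs; the package
substitutes a classical, fully parameterized detector so it can run
unattended: white top-hat filtering (image minus its opening with a disc
slightly larger than the largest MC — default 0.9 mm), a robust relative
threshold `median + k * MAD` (k = 3) with an absolute floor of 0.02 for
the noise-free limit, then connected components. Component size is
summarised as the equivalent-circle diameter `2 sqrt(area / pi) *
spacing`; candidates outside the published 0.1-0.5 mm ROI band are
discarded. On noise-free phantoms the detector attains recall 1.0 with
centers within 1 px and diameters within one pixel-equivalent.

`translate_pixels()` implements the published pixel-translation utility
(integer `(Bx, My)` shift, zero fill). The source text subscripts the
shift by class (benign x, malignant y) but never uses that reading again;
the package implements the plain translation and leaves the
class-conditional interpretation aside. `extract_roi_patches()` cuts
even-sized square patches centered on candidates (candidate pixel at
position `patch_px / 2`), zero-padded at borders, each carrying the
image-level label. Whole resized images are the default classification
input (the published input shape is the full 240 x 320 x 3 frame); the
patch path supports ROI-level experiments.

# The networks

Both classifiers are declared as `network_spec` objects and verified by
symbolic shape propagation (`shape_trace()`), which reproduces every
published output-shape cell:

| stage | FC-DSCNN | output (240 x 320 x 3 input) |
|---|---|---|
| conv 32 + BN, pool | separable | 240x320x32 -> 120x160x32 |
| (conv 64 + BN) x2, pool | separable | 120x160x64 -> 60x80x64 |
| (conv 128 + BN) x3, pool | separable | 60x80x128 -> 30x40x128 |
| flatten, dropout 0.5 | | 153600 |
| dense 256 (ReLU), softmax | | 256 -> 2 |

The DCNN is the identical topology with standard 3 x 3 convolutions. All
convolutions use "same" zero padding (inferred: the published tables show
spatial size preserved at stride 1) and odd kernels; pooling is 2 x 2
with floor division. Batch normalisation follows each convolution, per
the published row order (conv with ReLU, then BN). The "3 x 3 x 32"
kernel notation in the tables is read as 3 x 3 spatial kernels with 32
output filters.

The depthwise-separable convolution itself — the architectural
contribution — is implemented from first principles in C++: stage one
convolves each input channel independently with its own `kh x kw` filter;
stage two mixes channels at every pixel with 1 x 1 filters. Its
parameter count per layer is `9C + CF + F` against `9CF + F` for a
standard convolution; over the six-layer stack that is 51,515 vs 425,344
weights, the efficiency argument for the factorised design. Correctness
is pinned by 100 randomized comparisons against a nested-scalar-loop
oracle (tolerance 1e-6) and by a full finite-difference check of the
backward pass during development.

# Training

`train_config()` carries the published hyperparameters: batch size 32,
AdaGrad at learning rate 0.001 decayed by 0.1 every 5 epochs, dropout
0.5, 20 epochs, sparse categorical cross-entropy, random seed 42.
Decisions where the source is ambiguous or silent:

* **Splits**: the prose says 60/20/20 train/validation/test, the
  hyperparameter table says 0.8/0.1; the package defaults to the prose
  and both are expressible in `split_plan()`. Splits are stratified by
  class, deterministic under the plan seed, and carry a stratified
  `fold` column for 5-fold protocols; whether the published five-fold
  procedure wrapped or replaced the 60/20/20 split is never reconciled
  at the source, so both modes exist and neither is asserted as the
  original protocol.
* **Class weights**: the published "class weight [-1, 1]" is not
  interpretable as loss weights; since the stated purpose is the class
  imbalance, the package uses inverse-frequency weights normalised to
  mean 1 (the original string is kept in the config for provenance).
* **Optimizer internals**: AdaGrad accumulator epsilon 1e-7; He-normal
  weight initialisation for ReLU layers, Glorot-scaled softmax; batch
  norm epsilon 1e-3.
* **Batch-norm inference statistics**: with only a few dozen gradient
  steps, an exponential running average of the batch moments is still
  dominated by its initialisation, which wrecks inference-mode
  predictions while training-mode accuracy looks fine (measured: 0.91 vs
  0.50 on the same data). After each epoch the trainer therefore
  re-estimates the population moments with one clean forward pass over
  up to 256 training images ("precise BN"). This made inference match
  training behaviour and is always on.
* **Operating point**: screening CAD runs sensitivity-first.
  `choose_threshold()` picks the highest threshold reaching a target
  sensitivity (default 0.95) on a *calibration set the model never
  trained on* — scores on the training data themselves are overconfident
  (the fitted network separates them almost perfectly), which pushes the
  threshold far too high for unseen images. The study protocol therefore
  carves a stratified 20% calibration subset out of the training split.
  Validation data play no role in the choice.
* **Test-time view averaging**: `predict_proba(..., tta = TRUE)` averages
  predictions over the four shape-preserving dihedral views (identity,
  horizontal flip, vertical flip, 180-degree rotation — exact index
  permutations). The distribution archetypes are invariant under these
  views, so averaging reduces prediction variance at no modelling cost;
  oblique-angle augmentation is deliberately *not* used at inference for
  the same resolution reason it is off during training.

Divergence (non-finite loss) aborts with the epoch index. The training
loop, like every stochastic component, is reproducible from the config
seed.

# Evaluation

`full_report()` reports sensitivity, specificity, accuracy, F1,
precision, recall, FPi and AUC with malignant (= class 1) as positive.
Sensitivity and recall share one formula and are reported as one number
(the published results table lists them as different values, which is
arithmetically inconsistent with its own definitions; the package does
not emulate that). FPi is computed imagewise: FP divided by the number of
evaluated images. AUC is the trapezoidal area under the threshold-sweep
ROC, with tied scores moving diagonally, so a constant score yields 0.5;
it is verified against O(n^2) Mann-Whitney pair counting (and against
pROC) to 1e-12. Zero-denominator metrics raise explicit errors from the
scalar functions; `full_report()` maps them to `NA` and keeps the rest.

# The scaled-down study

The published headline results (sensitivity 0.99 at 2.45 FPi) came from
private clinical data and GPU-scale training and are out of reach at desk
scale. The package's own end-to-end study, run by the acceptance script
and the test suite, is:

* 400 phantoms (200 benign / 200 malignant), rendered *natively* at the
  24 x 32 network input, 0.4 mm/px (a 9.6 x 12.8 mm ROI-scale field),
  spot diameters 0.4-0.7 mm so every MC stays above the resolution
  limit, 8 spots per positive-bearing image, cluster radius 2.5 mm,
  segment length 8 mm, region 10 mm, centers at least one diameter
  apart;
* stratified 60/20/20 split (seed 42); the training split is divided
  80/20 into fit and calibration subsets; the FC-DSCNN is trained 20
  epochs with the published hyperparameters on the fit subset; the
  operating threshold is chosen on the calibration scores at target
  sensitivity 0.95; predictions average the four shape-preserving views;
* validation sensitivity and AUC are required to reach 0.9.

The native-resolution choice matters: rendering larger phantoms and
downscaling to 24 x 32 dilutes each spot's contrast by the area ratio
(measured early in development: a 10x downscale pushed validation AUC to
~0.59; 2x to ~0.83), which tests the resampler, not the classifier. The
problem sizes (400 images, 24 x 32, 20 epochs, single CPU, a few
minutes) were chosen so the whole study runs comfortably inside a test
suite.

# Known limitations

* The phantom generator models spot geometry and first-order image
  statistics only; conclusions transfer to clinical data only as far as
  spatial-distribution signal is the operative cue.
* The DICOM reader covers uncompressed little-endian monochrome
  transfer syntaxes only.
* The network engine is a correct reference implementation, not a fast
  one: it is single-threaded C++ with R orchestration, suitable for the
  scaled-down study, not for 240 x 320 training runs.
* 5-fold cross-validation is provided as fold bookkeeping; the package
  does not re-implement the full published protocol because its exact
  shape (wrapping vs replacing the split) is unspecified.
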