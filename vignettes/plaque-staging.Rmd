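---
title: "Staging atherosclerotic plaque from CARS microscopy: methods and design"
author: "carsPlaque"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Staging atherosclerotic plaque from CARS microscopy: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carsPlaque)
```

## The problem

Coherent anti-Stokes Raman scattering (CARS) microscopy images lipid-rich
structures label-free by matching the CH-bond vibrational frequency, which
makes the lipid-laden macrophages ("foam cells") of atherosclerotic plaque
directly visible as bright clusters on a dark arterial background.
`carsPlaque` implements an automated pipeline that takes 16-bit grayscale
CARS images and assigns each one of three lesion stages of increasing
severity:

* **EFS** — early fatty streak development: sparse, dim, scattered
  foam-cell clusters;
* **EF** — early fibroatheroma: a mixture of immature (dim) and mature
  (bright) lipid pools gathering around a few foci, classically the
  hardest stage to identify;
* **AA** — advancing atheroma: a dense, bright, coalesced accumulation of
  extracellular lipid.

Complex lesions (AHA types V/VI, collagenous caps, thrombosis) are out of
scope: they require a collagen-sensitive channel that CARS alone does not
provide.

The pipeline has five stages, run in order: preprocessing, four parallel
segmentation methods, a 27-feature morphology panel, two feature-refinement
methods, and three tuned supervised classifiers. `runPipeline()` executes
the full cross product (4 segmenters x 2 selectors x 3 classifiers) and
reports a summary row per combination.

## Preprocessing

`adjustContrast()` linearly maps the `lowFraction` and `1 - highFraction`
intensity quantiles to the representable range, saturating the tails;
`sharpen()` applies an unsharp mask,
`clip(img + amount * (img - gaussianBlur(img, radius)))`. Defaults are 1%
saturation at both tails, blur sigma 1.5 px and amount 0.8 — conventional
values for histogram stretching and unsharp masking; the method this
package follows names no numbers for either, so these are package
defaults, configurable in `pipelineConfig()`. All arithmetic is floating
point, rounded and clipped back to the integer grid once per operation to
avoid cumulative quantization.

Preprocessing exists to help *segmentation*. Feature extraction reads
intensities from the **raw** image under the segmented mask: the per-image
quantile stretch would erase the cross-image intensity scale that mean
intensity and integrated density depend on (a stretched EFS image and a
stretched AA image both span the full range).

## Segmentation

Four methods isolate plaque from background; foreground is always the
high-intensity phase.

**OTS** (`otsuSegment`) — the threshold maximizing between-class variance
over a 256-bin histogram of the image's own min–max range; the mask is
all pixels strictly above it. The bin count is a package decision (the
histogram resolution is not stated by the method source).

**IFCT** (`ifctSegment`) — independent foam-cell thresholding: a
permissive global seed threshold (quantile 0.75) proposes candidate
clusters; each candidate's bounding region is re-segmented by its own
local Otsu threshold; the per-region masks are unioned and components
under `minArea` (10 px) dropped. Candidate regions whose bounding box
shows no genuine bimodality (Otsu separability below 0.8, see below) are
discarded, which is what makes a background-only image yield an empty
mask. The exact original procedure is only sketched in the method's text;
this realization follows the description "individually segmenting foam
cell clusters".

**MCW** (`mcwSegment`) — marker-controlled watershed: foreground markers
are regional maxima of the sigma-2 Gaussian-smoothed image separated by at
least `markerMinDistance` (13 px) and above the global Otsu threshold; the
background marker is every pixel below that threshold; Meyer
priority-flood watershed then partitions the Sobel gradient magnitude of
the smoothed image. The mask is the union of non-background basins with
one-pixel watershed lines kept between touching foreground basins (so
merged clusters stay separable) and small components removed. The flooding
is implemented in C++: seeded region growing by path cost (as in
`EBImage::propagate`) is not a watershed and placed boundaries far inside
the blobs when we evaluated it.

**KMS** (`kmsSegment`) — k-means (k = 2) on per-pixel texture vectors:
Gabor magnitude responses at frequencies {0.05, 0.1, 0.2} cycles/px times
orientations {0, 45, 90, 135} degrees, each smoothed with a sigma-3
Gaussian, plus the pixel intensity. Channels are standardized and the
intensity channel is weighted by the square root of the bank size so it
carries the same total energy as the twelve Gabor channels — without this
the smoothing halo around small clusters dominates the clustering and
inflates masks. Clusters whose mean intensity exceeds the image mean are
reported as plaque; k-means is seeded, making KMS the only stochastic
segmenter.

**Reference masks.** When no ground truth exists, `traceReference()`
evolves an initial mask by a discrete region-based (Chan–Vese energy)
active contour: per iteration the mean intensities inside and outside are
recomputed and pixels in a one-pixel band around the boundary flip to the
closer region. The pipeline seeds it with a dilated Otsu mask.
Segmentation agreement is scored by the Dice coefficient
`2|A∩B| / (|A|+|B|)`, with `dice(∅, ∅) = 1` (agreement on absence), on a
seeded random subset of up to 50 images per stage group.

**Plaque-free images.** Global thresholding splits *any* histogram, so a
blank image would never produce an empty Otsu mask. We use the Otsu
separability (effectiveness) measure — between-class variance at the
chosen threshold over total variance — to recognise images with no real
foreground/background structure. On our phantoms, blank background noise
scores at most about 0.73 and genuine plaque at least about 0.86 (see
`otsuSeparability`); `classifySingle()` and IFCT use 0.8 as the floor.

## The 27-feature panel

For each segmented plaque, `extractAll()` concatenates, in a fixed
canonical order (`featurePanelNames()`):

* **6 first-order statistics** of masked intensities: mean, object count
  (8-connected components of the mask, a surrogate for the number of
  lipid cells, with no size floor), skewness, kurtosis (Pearson
  convention, normal = 3), sample standard deviation, and integrated
  density (sum of masked intensities). Zero-variance regions take
  skewness = kurtosis = 0.
* **4 shape descriptors** of the mask union: area (px²), circularity
  `4π area / perimeter²`, perimeter, extent (area over bounding-box
  area). Perimeter uses the corrected chain-code estimator (weights 0.980
  per axial step, 1.406 per diagonal step, −0.091 per corner) over
  `EBImage::ocontour` boundaries, so large digital disks score
  circularity near 1. Multi-component masks sum area and perimeter and
  use the union bounding box.
* **17 Haralick texture statistics** from gray-level co-occurrence
  matrices: autocorrelation, cluster prominence, cluster shade, contrast,
  correlation, difference entropy, dissimilarity, energy, entropy, the
  two information measures of correlation (IMC1, IMC2), maximum
  probability, sum average, sum entropy, sum-of-squares variance, sum
  variance, homogeneity. A 9x9 window slides over every pixel whose
  centre is in the mask (mirror padding at image borders); co-occurrences
  are accumulated symmetrically at distance 1 for the four standard
  orientations; the 17 statistics are computed per orientation and
  averaged, then averaged over all window centres. Natural logarithms
  with 0·log 0 = 0; degenerate (single-entry) matrices give correlation,
  IMC1 and IMC2 of 0.

Numerical choices: 16-bit input is quantized once per image to 32
equal-width gray levels over the image's min–max range — 32 levels keep
9x9 windows (144 symmetric pair counts per orientation) from being
vanishingly sparse, while the window size and the four orientations follow
the protocol this package implements. The offset distance is fixed at
1 px. Averaging *features* over orientations is the default; pooling the
co-occurrence counts first is available as
`glcmConfig(averaging = "matrices")`. The sliding-window accumulation is
implemented in C++ (`src/texture.cpp`); the exported `computeGLCM()` and
`haralickFeatures()` give the same quantities in plain R for single
windows, and the test suite holds the two paths to each other and to a
naive double-loop oracle.

## Feature refinement

**CV selection** (`cvSelect`) — the interclass coefficient-of-variation
rule: per feature, take the three class-conditional means and compute
`CV% = 100 · sd(class means) / mean(class means)` with the sample (n−1)
standard deviation over the three means; retain features with CV strictly
above 8%. Class means of (90, 100, 110) give exactly 10% (retained);
(95, 100, 105) give 5% (dropped). CV is computed on raw feature values —
it is scale-invariant, so normalizing first would change nothing. A
feature whose grand mean is exactly 0 has an undefined CV; it is assigned
+Inf and retained, with a warning.

**FTF selection** (`ftfSelect`) — chi-square filter-type selection: each
feature is discretized into 10 equal-frequency bins (degenerate bins
merged), the chi-square statistic of the bin-by-class contingency table
is computed, and features are ranked by ascending p-value (ties by
descending statistic, then canonical order); the top 15 are retained. No
multiple-testing correction is applied: FTF is a ranking, not an
inference. Constant features score 0 and rank last.

## Supervised staging

`splitDataset()` makes a stratified 60/20/20 train/test/validation split
(largest-remainder rounding per class, ties resolved train, test, then
validation). `tuneAndTrain()` minimizes stratified 10-fold
cross-validation misclassification over a seeded random search (default
30 draws) of the algorithm's space:

* **kNN** — neighbours 1..25, Euclidean or Manhattan metric
  (`e1071::gknn` on standardized features);
* **DT** — `rpart` with maximum depth 1..15, minimum leaf size 1..15,
  minimum parent size 2..40, complexity parameter log-uniform on
  [1e-4, 0.1]. The original tree controls "number of splits" and "parent
  size" map onto the complexity parameter and `minsplit` here — an
  interpretation, since those names come from a different numeric
  environment;
* **MCSVM** — a one-vs-one error-correcting output-code SVM: three
  pairwise radial-kernel binary SVMs (`e1071::svm`, box constraint
  log-uniform [0.1, 100], kernel width log-uniform [1e-3, 1]); prediction
  is by majority vote, with voting cycles broken by the largest aggregate
  signed margin over the learners involving each class.

Random search replaces the original Bayesian optimization: the same
interface, the same spaces and budget semantics, but reproducible from a
single integer seed and free of acquisition-function settings the source
never reports. The best configuration is refit on the full training
table. `evaluateModel()` reports the 3x3 confusion matrix, per-class
accuracy (correct-in-class / class size, i.e. recall), one-vs-rest
precision/recall/F1, macro averages, and a **generalization error**
defined as training accuracy minus mean cross-validation accuracy — the
source uses the term without a formula, so this definition is a package
decision, chosen because it measures exactly the train/validation gap
that diagnoses overfitting.

## The phantom generator

The image data this method was developed on (566 CARS images of rabbit
aorta: 214 EFS, 134 EF, 218 AA) is not publicly deposited, so
`generatePhantom()`/`generateDataset()` synthesize foam-cell images with
per-image ground-truth masks and labels. What it emulates:

* foam-cell clusters as isotropic Gaussian-profile discs
  (`L · exp(−d²/2r²)`) with a hard support at one standard deviation, so
  blobs read as bright plateaus with steep rims, as foam-cell clusters do
  in CARS; the truth mask is the union of supports. We deliberately chose
  the support at 1σ rather than a wider skirt: with a 2σ support, most of
  each blob's ground-truth area lies below any defensible threshold and
  the strongest gradient ring sits at half the support radius, so no
  threshold or gradient-watershed method can recover the nominal truth —
  the benchmark would measure the phantom, not the segmenters.
* overlapping blobs combine by pixelwise maximum: CARS signal saturates
  within a dense lipid cluster, and summation would make scattered-blob
  images (EFS) the most skewed and heavy-tailed class, inverting the
  stage phenomenology;
* stage archetypes: blob count falls and blob radius, peak intensity and
  clustering rise from EFS to AA, so mean foreground intensity, lesion
  area, integrated density and compactness (fraction of foreground in
  the largest connected component) all increase with stage. EFS centres
  scatter uniformly; EF gathers around 3 foci; AA coalesces around 1.
* the EF stage is a *mixture of EFS-like and AA-like components*: dim
  immature blobs (16 000 at defaults) and bright mature blobs (32 000,
  near the AA level), with the per-image bright fraction drawn from a
  Beta distribution (mean 0.3, concentration 4). Single EF images
  therefore shade into both neighbouring stages — which both produces
  the highest intensity skewness and kurtosis of the three classes and
  makes EF the intrinsically hardest class, as expected of the
  intermediate lesion. The dim level is kept well above the EFS level so
  dim blobs stay visible to global thresholding; pushing it down to the
  EFS level itself would put the dim population below the global Otsu
  threshold of bright-containing images and make the ground truth
  unrecoverable by any of the implemented segmenters.
* noise: Poisson shot noise on the pre-clip signal plus Gaussian read
  noise (SD 100) over a background level of 800, then rounding and
  clipping to the 16-bit grid.

`strongSeparationConfig()` is the benchmarking preset: stage archetypes
pulled far enough apart that the interclass CV of mean intensity,
integrated density and area clearly exceeds the 8% threshold. The
acceptance benchmark (150 images per stage at 128x128, everything seeded)
runs the full chain on it.

What the phantom does **not** emulate: optical point-spread and resonant
background of CARS contrast, vignetting and illumination gradients,
anatomical context (vessel wall, elastin autofluorescence), non-circular
cluster morphology, pixel-size calibration (all geometry is in pixels —
the source states no calibration), or 3-D structure. Passing the phantom
benchmark therefore demonstrates that the pipeline's machinery recovers
known structure under controlled conditions; it does not certify
performance on real rabbit or human tissue, and the headline accuracies
on phantoms are not comparable to accuracies on the original dataset.

## Problem sizes used by the tests and the acceptance benchmark

Unit tests run on 48–96 px phantoms with a handful of images per stage;
the oracle-equivalence suites use 1 000 random 16x16 images (Otsu) and
1 000 random co-occurrence matrices (texture). The end-to-end benchmark
uses 150 images per stage at the 128x128 default — large enough that
stratified 60/20/20 splitting leaves 30 test images per class, small
enough to run on a single CPU in minutes. These sizes are the package's
benchmarking choices.

## Known limitations

* The IFCT realization follows a one-sentence description; the original
  supplementary specification was not available, and other readings are
  possible.
* Whether the original Dice evaluation scored one plaque region per image
  or whole masks is unstated; we score whole-mask versus whole-mask.
* The EF ordering of the `intensity` slot uses the mixture mean; with
  extreme user-supplied mixture settings the per-image mean can stray
  far from it.
* Class imbalance is neither modelled nor corrected (the emulated study
  reports none); labels enter as hard assignments with no observer
  uncertainty.
* `generalization_error` as defined here is small for well-separated
  phantoms; its magnitude is not comparable to gap statistics computed
  under other definitions.
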