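---
title: "Estimating tumour cellularity from H&E patches: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating tumour cellularity from H&E patches: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

After neo-adjuvant chemotherapy, pathologists grade the response by the
residual tumour cellularity (TC): the fraction of a tissue patch's area
still occupied by malignant cells. Scoring is done by eye on
hematoxylin-and-eosin (H&E) slides, patch by patch, and is slow and
rater-dependent. `patchCellularity` implements a classical
computer-vision pipeline that automates the score on 512 x 512 px
patches at 20x magnification (0.5 um/px): colour separation, nuclei
segmentation, morphological feature extraction at three spatial levels,
key-parameter selection against pathologist TC labels, benign/malignant
nucleus classification, and a dilation-based area score.

Everything is testable without clinical material: a synthetic phantom
generator plants nuclei with pixel-exact ground truth (label maps,
classes, and a known TC), and the whole test suite and the acceptance
script run on phantoms alone.

## Colour separation

H&E renders stroma pink, nuclei blue-purple and background/fat white.
Each pixel's HSV triple (all channels on [0, 1]) is clustered with
k-means (k = 3, Lloyd iterations from a seeded k-means++
initialisation, so results are reproducible bit for bit). Roles are
assigned deterministically: the centroid with the largest
value-minus-saturation is the background plane `Iba`; of the remaining
two, the centroid whose hue is circularly closest to pink (0.95 on the
hue circle, wrapping at 0/1) is the stroma plane `Ip`, the other the
nuclei plane `Ib`. Clustering runs per patch; nothing is fitted across
patches.

A separate pink filter flags stroma by an HSV box
(H in [0.85, 1] + [0, 0.05], S in [0.05, 0.6], V in [0.5, 1] by
default); its flagged fraction is the "stroma filter mean" feature.
The interval is configuration, not dogma — real scanners and stains
will need their own box.

## Nuclei segmentation

The grayscale luminance `Io` and its 3 x 3 median-filtered version `Im`
are combined into an enhanced image

    In = (K1 * Io * Im + K2 * Io + Im^0.1) / (K1 + K2 + 1)

with defaults `K1 = 0.7, K2 = 0.3`. The product term darkens dark
regions quadratically, the gamma term (exponent 0.1) lifts the
background, so nuclei end up darker and the background lighter. Each
additive term is bounded by 1 on [0, 1] inputs; dividing by
`K1 + K2 + 1` — the transform's theoretical maximum — keeps the image in
[0, 1] *without* saturating the background. We tried hard clipping
first: it flattens everything bright to 1.0 and destroys exactly the
contrast the transform exists to create, so the affine rescale is the
package's choice.

`In` is thresholded by Otsu's method (an in-package, exhaustive
between-class-variance maximiser over a 256-bin histogram; ties go to
the lowest split) with the dark class flagged as nuclei. Two gates
protect degenerate inputs, since Otsu always splits *something*:

* **Contrast gate** (default 0.08): on a blank textured patch the
  "dark class" is just the lower half of the noise; its mean gap to the
  light class is tiny and the patch is declared nucleus-free. Without
  the gate, thresholded noise percolates into huge fake regions.
* **Haematoxylin gate** (default 15 intensity units): nuclei are
  haematoxylin-stained, i.e. blue. The dark class must exceed the
  light class in blue excess `B - (R + G)/2` by the margin. On a
  nucleus-free patch containing fat, Otsu prefers the stroma|fat split
  and the "dark" class is pink stroma — no bluer than fat — so the gate
  rejects it. When the gate rejects the first split on a patch that
  *does* contain nuclei (a trimodal histogram: few dark nuclei, much
  mid stroma, some bright fat), a second Otsu pass restricted to the
  dark class recovers the nuclei|stroma threshold and is accepted if it
  passes the gates.

Touching nuclei are split by a watershed on the Euclidean distance
transform of the mask, with markers from regional maxima after an
h-maxima suppression of 2 px (8-connectivity); regions under 20 px^2
(sub-lymphocyte at 0.5 um/px) are dropped and labels renumbered. The
whole segmentation is seedless and deterministic. Validation against
reference masks uses the Jaccard index (two empty masks score 1, the
perfect-agreement convention).

## Feature extraction

One row per segmented nucleus, no missing values, >150 feature values
per row counting window replicates:

* **Nucleus geometry**: area, 4-connected boundary-pixel perimeter,
  roundness `4*pi*A/P^2` (discretisation can push it slightly above 1;
  reported as-is), centroid (0-based, x = column), and the
  equivalent-ellipse major/minor axis, eccentricity and orientation
  from second central moments.
* **Nucleus texture and colour**: grey-level co-occurrence contrast and
  homogeneity at offsets (0,1) and (1,0) — two offsets for the two
  numbered features — on 8 grey levels, symmetric and normalised,
  computed inside a 3 x 3-eroded sub-region of the cell body (falling
  back to the whole nucleus when erosion empties it), plus mean H/S/V
  there.
* **Regional concentrations**: for windows of 30/60/90/120 px centred
  on the rounded centroid, the concentration `R = TW/TP` of each colour
  plane, an "epithelial" concentration (the nuclei plane dilated by the
  cytoplasm radius — the tissue table names this quantity but never
  defines it; the dilation proxy is our reading and is labelled as
  such), per-channel HSV means and 4-bin HSV histograms (equal-width
  over [0, 1], normalised to sum to 1). Windows are cropped at the
  border and `TP` counts in-image pixels only, so border nuclei carry
  no padding bias.
* **Duct/cluster morphometrics**: ducts appear as dense packs of
  nuclei. The nuclei plane is opened (disc r = 3, removing
  sub-nucleus specks) then closed (disc r = 7, merging packed nuclei).
  The order matters: closing-then-opening severs the thin bridges the
  closing just built, so dense groups never merge — we do it the other
  way. Components of at least 2000 px^2 containing at least 5 nucleus
  centroids become clusters, reporting area, roundness, member count
  and mean centroid distance. Nuclei outside any cluster carry zero
  sentinels.
* **Global features**: whole-patch plane concentrations (they sum to 1
  by the partition property), whole-patch HSV means, and the pink
  filter mean.

## Key-parameter selection

Rows are snapped to the 11-level TC grid (0, 0.1, ..., 1; +-0.025,
others dropped) and summarised per level; each feature's level means
are correlated with TC (Pearson `r` and OLS slope). A feature is kept
when `|r| >= 0.80` — sign-agnostic, because the strongest correlates of
cellularity (stroma concentration, global V) are *negative* — **and**
the lasso selects it. The lasso (`glmnet`, z-scored features, seeded
5-fold CV) uses `lambda.min`, not the one-standard-error rule: the
informative features are mutually correlated by construction (all track
TC), and the 1-SE rule's parsimony deliberately prunes correlated
groups, which would contradict the requirement that all planted
informative features be recovered. Redundancy is instead handled
explicitly: among kept features, pairs with raw-column `|Pearson| >
0.95` lose the lower-`|r|` member. Results are ordered by `|r|`.

The canonical 22-name manifest shipped in `keyParameterSet()` (5
nucleus geometry + 13 regional at the 30-px window + 4 global/stroma
entries) reflects the feature families with the strongest reported TC
correlation — the small window correlates best — and lets the
classifier run without re-running selection. The exact 22 identities on
the original clinical data are not recoverable without that data; the
manifest is the package's own choice from the named families.

## Classification

Three classifiers on the z-scored manifest columns: RBF SVM
(`cost = 1`, `gamma = 1/p`), KNN (`k = 5`, Euclidean) and discrete
AdaBoost over 100 depth-1 stumps (implemented in-package; no
AdaBoost-family package is part of the stack). Hyperparameters are
implementation defaults, configurable, and not tuned per dataset.
Training reports accuracy, malignant-class TPR, ROC AUC (threshold
sweep with ties grouped; the trapezoidal AUC equals the pairwise
concordance probability) and a seeded 5-fold cross-validated accuracy.
Predictions are deterministic and invariant to affine rescaling of any
feature column (the z-scoring contract).

## Cellularity scoring

Malignant nucleus pixels are dilated by a disc (default radius 10 px ~
5 um of cytoplasm rim at 0.5 um/px; the structuring element is a disc
because cytoplasm surrounds the nucleus isotropically) and TC is the
covered fraction of the patch. Overlapping dilations count once — the
area-ratio definition forces a union. Benign nuclei contribute
nothing. TC is therefore monotone in the dilation radius, and equals
brute-force pixel counting of the dilated mask exactly (a test
enforces both). Batch mode processes a directory, logs and skips
unreadable files, and writes a deterministic CSV sorted by patch id.

Agreement with a reference rater uses MSE and ICC(2,1) — two-way
random, single rater, absolute agreement, the standard variant for
method-vs-rater comparison — with McGraw–Wong F-based 95% bounds,
cross-checked in the tests against a value frozen from an independent
implementation.

## The phantom generator

Phantoms emulate the structure the pipeline exploits, not histology
itself: pink stroma with per-pixel Gaussian texture (jitter SD 6),
white fat blobs (8% area by default), blue elliptical nuclei — benign
small (semi-major 4–7 px) and round (eccentricity <= 0.3), malignant
larger (8–14 px), eccentric (0.4–0.8), with a sinusoidally perturbed
boundary and stronger internal texture — and optional duct clusters of
packed benign nuclei. Malignancy expressed through size, eccentricity
and texture is a modelling choice of the fixture so that the feature
table is genuinely discriminative; it is not biology. Nuclei never
overlap (a 1 px claimed ring enforces separation), colours sit at
typical H&E renderings (stroma ~(230,160,200), nuclei ~(60,40,120),
fat ~(245,245,245)), global pixel noise has SD 4, and rendering rounds
to 8-bit so a seed reproduces identical bytes. The planted TC is
computed from the stored malignant masks with the same
`computeTCFromMasks()` the pipeline uses, so ground truth is
self-consistent by construction.

`phantomSuite()` plants TC levels on the (0, 0.1, ..., 1) grid by
adding malignant nuclei until the dilated coverage reaches the target,
sampling candidate centres from still-uncovered pixels (dilation
distributes over union, so coverage updates are exact and local); near
the target it prefers smaller nuclei so the last increment does not
overshoot. High targets shrink the fat budget (a patch that must be
95% tumour cannot also be 8% fat) and drop ducts above TC 0.6. Targets
are met within +-0.03 up to 1.0; an unreachable target reports the best
achievable coverage. Training phantoms for the classifier span the full
TC range, mirroring a training design with cellularity spread uniformly
from zero to one — an RBF SVM asked to extrapolate global-concentration
features far outside its training range degenerates, which is visible
on phantoms trained only at mid-range TC.

What phantom results do **not** show: robustness to stain variation
between scanners, out-of-focus regions, overlapping nuclei,
lymphocyte-vs-tumour ambiguity, or any of the colour complexity of real
H&E. Passing tests certify the machinery — colour separation, the
segmentation operators, feature algebra, the selection rules, the score
definition — under controlled conditions with exact ground truth, not
clinical performance. The reported clinical-scale figures of merit for
this class of method (ICC against pathologists around 0.78, mean
segmentation Jaccard around 0.73) come from a non-deposited challenge
dataset and are context, not targets this package can recompute.

## Numerical choices and degenerate inputs

* All intensity math on [0, 1]; patches stored as 8-bit 0–255.
* 0-based pixel coordinates, x = column, y = row; orientation in image
  coordinates (y down), degrees in (-90, 90].
* Otsu ties resolve to the lowest split; the threshold is the midpoint
  of the flanking bins.
* A constant image is a degenerate-threshold error; a uniform patch is
  a degenerate-clustering error; an empty mask segments to zero nuclei
  (not an error); two empty masks have Jaccard 1; a zero-variance
  feature gets `r = 0` and a flag.
* Every seed consumed anywhere (k-means++, CV folds, phantom
  construction) is caller-supplied; pipeline stages with no stated seed
  are seedless and bitwise reproducible.

## Problem sizes

The test suite and `scripts/acceptance.R` generate phantoms of
160–256 px (the generator's default remains 512): segmentation recall
runs 20–30 phantoms, selection recovery 50 seeded tables, classifier
checks 1000 22-D points, and the end-to-end check trains on 5 phantoms
spanning the TC range and scores 33 phantoms on the 11-level grid.
These sizes were chosen to keep a full run in minutes on one CPU while
leaving every statistical margin comfortable; the pipeline itself is
size-agnostic.
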