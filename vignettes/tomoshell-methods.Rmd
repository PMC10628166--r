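---
title: "Label-free 3D T-cell morphometry: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Label-free 3D T-cell morphometry: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tomoshell)
```

## The measurement model

Holotomographic microscopy reconstructs, for a single living cell, a 3D
map of the refractive index (RI) on a voxel grid. Because the RI elevation
of cytoplasm over the surrounding medium is, to good approximation,
proportional to the local protein concentration, an RI tomogram is a
label-free biochemical measurement: from it one can segment the cell,
count voxels into a volume, convert mean RI excess into protein density,
and integrate the two into the cell's dry mass. In immune cells these
quantities shift with activation state, which makes single-cell
morphometry of CD8+ T cells a candidate biomarker for conditions such as
sepsis, where cohorts are typically structured as healthy controls (H)
versus patients sampled at septic-shock onset (T1), shock resolution (T2)
and pre-discharge (T3), with survivor/non-survivor outcomes at T1.

`tomoshell` implements the full analysis chain over such tomograms:
simulation, input/output and quality control, morphometry, radial
shell-density profiles, cohort statistics, and a compact 3D convolutional
classifier with bootstrap few-cell evaluation.

## Phantoms and synthetic cohorts

Real cohort tomograms are rarely redistributable, so the package ships a
first-class generator. A phantom (`phantom_spec()`, `make_phantom()`) is
an ellipsoidal cell of constant cytoplasmic RI containing a concentric
ellipsoidal nucleus, optionally with a dense peripheral rim, plus i.i.d.
Gaussian RI noise. Membership of a voxel in cell, nucleus or rim is
decided at the voxel centre; this makes the construction exactly
reproducible by a brute-force lattice count, which the tests use as an
oracle. Default optical parameters are typical for lymphocytes in culture
medium: medium RI 1.337, cytoplasm 1.356, nucleus 1.39, all constrained
to [1.30, 1.45]; spacing defaults to 0.2 um isotropic.

Cohorts (`make_cohort()`) draw subject-level random effects — Gaussian on
log-radius, so radii stay positive, and additive on RI — and cell-level
jitter around them. Group contrasts are expressed as a radius scale, an
RI offset, and a *peripheral density weight* in [0, 1] that raises the RI
of the outer radial band of the cell towards the nuclear value,
emulating a cell whose dense material sits peripherally. The default
cohort (`default_cohort_groups()`) mirrors a small clinical study: 20
healthy subjects and 8 sepsis subjects over three time points, a few
hundred cells per group, with effects ordered T1 > T2 > T3 = H in size
and RI and non-survivors more peripherally dense than survivors at T1.
No published effect sizes exist for these contrasts (only test
statistics on unavailable patient data), so the default magnitudes were
chosen once for direction and plausibility — roughly 10-30 % volume
differences and RI offsets of a few 1e-3 — and are fully configurable.

Clinical covariates (CRP, WBC, neutrophil %, lymphocyte %, and the
cytokines CCL2/MCP-1, IL-10, IL-2, TNF-alpha) are generated per subject
as `cov = mean + a * (subject mean RI - grand mean) + noise`, with the
slope `a` and noise variance solved in closed form from the target
correlation and marginal standard deviation, so the expected Pearson
correlation with subject mean RI equals the target exactly without
iteration. Lymphocyte percentage defaults to a negative correlation; the
other markers are positive, matching their opposite movement during
recovery.

What the generator deliberately does not emulate: optical diffraction,
missing-cone reconstruction artifacts, organelle texture, or irregular
cell shapes. Tests passing on phantoms therefore establish the
correctness of the *computations*, not robustness to real acquisition
artifacts.

## Input/output and quality control

Tomograms travel as multi-page TIFF (one page per z-slice) or raw
little-endian float32, each with a JSON sidecar holding the metadata
contract: shape, voxel spacing, medium RI, cell id, labels. The TIFF
samples store RI − 1 on the writer's 32-bit integer grid in [0, 1];
round-trips are accurate to about 5e-10 RI, far below any measurement
noise, while the raw format round-trips bit-exactly. Missing sidecar
keys and shape mismatches are hard errors.

The original curation of acquisitions is typically manual. `qc_filter()`
replaces it with three explicit, configurable rules on the
super-threshold foreground: its volume fraction must lie in
[0.1 %, 60 %]; it must form a single connected component (a second
component at least 10 % the size of the largest indicates adjoined
cells); and it must not touch the volume border (truncated cell). These
proxies are stated, not inferred from the manual criteria.

## Morphometry

Segmentation thresholds the volume at `tau_seg` and keeps the largest
26-connected component, which removes stray super-threshold noise
voxels. The threshold is "predetermined" in the measurement tradition;
as no published value exists, the default is `medium RI + 0.005`, robust
on phantoms up to noise of about 0.002 RI, and configurable.

From the mask:

* volume `V` = voxel count x voxel volume (um^3 = fL);
* protein density `C` = 100 * (mean in-mask RI − medium RI) / alpha in
  g/dL, with the refraction increment `alpha` defaulting to 0.19 mL/g,
  the middle of the 0.18-0.21 mL/g range for protein;
* dry mass `m = C * V * 1e-2` pg, an identity the package stores
  consistently to machine precision;
* centre = arithmetic mean of mask coordinates, radius = maximum
  (physically scaled) distance from centre to a mask voxel.

Mean overall and nuclear RI are measured by default on the 2D
cross-section through the cell centre, the nuclear component being
pixels above RI 1.38; whether such features should be sectional or
volumetric is genuinely ambiguous in practice, so a `full_3d` mode is
provided behind a flag and the sectional mode is the default. When no
pixel exceeds the nuclear threshold the nuclear mean is reported absent
(`NA`) rather than zero.

## Shell-density profiles

The spatial-distribution statistic ranks every analyzed pixel of the
central section by Euclidean distance from the cell centre and splits
the ranked list into eight contiguous blocks of equal size (remainder
pixels go to the innermost shells; distance ties break by row-major
index so the partition is a pure function). Shell 1 is innermost, Shell
8 outermost. The density of a shell is the fraction of its pixels above
an intensity threshold — the segmentation threshold for the "overall"
component and 1.38 for the "nuclear" component. With anisotropic voxels
distances are computed in physical units, which is what makes the
iso-distance contours elliptical; the rank-based equal-count
construction is the operative definition.

Two analyzed-pixel conventions exist because the source procedure is
ambiguous: the default ranks *all* pixels of the rectangular section
(background included, which dilutes outer-shell densities), and a
`restrict = "cell"` option limits the ranking to pixels within the cell
radius. Both are available; all package tests state which they use.

## Cohort statistics

Morphometric features are compared across status groups with classical
one-way ANOVA, and pairwise with pooled-variance Student t-tests
(Welch's form behind a flag), Bonferroni-corrected as
`min(1, m * p)`. Shell densities get a per-shell ANOVA across the four
status groups and a survivor/non-survivor t-test at T1, each family
Bonferroni-corrected over the eight shells. Degenerate inputs follow
documented conventions: zero within-group variance with differing means
reports `F = Inf, p = 0`; a zero-pooled-variance pair is flagged.
Stars follow `* < 0.05, ** < 0.01, *** < 0.001`.

The unit of analysis is the cell, matching the per-cell comparisons such
data are usually presented with; this ignores within-subject
correlation, so a per-subject aggregation mode exists as a deliberate
deviation option (default off). Correlations between a morphology
feature and clinical covariates are Pearson's, under two pairings:
per-time-point means (a handful of points, the figure-style pairing) or
per-subject means.

## The 3D dense-block classifier

The classifier is a DenseNet-style 3D CNN written from first principles
in compiled code: an initial 3x3x3 convolution with 2x average pooling,
dense blocks whose composite layers apply batch norm, ReLU and a 3x3x3
convolution adding `growth` channels to the running concatenation, 1x1x1
compression convolutions with 2x pooling between blocks, then batch
norm, ReLU, global average pooling and a linear softmax head. The desk
default — 4 blocks x 2 layers (8 dense layers), growth 4, 8 initial
channels, 32^3 inputs — trains in minutes on one CPU core; a
paper-scale deep configuration (dozens of dense layers, 210x276x276
nominal extents) is expressible through the same `model_config()` fields
but is not what the tests exercise. Every gradient (convolutions, batch
norm, pooling, classifier head) is verified against central finite
differences in the test suite.

Preprocessing centre-crops each cell to centre +- radius per axis
(padding with medium RI where the box leaves the volume), resamples
trilinearly to a fixed target shape — either an explicit triple or the
median training-set crop shape, fixed before training and reused at
inference — and min-max normalizes per image. Normalization is applied
after resampling so every non-constant volume attains 0 and 1 exactly; a
constant volume maps to zeros by convention.

Training follows the standard small-scale protocol: cross-entropy loss,
SGD with momentum 0.9, cosine-annealed learning rate (initial 1e-3,
period 64 epochs), batch size 16, once-per-image-per-epoch augmentation
(axis-aligned 90-degree in-plane rotations and flips — interpolation-free
by default; arbitrary angles are out of scope), and early stopping on
validation loss with patience 30, keeping the best-epoch parameters.
The 8:1:1 cell-level split is the default; a `by_subject` split is
offered because cell-level splitting lets cells of one subject straddle
train and test, which can inflate performance when subjects are few —
both options are provided rather than guessing which convention a given
study used.

Evaluation replicates few-cell prediction: per bootstrap iteration, `k`
cells (1-5) are drawn per unit and an AUROC is computed by pairwise
concordance with ties counted one half; the point estimate is the mean
over 1000 iterations with a 2.5/97.5 percentile interval. With subject
ids the `k` cells of each subject are aggregated — mean probability by
default, majority vote behind a flag, since the aggregation rule is not
standardized — into one score per subject; without subject ids, `k`
cells are drawn per class and the AUROC is computed over the individual
cell scores, which avoids the degenerate two-score comparison that
per-class aggregation would produce.

Grad-CAM saliency weights the feature maps of a chosen dense block by
the spatial mean of the target-class logit gradient, ReLUs the weighted
sum, upsamples it trilinearly and normalizes its maximum to 1. By
default the deepest block whose maps keep at least 4 voxels per axis is
used: with global average pooling directly above, the maps of the last
block can collapse to a single voxel and carry no localization.

## Numerical choices and degenerate inputs

* Voxel membership at centres; 26-connectivity for components.
* Shell partitions: remainder to inner shells, row-major tie-break.
* Empty segmentation, empty masks, sections missing the mask, fewer
  than eight pixels, and missing cohort labels are errors, not silent
  results.
* Batch norm uses eps 1e-5 and running-stat momentum 0.1; inference uses
  running statistics.
* He initialization scaled by fan-in; all randomness (initialization,
  shuffling, augmentation, splits, bootstrap) flows from explicit seeds,
  and the generator restores the session RNG state.
* Training aborts with the last valid epoch on a non-finite loss.

## Problem sizes used in the checks

The package's own verification runs at sizes a laptop handles in
minutes, chosen once: phantoms of 12-64 voxels per axis; parameter
recovery on 100 cells per group at 48^3; type-I-error calibration from
500 replicate null cohorts; classifier properties on 200 cells at 32^3
with a 15-epoch budget, which suffices for the strongly contrasted
synthetic cohort to reach ceiling performance. Scaling the same
configuration objects up to instrument-sized volumes changes nothing in
the code paths, only the runtime.

## Known limitations

* Phantoms are piecewise-constant ellipsoids; none of the texture,
  shape irregularity or reconstruction artifacts of real tomograms are
  modelled, so real-data performance claims cannot be read off the
  synthetic results.
* Cell-level statistics ignore within-subject correlation unless the
  subject-aggregation mode is chosen.
* The classifier implementation favours clarity and testability over
  throughput; paper-scale training (tens of dense layers on full-size
  volumes) is expressible but impractical without GPU hardware.
* TIFF storage quantizes to a 2^-32 grid of RI − 1; use the raw format
  where bit-exactness matters.
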