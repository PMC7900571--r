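---
title: "Knee cartilage thickness from label volumes: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Knee cartilage thickness from label volumes: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carthick)
```

## What the package computes

`carthick` measures articular cartilage thickness of the knee from
segmentation label volumes (femur, tibia, patella and their cartilages),
partitions the cartilage into the 14 WORMS anatomical regions, and runs the
cohort-level statistics used to describe thickness differences across
regions, sexes, sides and ages. Segmentation itself is out of scope: the
pipeline consumes integer label masks from any source (manual labelling, a
U-Net, or the bundled phantoms).

## The thickness algorithm

For one bone--cartilage pair the chain is:

1. **Signed distance fields.** For both the bone mask and the cartilage
   mask, the exact Euclidean distance transform is computed with the
   physical anisotropic voxel spacing (a separable lower-envelope
   algorithm, implemented in C++). The signed field is negative inside the
   structure and positive outside; the magnitude is the distance in mm
   from the voxel centre to the nearest voxel centre of the opposite
   phase, so voxels flanking an interface carry magnitudes of at most one
   voxel spacing.
2. **Gradient fields.** First-order gradients of the two signed fields
   (central differences interior, one-sided at grid edges, per-axis
   division by the spacing). By default the fields are first smoothed
   with a Gaussian of one voxel sigma per axis: raw distance-transform
   gradients are noisy at the voxel scale, and only the *sign* of a dot
   product is consumed downstream, so smoothing changes essentially
   nothing except robustness near the medial axis.
3. **Boundary classification.** Boundary voxels of the cartilage
   (cartilage voxels with a face-adjacent non-cartilage neighbour,
   6-connectivity) are classified by the dot product of the two gradient
   fields: negative means the voxel faces the bone (inner boundary, the
   bone--cartilage interface), positive means it faces away (outer
   boundary, the articular surface). An exactly zero dot product is
   resolved deterministically: outer if any face neighbour is background,
   else inner.
4. **Thickness.** A distance map seeded at the outer boundary points is
   read at every inner point: thickness at an inner point is the
   Euclidean distance in mm to the nearest outer boundary point.
5. **Region averaging.** Each inner point takes the region code of the
   atlas voxel it occupies, and per-region thickness is the arithmetic
   mean over the region's inner points; a region with no points is
   reported missing, never zero.

### Numerical choices

* **Dimensionality.** Thickness is computed fully in 3-D by default.
  Physical thickness is a 3-D quantity, and with 3 mm slices a per-slice
  2-D computation mismeasures any surface not perpendicular to the slice
  plane. A `mode = "2d"` flag computes slice-wise transforms for
  sensitivity analysis.
* **Boundary definition.** 6-connectivity gives the minimal boundary set;
  26-connectivity inflates boundaries on anisotropic grids. Out-of-grid
  neighbours count as *inside* the structure: a structure cut by the field
  of view must not grow a spurious boundary (and hence spurious thickness
  readings) on the cut plane.
* **Voxel-centre convention.** All distances are voxel-centre to
  voxel-centre in mm. A shell voxelized by centre membership therefore
  reads about one voxel thin (half a voxel lost at each surface). The
  phantom generators place surfaces symmetrically around voxel centres
  (a voxel is cartilage when its centre lies within half a voxel of the
  continuum shell), which cancels the bias; on real segmentations the
  same convention question belongs to the segmenter, and readings carry
  the usual half-voxel-per-surface uncertainty.
* **Floating cartilage.** If a cartilage shell is nowhere adjacent to its
  bone, the classifier still partitions every boundary voxel: the ring
  facing the bone is classified inner and the articular ring outer,
  because the dot-product sign encodes *facing direction*, not contact.
  (A derivation that all boundary voxels of a floating shell come out
  "outer" is geometrically wrong for this rule: the bone field's gradient
  points away from the bone everywhere, so the bone-facing ring always
  produces a negative dot product.)

## The region atlas

The 14 regions (FMA ... PL) are assigned by a geometric atlas built from
the subject's own bones: a parasagittal plane through the tibial centroid
(patellar centroid for the patella) splits medial from lateral, and the
anteroposterior extent of each bone's cartilage is cut into
anterior/central/posterior at configurable fractions (equal thirds by
default). The anatomical definition of the load-bearing "central" region
has no universally quantified boundary, so equal thirds is a reproducible
convention, not a reproduction of any particular atlas. Deformable
registration is deliberately replaced by a pluggable transform hook
(identity and 4x4 world-coordinate affine supplied): registration
internals are not this package's contribution, and the geometric atlas
makes the pipeline self-contained on phantoms. Tie voxels at interfaces
belong to whatever code occupies the atlas voxel (determinism over
probabilistic assignment).

## Synthetic data: what it emulates, and what a green test proves

The **annulus phantom** wraps a cylindrical bone in a cartilage shell of
known, possibly angle-dependent thickness at MR-like anisotropic spacing
(default 0.5 x 0.5 x 3 mm). Because the continuum geometry is known, it
calibrates the estimator: recovered mean thickness on 1.5/2/3/4 mm shells
is accurate to well under one in-plane voxel. The **knee phantom** adds a
tibial plate and a patellar plate so that all 14 regions, the atlas and
the end-to-end subject pipeline can be exercised with known answers. Its
anatomy is schematic; plate thickness readings quantize to the voxel grid
along the plate normal and plate rims bias edge points low, which the
tests budget for. Neither phantom emulates MR intensities, segmentation
errors, or real anatomical curvature, so green geometry tests establish
algorithmic correctness, not segmentation robustness.

The **cohort generator** draws a table shaped like a large cross-sectional
study of radiographically normal knees: n = 2,481; ages truncated-normal
with mean 35, SD 10 on [15, 64] (the published cohort reports exactly
these moments and range, and the truncated normal matches both); exact
strata of 1,355 male / 1,126 female and 1,228 left / 1,253 right; and
per-region thickness `Normal(baseline + slope*(age-35) + sex_offset*I(male)
+ side_offset*I(left), SD)` truncated at zero by redrawing (clipping would
silently shrink the SD). Thirteen baselines and SDs are calibrated to the
published region means; **PL has no published value** -- its default
(2.08, SD 0.30) is flagged `calibrated = FALSE` and is excluded whenever
"the calibrated regions" are compared. Age slopes and offsets default to
zero because the publication reports signs and significance but not
magnitudes; tests that need a slope configure it explicitly. A green
cohort test therefore establishes that the statistics stage recovers what
the generator put in, under the published first and second moments -- not
that the generator reproduces the real joint covariance of regions, which
is unpublished (regions are drawn independently given covariates).

## Statistics

* **Tukey pairwise comparisons.** One-way layout per factor (region, sex,
  side -- the source analyses read as separate one-way comparisons, and no
  multi-way model is claimed), with simultaneous 95% intervals from the
  studentized range at the pooled residual df (Tukey-Kramer for unequal
  n). For k = 2 the critical value uses the exact identity
  `q = sqrt(2) * t` rather than the generic quantile numerics. A
  Games-Howell unequal-variance variant is available behind
  `var_equal = FALSE`; the pooled form is the default because it is the
  named method. Significance is "interval excludes zero" at fixed
  two-tailed alpha 0.05.
* **Age x condition regression.** OLS of one region's thickness on age,
  a two-level condition (sex or side) and their interaction. The
  interaction coefficient *is* the difference of the condition-specific
  age slopes (the tests assert the identity against stratified fits).
  Age is centred at the cohort mean for conditioning; coefficients are
  mapped back to the uncentred scale, including the covariance, so
  reported SEs and p-values refer to the conventional parameterization.
  "Consistent between conditions" means the interaction p-value is at or
  above alpha. Confidence bands are pointwise 95% intervals of the
  conditional mean over an age grid, per condition level; grids outside
  the fitted age support warn about extrapolation.
* **Dice similarity.** `2|A&B| / (|A| + |B|)` over whole 3-D masks
  ("per individual", not slice-averaged). Two empty masks score 1:
  agreement on absence is perfect agreement and avoids 0/0. The published
  per-structure DSC table came from 20 proprietary test scans and trained
  network weights, so it is not reproducible here; the module instead
  ships a perturbation fixture whose DSC decreases monotonically with
  severity.

## Known limitations

* Thickness readings inherit the voxel grid: expect quantization at the
  slice spacing along surfaces normal to the slice direction, and
  rim/edge effects wherever cartilage terminates.
* The geometric atlas encodes a convention (centroid split, equal
  thirds); it is not a learned anatomical atlas, and region boundaries on
  real knees will differ from any clinical parcellation.
* The cohort generator draws regions independently given covariates and
  is calibrated only to published means/SDs; between-region correlations
  and non-Gaussian tails of real cohorts are not emulated.
* The NIfTI layer is a minimal single-file NIfTI-1 subset (diagonal
  orientation, common datatypes); it is not a general neuroimaging I/O
  library.
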