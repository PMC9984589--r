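---
title: "Quantifying the repeatability of repeated 3D muscle segmentations"
author: "repseg package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the repeatability of repeated 3D muscle segmentations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repseg)
```

## The problem

Manual, slice-by-slice segmentation of skeletal muscle on clinical MRI is
the reference standard against which automatic methods are validated, yet it
is itself an imprecise measurement: the same trained operator, segmenting
the same muscle on different days, draws slightly different contours.
`repseg` quantifies that intra-operator repeatability for hip muscles
(gluteus medius, iliopsoas) and — crucially — localizes it along the muscle:
is the disagreement concentrated at the tendinous extremities, which are
notoriously hard to identify on T1-weighted images, or spread over the
muscle belly?

The package implements the full analysis pipeline as reusable, tested
components and pairs it with a synthetic phantom generator, so every stage
can be exercised and validated end-to-end without access to patient images.

## The pipeline

For each subject and muscle, with at least two repeated binary label
volumes:

1. **Virtual palpation input.** Twelve named bony landmarks per subject
   (`LandmarkSet`, CSV `name,x,y,z` in world mm), plus the corresponding
   atlas landmarks and the atlas muscle origin/insertion points.
2. **Muscle point morphing.** A 12-degree-of-freedom affine
   \(p \mapsto A p + t\) is fitted by least squares to the
   atlas-to-subject landmark pairs through the SVD pseudoinverse of the
   homogeneous design (`fitAffine()`), and applied to the atlas attachment
   points (`applyTransform()`). Attachments that miss the bone are
   relocated to the nearest point of the bone surface mesh
   (`snapToSurface()`), searching triangle interiors and edges, with a
   15 mm default ceiling beyond which the point is left alone and flagged —
   the automated analogue of a visual check. A similarity (Umeyama)
   alternative, `fitSimilarity()`, is provided for sensitivity analyses;
   the full affine is the default because the morphing step is defined as
   an affine registration.
3. **Proximal standardization (iliopsoas only).** Retrospective clinical
   scans truncate the proximal psoas inconsistently, so each segmentation
   is cut by a plane normal to the origin–insertion line through the
   midpoint of the left and right iliac-crest landmarks, and the proximal
   (origin-side) part is discarded (`standardizeProximal()`). A plane
   through two landmarks with a fixed normal is over-determined; the
   midpoint is the canonical single point and is the documented choice.
4. **Sub-volume decomposition.** The origin–insertion line defines the
   muscle length \(L\) and the normal of all cutting planes
   (`makeAxis()`). Starting from the midpoint between the attachments, two
   parallel planes move outward in 5% steps of \(L\); at each step only
   the slab between them is kept (`cutSeries()`). Level \(k\) contains the
   voxels whose center projection \(p\) satisfies
   \(|p - c| \le 0.05\,k\,L\); the tenth level is the complete, uncut
   segmentation, because muscle tissue can extend beyond the attachment
   planes and the full segmentation is the natural 100% reference. Voxels
   exactly on a plane are included (closed slab), which guarantees nesting
   \(S_k \subseteq S_{k+1}\) and makes the decomposition reproducible by a
   trivial per-voxel filter — the test suite holds the vectorized
   implementation to bit-identity against that brute-force oracle.
5. **Agreement metrics.** For each level and each unordered pair of
   repeats (1–2, 2–3, 1–3 for three repeats), `compareRepeats()` computes
   the Jaccard index \(|A \cap B| / |A \cup B|\) on the voxel masks, the
   maximal symmetric Hausdorff distance between the extracted boundary
   surfaces, and, across all repeats, the normalized volume variance
   \(\mathrm{nVV} = 100 \cdot s^2 / \bar V\) (sample variance over mean).
   JI and HD are averaged over the pairs.
6. **Statistics.** Per metric and muscle, a subjects × levels matrix
   (`metricMatrix()`, listwise deletion of subjects with flagged levels)
   enters a normality-gated repeated-measures comparison (`testLevels()`):
   Shapiro–Wilk per level column, parametric branch (one-way RM-ANOVA +
   Bonferroni-corrected paired t tests over all 45 level pairs) only if
   every column passes at \(\alpha = 0.05\), otherwise Friedman +
   Wilcoxon signed-rank. `iccAgreement()` supplies Shrout–Fleiss
   ICC(1,1) and ICC(3,1) with F-based confidence intervals for
   agreement-style questions (e.g. between operators).

## The phantom generator

`makePhantom()` rasterizes a tube-like muscle onto an anisotropic voxel
grid emulating the target acquisitions: 0.817 mm in-plane pixels and 4 mm
slices by default (the published acquisition tables for 1.5 T coronal
T1-weighted hip protocols report 0.817 ± 0.053 mm pixels and 4–6 mm
slices). Three shapes cover the anatomy of interest: `straight_tube`,
`tapered_tube` (radius shrinking quadratically toward the extremities, a
gluteus-like fan reduced to revolution symmetry) and `wrapped_tube`
(centerline bowing laterally mid-length, an iliopsoas-like wrap around the
iliac crest). The grid is auto-sized to the muscle plus a 5-voxel margin;
an explicit grid that cannot contain the muscle plus margin is rejected
with the required dimensions. Since every metric in the pipeline depends
only on the foreground geometry in world mm, cropping the clinical
512 × 512 field of view to the muscle bounding box changes nothing and
keeps the default phantoms fast.

The muscle axis runs along the slice-stack normal, so each slice is a
cross-sectional disc. Real coronal hip acquisitions have the muscle partly
in-plane; the through-slice orientation is a deliberate simplification
that keeps the per-slice contour model exact.

Twelve bony landmarks sit at fixed offsets in the muscle frame (never
coplanar), the atlas side is produced by inverting a seed-determined
random affine (small rotations, 0.9–1.1 anisotropic scale, mild shear,
±20 mm translation), and a synthetic two-block bone mesh touches both
attachments so snapping is exercised as a no-op in the clean case.

### The noise model

`simulateRepeats()` encodes the hypothesized error mechanism: the operator
re-draws each 2D contour with a smooth, spatially correlated error whose
magnitude grows toward the muscle extremities.

* Per slice, the contour is displaced along its normal by a stationary
  Gaussian process on the circle (spectral synthesis, squared-exponential
  spectrum with arclength correlation `correlation_length_mm`, default
  10 mm). Displacement is applied through the in-slice signed distance
  transform, with a half-pixel dead-zone correction so sub-pixel
  displacements act on the correct side of the boundary.
* The displacement SD interpolates linearly in the normalized axis
  coordinate \(|p - c| / (L/2)\) from `belly_sigma_mm` (default 0.5 mm,
  sub-pixel: the belly is easy) to `extremity_sigma_mm` (default 3 mm,
  several pixels: the ends are hard).
* Terminal slices are dropped entirely with probability
  `end_slice_dropout_prob` (default 0.1), modelling a missed extremity
  contour.
* Slices are perturbed independently of one another; each repeat is
  reduced to its largest 6-connected component.
* One global seed expands into per-repeat, per-slice substreams by fixed
  integer hashing, so runs are bit-reproducible and repeats mutually
  independent.

The true error distribution of a human operator is not characterized
anywhere; the Gaussian-correlated field is an assumption, chosen as the
simplest smooth stationary model, and is documented as such.

**What passing tests show — and what they do not.** With these defaults
the phantoms reproduce the qualitative signatures expected of
extremity-concentrated error: mean JI at the 100% level falls below the
70% level, and mean HD grows monotonically with level. They do *not*
certify behaviour on real MRI, which adds intensity ambiguity, interpolated
inter-slice contours, operator memory effects and pathology-dependent
contrast that the generator deliberately omits.

**A known limitation.** With slice-independent noise, a slice's
contribution to nVV is proportional to
\(\sigma(s)^2 P(s)^2 / A(s) = 4\pi\,\sigma(s)^2\)
(perimeter \(P\), area \(A\)) — independent of the radius. Extremity
weighting therefore makes the phantom nVV *rise* with level, whereas
clinical data can show the opposite, which requires error correlated
across slices (e.g. a consistent whole-muscle bias). The pipeline
consequently asserts the JI and HD level trends on phantoms and reports
the nVV profile without asserting its direction.

### Units

nVV as variance-over-mean is not dimensionless. `repseg` evaluates it on
volumes in cm³, the conventional unit for muscle volumes, which places
whole-muscle nVV in the few-percent range; `volumeCV()` offers the
dimensionless coefficient of variation as an alternative.

## Numerical choices

* **World frame.** NIfTI RAS mm; the affine maps 0-based voxel indices
  (voxel centers) to world coordinates; masks are uint8 on disk and any
  value > 0.5 on read is foreground.
* **Surfaces.** `maskToSurface()` builds the closed voxel-boundary
  (cuberille) triangulation at the 0.5 iso-level: exact enclosed volume,
  consistently oriented, no interpolation parameters. The maximal
  Hausdorff distance is computed over mesh vertex sets with a
  sorted-coordinate early-exit search that is exactly equal to the
  all-pairs computation (property-tested).
* **Degenerate statistics.** A constant metric column forces the
  nonparametric branch; an all-tied Friedman input returns statistic 0,
  p = 1 with a warning; a zero-variance post hoc difference yields p = 1;
  an RM-ANOVA with both zero level and zero error sums of squares is
  defined as F = 0; negative ICC estimates are reported, not clamped.
* **Ties and boundaries.** Sub-volume planes include boundary voxels
  (closed slabs); Wilcoxon uses the zero-discard, midrank convention with
  the normal approximation, so small-sample p-values are stable in the
  presence of ties.
* **Registration guards.** Affine fitting requires at least 4 pairs and
  rejects coplanar/collinear sources when the smallest-to-largest singular
  value ratio of the centered source matrix drops below 1e-9.

## Problem sizes

The shipped tests and the acceptance script run entirely on phantoms:
default-geometry phantoms (≈ 49 × 49 × 35 voxels after auto-cropping,
0.817 mm pixels, 4 mm slices), 20 subjects per muscle with 3 repeats for
the study-level checks, 1000 within-subject permutations for the Friedman
size check, and 100 subjects × 3 raters for ICC parameter recovery. These
sizes give stable Monte-Carlo estimates while a complete run stays in the
minutes range on a single core.

## A short example

```{r example, eval = FALSE}
cfg <- studyConfig(mode = "synthetic", n_subjects = 6,
                   muscles = "gluteus_medius",
                   noise = noiseModel(belly_sigma_mm = 0.5,
                                      extremity_sigma_mm = 3, seed = 1),
                   seed = 1, out_dir = "gmed_run")
res <- runStudy(cfg)
res$summary[, c("level_percent", "ji", "hd_mm", "nvv_percent")]
res$stats[["gluteus_medius.ji_mean"]]
```

## Limitations

* Phantoms are solids of revolution with analytic centerlines; real
  muscles have non-convex cross-sections and oblique fiber architecture.
* No grey-level image synthesis: the generator emulates label noise, not
  the perceptual task of contour identification.
* Left/right muscles from the same patient are treated as independent
  subjects; no within-patient correlation is modelled.
* Etiology-level mixed-model analyses of repeatability are out of scope.
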