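# repseg

Repeatability analysis of repeated 3D muscle segmentations on clinical MRI.

## What problem this solves, and for whom

Slice-by-slice manual segmentation is the reference standard for measuring
skeletal muscle volume and shape on MRI — for sarcopenia assessment, sports
medicine, and subject-specific musculoskeletal models — yet it is itself a
noisy measurement: the same operator segmenting the same muscle on
different days produces slightly different label volumes. Anyone validating
an automatic segmentation method against manual labels, or propagating
muscle volumes into a downstream model, needs to know how large that
intra-operator error is and *where* along the muscle it lives (at the
tendinous extremities, which are hard to identify on T1-weighted images,
or in the belly).

`repseg` implements the complete analysis as an R package for hip muscles
(gluteus medius, iliopsoas):

1. **Atlas morphing** — a 12-DOF affine `p -> A p + t` fitted to paired
   bony landmarks by SVD least squares (`fitAffine`), applied to atlas
   muscle origin/insertion points (`applyTransform`), with
   nearest-point-on-mesh snapping to the bone surface (`snapToSurface`).
2. **Sub-volume decomposition** — from the midpoint of the
   origin–insertion axis, two parallel cutting planes normal to the axis
   move outward in 5% steps of the muscle length `L`; level *k* keeps the
   voxels with `|p − c| ≤ 0.05·k·L`, level 10 is the complete
   segmentation (`makeAxis`, `cutSeries`). The iliopsoas is first
   standardized by removing everything proximal to the iliac-crest plane
   (`standardizeProximal`).
3. **Agreement metrics per level, over all repeat pairs** — Jaccard index
   `|A∩B|/|A∪B|` on voxel masks, maximal symmetric Hausdorff distance
   `max(max_x min_y ‖x−y‖, max_y min_x ‖x−y‖)` on boundary surfaces, and
   normalized volume variance `nVV = 100·s²/V̄` (`compareRepeats`).
4. **Statistics** — Shapiro–Wilk-gated one-way repeated-measures
   ANOVA / Friedman across the ten levels, Bonferroni-corrected paired
   t / Wilcoxon post hoc over all 45 level pairs, and Shrout–Fleiss
   ICC(1,1)/ICC(3,1) (`testLevels`, `iccAgreement`).
5. **Synthetic phantoms** — tube-like muscle label volumes on realistic
   anisotropic grids with spatially correlated, extremity-weighted
   boundary noise and terminal-slice dropout (`makePhantom`,
   `simulateRepeats`), so the whole pipeline is testable without patient
   data.

See `vignettes/repseg-methods.Rmd` for the model, assumptions and design
choices.

## Worked example

A small synthetic study — six gluteus-medius phantoms, three simulated
re-segmentations each, 0.5 mm belly / 3 mm extremity boundary noise:

```r
library(repseg)
cfg <- studyConfig(mode = "synthetic", n_subjects = 6,
                   muscles = "gluteus_medius",
                   noise = noiseModel(belly_sigma_mm = 0.5,
                                      extremity_sigma_mm = 3, seed = 1),
                   seed = 1, out_dir = "gmed_run")
res <- runStudy(cfg)
res$summary[, c("level_percent", "n", "ji", "hd_mm", "nvv_percent")]
```

```
 level_percent n                   ji                hd_mm           nvv_percent
            10 6 0.917 (0.899, 0.929) 2.226 (1.855, 2.452)  0.610 (0.104, 1.420)
            20 6 0.895 (0.869, 0.908) 3.140 (2.493, 4.029)  0.936 (0.166, 1.973)
            ...
            70 6 0.811 (0.803, 0.822) 5.947 (5.416, 6.459)  9.054 (0.357, 32.192)
            ...
           100 6 0.760 (0.749, 0.767) 7.251 (6.428, 7.847) 16.844 (5.707, 32.908)
```

Each cell is `mean (min, max)` across subjects of the per-subject,
pair-averaged metric. Reading it: the innermost 10% of the muscle is
re-segmented almost identically (JI 0.92, worst surface error 2.2 mm);
including the full muscle drops JI to 0.76 and pushes the worst surface
disagreement above 7 mm — the segmentation error is concentrated at the
extremities, exactly the mechanism the noise model injects.

```r
res$stats[["gluteus_medius.ji_mean"]]
```

```
TestReport: parametric branch; omnibus stat 277.9492, p 2.229e-36 (alpha 0.05)
  39 of 45 post hoc pairs significant after Bonferroni
```

The amount of volume analysed has a significant main effect on JI, and the
Bonferroni-corrected post hoc matrix (written to
`gmed_run/posthoc_ji_gluteus_medius.csv`, levels 10–100 as rows and
columns) localizes which level pairs differ.

`runStudy` writes `metrics.csv` (tidy per-subject records),
`summary.csv`, `posthoc_<metric>_<muscle>.csv`, `stats.json`,
`run_manifest.json` and `log.txt`; re-running with the same config and
seed reproduces every file byte-for-byte.

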