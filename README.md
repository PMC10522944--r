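# mgscaffold

Degradation morphometry of bioresorbable magnesium coronary scaffolds
from synchrotron phase-contrast micro-CT.

Bioresorbable magnesium scaffolds corrode away after supporting a
coronary vessel. Quantifying that corrosion in vivo — how much material
has converted, where on each strut conversion starts, and how localized
severe corrosion relates to the tissue response — requires segmenting
3D micro-CT volumes into corrosion phases and measuring the result.
`mgscaffold` implements the full analysis chain for researchers working
on resorbable implants:

* **Synthetic phantoms**: a parametric crown-and-link scaffold generator
  with ground-truth labels (0 background/soft tissue, 1 metallic Mg,
  2 degraded Mg, 3 severely degraded Mg), emulating surface-inward,
  bend-concentrated slight degradation, randomly located swelling/cracked
  severe degradation, PSF blur and noise — so the whole pipeline is
  testable without beamline data.
* **Scan stitching**: merging vertically overlapping scans
  (`H = Σhᵢ − (n−1)·round(overlap/voxel)`), optional cross-correlation
  overlap refinement, and percentile-clipped 16-bit normalization.
* **Segmentation**: a self-contained 2D U-Net (compiled forward/backward
  passes and Adam inside the package, bit-reproducible) trained on 2D
  patches from the three orthogonal plane families; per-voxel class
  probabilities from the three families are averaged and argmaxed into a
  3D 4-label volume. Dice `2|A∩B|/(|A|+|B|)` and IoU evaluation included.
* **Morphometry**: per-phase volumes (`count × voxel³`), degraded
  fraction `(V₂+V₃)/(V₁+V₂+V₃)`, isosurface surface area (triangle-sum
  over a tetrahedral decomposition, anti-aliased mask), the
  luminal/lateral/abluminal partition of degraded material by escape
  direction versus the outward radial vector (45° cones), and STL/PLY
  mesh export.
* **Clinical statistics**: late lumen loss
  `LLL = MLD(implantation) − MLD(follow-up)`, recoil
  `R = (mean LD(implantation) − mean LD(FUP)) / mean LD(implantation) × 100%`,
  one-way ANOVA with Tukey-Kramer post hoc comparisons across treatment
  groups, and Spearman correlation of severe degradation volume with the
  ordinal inflammation score.

## Worked example

```r
library(mgscaffold)

spec <- phantom_spec(scaffold_length = 0.2, outer_diameter = 0.22,
                     wall_thickness = 45, strut_width = 40,
                     n_crowns = 3, n_links = 3,
                     n_severe_blobs = 2, severe_blob_radius = 35,
                     seed = 101)
phantom <- make_phantom(spec)
phantom$labels
#> <label_volume> 65 x 81 x 81 voxels @ 3.07 um
#>   labels: 0 (background) 326435 | 1 (metallic) 53447 | 2 (degraded) 40012 | 3 (severe) 6571

morphometry_report(phantom$labels)
#> <morphometry_report>
#>   metallic  0.00154646 mm^3
#>   degraded  0.00115772 mm^3
#>   severe    0.000190128 mm^3
#>   degraded fraction 0.4657
#>   surface area 0.263141 mm^2
#>   regional (label 2): luminal 0.000217471 | lateral 0.000585026 | abluminal 0.000355228 mm^3
#>   luminal:abluminal ratio 0.612
```

The degraded fraction (46.6%) is the converted share of the solid
scaffold; the regional volumes say where the conversion layer sits on
the struts (here more abluminal than luminal; the lateral class counts
both side faces). Training a U-Net on one phantom and segmenting another
(`extract_patches()`, `train_unet()`, `predict_volume()`) recovers these
ground-truth volumes from grey data alone — `run_pipeline()` wires the
whole chain together.

On the clinical side:

```r
rec  <- simulate_lumen_records(n_per_group = 3, seed = 6)
summ <- clinical_summary(rec)
summ$anova
#> <group_stats> one-way ANOVA: F = 5.912, p = 0.0199
#>                       pair    diff     lwr     upr   p_adj significant
#> ...
#> 6  G95_5%_DCB-G95_10%_POBA -0.6623 -1.2069 -0.1178 0.01918        TRUE
```

Late lumen loss differs across treatment groups (p = 0.0199); the
drug-coated-balloon thin-strut group beats the plain-balloon group in
the Tukey-Kramer comparison. Severe degradation volume and inflammation
score correlate strongly in the simulated records
(rho = 0.957, p = 1.1e-06).

A thin command-line wrapper over these functions is installed at
`inst/scripts/mgscaffold.R` (subcommands `phantom`, `stitch`,
`quantify`, `stats`, `run`).

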