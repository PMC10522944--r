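---
title: "Quantifying magnesium scaffold degradation from synchrotron micro-CT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying magnesium scaffold degradation from synchrotron micro-CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mgscaffold)
```

## The problem

Bioresorbable magnesium scaffolds support a coronary vessel mechanically
and then corrode away over months. Understanding *how* they corrode in
vivo — how much material converts, where on each strut conversion starts,
and how localized severe corrosion relates to tissue response — requires
segmenting phase-contrast micro-CT volumes into corrosion phases and
measuring the result in three dimensions. This package implements that
analysis chain end to end:

1. **phantom** — a parametric crown-and-link scaffold generator with
   ground-truth corrosion labels, so every later stage can be validated
   without beamline data;
2. **stitch** — merging vertically overlapping scans into one volume and
   16-bit normalization;
3. **segmentation** — a compact 2D U-Net trained on patches from the
   three orthogonal plane families, fused into a 3D 4-label volume
   (0 background/soft tissue, 1 metallic Mg, 2 degraded Mg, 3 severely
   degraded Mg);
4. **morphometry** — per-phase volumes and fractions, isosurface surface
   area, and the luminal/lateral/abluminal partition of degraded
   material;
5. **clinical statistics** — late lumen loss (LLL) and recoil, one-way
   ANOVA with Tukey-Kramer post hoc comparisons across treatment groups,
   and the rank correlation of severe degradation volume with the
   ordinal peri-strut inflammation score.

## The phantom model

The generator voxelizes a scaffold as sinusoidal rings with
`n_crowns` peaks living on a cylindrical shell (`wall_thickness` radial
extent, `strut_width` in-shell width), connected by `n_links` axial
bars. Geometry is deterministic given the spec. The number of rings
follows the scaffold length at roughly one ring per 1.2 mm — a typical
crown pitch for coronary devices — with the sinusoid amplitude set to
half the ring pitch so crowns are strongly bent.

Degradation has two morphologically distinct components:

* **Slight (conversion-layer) degradation** grows from the strut
  surface inward. Implementation: the Euclidean depth below the strut
  surface is computed exactly (separable squared-distance transform);
  voxels convert to label 2 in order of `depth / w`, where the weight
  `w = 1 + curvature_bias * |sin(n_crowns * theta)|` concentrates
  conversion at crown bends and a seeded piecewise-constant jitter over
  axial/angular sectors makes the layer depth patchy. Conversion stops
  exactly at the requested volume fraction of the solid scaffold
  (`slight_degradation_fraction`, default 0.4 — the study midpoint of a
  30–50 vol.-% degraded state at four weeks). Because the conversion
  threshold is constant along each radial column and depth increases
  from the surface inward, label 2 always forms a layer between
  background and remaining metal.
* **Severe degradation** is placed as seeded spheres centred on strut
  voxels (label 3) that dilate beyond the original strut envelope —
  severely corroded material swells and loses the strut shape — and,
  with `crack_texture`, are carved by thin random planes so renderings
  look broken up.

Rendering maps each phase to a mean 16-bit intensity (defaults:
background 12000, severe 28000, degraded 40000, metallic 52000 —
metallic brightest, matching the visual contrast of reconstructed
phase-contrast slices; the true grey separation is not known
quantitatively, so these are exposed parameters), blurs with an
isotropic Gaussian PSF (`psf_sigma`, default 3 um at a 3.07 um voxel)
and adds seeded Gaussian noise (`noise_sd`, default 800 intensity
units). The phantom emulates geometry, partial-volume blur and noise; it
does **not** emulate reconstruction artefacts (rings, phase fringes),
soft-tissue texture, or corrosion chemistry. Passing phantom-based tests
therefore demonstrates the correctness of the analysis chain, not
segmentation performance on arbitrary beamline data.

## Scan splitting and stitching

Tall samples are scanned in 3–4 vertical blocks with roughly 750 um
overlap. `split_scans()` cuts a volume into such blocks (overlap rounded
to whole slices); `stitch_scans()` concatenates them, filling the
overlap with a linear blend, which is exactly the identity when the
overlapping data agree — so split followed by stitch is bit-exact. With
`refine = TRUE` the per-pair overlap is adjusted by maximizing the
normalized cross-correlation over ±10 slices on a central crop; a best
correlation below 0.5 falls back to the nominal overlap with a warning.
The merged height always satisfies
`H = sum(h_i) - (n - 1) * round(overlap / voxel_size)`.

## The U-Net and its training

The network is a standard compact U-Net: `n_encoding_stages` encoder
stages (default 3) of `convs_per_stage` (default 2) 3×3 same-padding
convolutions + ReLU, feature maps from `base_features` (default 16)
doubling per stage, 2×2 max-pooling, a mirrored decoder with 2×2
stride-2 up-convolutions and skip concatenations, and a 1×1 head. The
forward pass, backpropagation and the Adam optimizer are implemented in
compiled code inside the package; training is single-threaded and fully
seeded, so runs are bit-reproducible. Backpropagation is verified in the
test suite against central finite differences, and the allocated
parameter vector length is verified against an independent analytic
layer-by-layer count for randomized architectures.

Two head designs are provided because a single-feature-map output cannot
express four classes directly: the default `multiclass_4` head (4-channel
softmax, class-weighted cross-entropy) and `binary_per_class`, which
trains three single-channel sigmoid networks (one per material phase)
whose outputs are fused by highest probability with background
elsewhere.

Training data are 2D patches tiled from every slice of the three
orthogonal plane families (flush-to-edge placement, no padding): a cubic
volume of side `s` at patch size `s` with zero overlap yields exactly
`3*s` pairs. Patches are z-scored with training-set statistics stored in
the model. Class weights default to *square-root tempered* inverse
frequency: plain inverse-frequency weights systematically over-segment
the minority phases at blurred boundaries (inflating the degraded-phase
volume), while tempering retains enough weight on rare classes for the
severe blobs to be learned. Train/validation splits are by whole volume,
never by patch, to avoid slice leakage. `subsample_patches()` offers a
seeded, stratified reduction that preferentially keeps patches
containing rare classes.

Inference runs the 2D network over all slices of all three plane
families, averages the three per-voxel class-probability fields, and
takes the argmax. Fusion is permutation-invariant in the three planes.

## Morphometry

* **Volumes**: phase volume = voxel count × voxel volume; the degraded
  fraction is `(V2 + V3) / (V1 + V2 + V3)`.
* **Surface area**: the 0.5-level isosurface of the phase-union mask is
  triangulated per grid cube via a six-tetrahedron decomposition and the
  triangle areas are summed. The binary mask is anti-aliased with a
  one-voxel Gaussian first: the raw binary level set is a staircase
  whose area is biased high (about +13% on a voxelized cylinder),
  whereas after anti-aliasing the interpolated vertices land on the
  underlying smooth boundary (cylinder error about 0.1%, against the
  closed form `2*pi*r*h + 2*pi*r^2`). `smooth_sigma = 0` restores the raw
  behaviour. Structures thinner than about two voxels may vanish under
  smoothing; the phantom enforces struts of at least two voxels.
* **Axis**: the scaffold axis is the principal component of the
  non-background voxel coordinates. PCA needs a scaffold clearly longer
  than its diameter; for short test volumes the partition uses the
  volume's `axis_hint` instead.
* **Regional partition**: every *degraded* (label 2) voxel is classified
  by the angle between its escape direction and the outward radial unit
  vector: within 45° of outward → abluminal (vessel-wall face), within
  45° of inward → luminal (blood-flow face), otherwise lateral (the two
  circumferential side faces share one class). Severely degraded voxels
  are excluded from this analysis entirely. The escape direction is the
  gradient of a 1.5-voxel-smoothed background-indicator field: the
  literal vector to the single nearest background voxel is quantized to
  45° steps at one-to-two-voxel depths and misclassifies about a tenth
  of a pure outer-skin test construction, while the gradient estimator
  resolves outer-skin, inner-skin and symmetric constructions
  essentially perfectly. The 45° default gives each radial class an
  equal angular budget; note that equal skins on the inner and outer
  faces of a *thick* shell still differ in volume by `r_in/r_out`, so
  near-unity luminal:abluminal ratios are expected only for struts thin
  relative to the vessel radius.
* **Meshes** are exported as binary STL or ASCII PLY in millimetres,
  with exactly deduplicated vertices (watertight; a cube mask yields
  Euler characteristic 2).

## Clinical statistics

`late_lumen_loss()` is the difference of minimal lumen diameters
(implantation minus follow-up, mm; negative values are flagged as lumen
gain) and `recoil()` the relative loss of mean lumen diameter in
percent. Group comparisons use one-way ANOVA followed by Tukey-Kramer
post hoc pairwise comparisons (studentized-range distribution, valid for
unequal group sizes), significant at p < 0.05; all-constant input
returns the `F = 0, p = 1` convention. The severe-degradation vs
inflammation-score association uses Spearman rank correlation with
midranks for ties, because the Kornowski inflammation grade is ordinal
(0–3); Pearson is available via a flag.

`simulate_lumen_records()` generates per-scaffold clinical records for
the four treatment groups (wall thickness 130 vs 95 um; post-dilatation
none / plain balloon / drug-coated balloon; reduced-alloy variant) with
group-mean LLL 1.0/1.1/0.6/0.5 mm and recoil 6.1/22/1.7/0% — the
reported angiographic group values — plus per-scaffold scatter, and
couples the ordinal inflammation score stochastically to the severe
degradation volume.

## Numerical choices and test-scale conditions

* All randomness is seeded; phantom generation, rendering and training
  are bit-reproducible for a given spec and seed (training is
  single-threaded compiled code).
* Patch and volume dimensions must be divisible by
  `2^n_encoding_stages`; volumes are cropped (never padded) to that
  grid.
* Argmax ties in fusion resolve to the lowest class index; escape
  directions exactly on the 45° cone count as radial.
* The test suite and the acceptance script run at desk scale: phantoms
  of 0.2 mm length and 0.22 mm outer diameter (45/40 um struts, 3
  crowns, 3 links, 2 severe blobs) at the native 3.07 um voxel size
  (~96³ voxels), a 2-stage/8-feature U-Net trained for 60 epochs on 260
  stratified 32² patches, with training and held-out evaluation on
  phantoms of different seeds. These sizes keep a full end-to-end run in
  the minutes range on one CPU while exercising every code path;
  paper-scale runs only change the spec numbers.

## Known limitations

* The phantom's grey-level separation between phases is a free
  parameter; no quantitative contrast calibration is available.
* No reconstruction artefacts (rings, phase fringes) or soft-tissue
  texture are simulated; segmentation accuracy on real beamline data is
  not implied by phantom results.
* `estimate_axis()` assumes an elongated scaffold; stubby volumes need
  an explicit axis or `axis_hint`.
* Lateral regional volumes aggregate both side faces and are therefore
  roughly double a single face, which should be kept in mind when
  comparing luminal/lateral/abluminal magnitudes.
* No neointima or soft-tissue morphometry; the analysis stops at the
  scaffold phases.
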