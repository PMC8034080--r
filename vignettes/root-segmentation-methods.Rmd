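---
title: "Shape-based root segmentation in soil CT: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shape-based root segmentation in soil CT: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the model behind each processing stage, the parameters that matter and
their defaults, what the synthetic phantom does and does not establish,
and the numerical choices made where the design was genuinely open.

## The segmentation model

Roots in a CT scan of repacked soil share their gray-value range with
water films, organic matter and parts of the soil matrix, and the
partial-volume effect spreads every boundary over several voxels. Two
properties remain discriminative: roots are *cylindrical*, and they are
*connected* to the top of the imaged column. The pipeline uses gray
values only to discard what cannot be root (background removal), then
detects cylinders (multi-scale Hessian filtering), then enforces
connectivity and re-admits fragments by object-level shape.

### Background removal

The root average gray value is not fixed across scans (8-bit conversion
stretches each reconstruction differently), but its *position between
two characteristic histogram peaks* is stable: the pot-wall peak P1 and
the soil-matrix peak P2, read from the extended-ROI histogram. With a
factor `f_r` calibrated once per dataset,

    v̄_r = f_r (P2 − P1) + P1,

the absolute difference transform `v_ADT = 255 − |v − v̄_r|` brightens
voxels near the root gray value, and thresholding at
`t_ADT = 255 − R_r/2` keeps exactly the symmetric band
`|v − v̄_r| ≤ R_r/2`. Both `v̄_r` and `t_ADT` are kept as reals and the
band comparison uses the unrounded transform: `t_ADT` is half-integral
for odd `R_r`, and rounding first would move the band edge by half a
gray value.

### The tubeness scale space and its calibrated threshold

The Hessian of a Gaussian-smoothed volume has two strongly negative
eigenvalues across the axis of a bright tube; the response
`sqrt(λ₁λ₂)` (both negative, else 0) is computed with scale-normalized
Gaussian derivative kernels (truncation 4σ, reflected boundaries, the
second-derivative kernel corrected to zero DC so constant volumes give
an exactly zero response). Each filtered volume is normalized so its
maximum maps to 255, which makes the *normalized smoothing strength*
`q = σ/d` the only geometric parameter.

The lower hysteresis threshold is derived, not tuned: a synthetic
anti-aliased cylinder (d = 32 voxels in a 96³ volume) is filtered over a
q grid; for `q ≤ 0.125` the transect across the root is hollow (central
local minimum — those grid points are excluded), above it concave; the
normalized gray value at the original root outline defines `t_opt(q)`.
A small model family (power, exponential, quadratic) is fitted and the
best-R² model — the quadratic on the default grid, R² ≈ 0.94 — is
evaluated at the working point `q = 0.5`, giving `t_opt ≈ 79`. Note that
`t_opt(q)` *increases* with q over the upper concave regime: more
smoothing spreads the normalized response outward, raising the value at
the fixed outline radius.

Detection passes cover diameters `d_min … d_max` in steps of `d_inc`
with `σ_i = q · d_i · f_s`; diameters above the resolution crossover
(default 8 voxels) run on the block-mean half-resolution volume
(`f_s = 0.5`), so the default increment of 4 voxels advances σ by
exactly 1 between coarse passes. The upper hysteresis threshold is a
constant seed level (200 of 255) and not sensitive; the union of all
passes (logical MAX) is the segmentation.

### Postprocessing and recovery

A 3D median (majority vote over a Euclidean ball; the kernel parameter
*is* the ball radius, the convention of the interactive tool whose
printed calibration values 3 and 2 this stage mirrors) smooths surfaces
and removes thin sheet-like debris such as partial-volume shells around
pores. A virtual all-foreground slice spanning the bounded ROI is added
above the stack before 26-connected labeling, so every root segment
reaching the top belongs to the connected system even though the seed is
outside the image. Each remaining object is fitted with its equivalent
ellipsoid (semi-axes `λ_k = sqrt(5 e_k)` from the coordinate covariance
eigenvalues — the solid-ellipsoid moment convention) and scored with

    Rb = λ₁/√(λ₂λ₃),  Ra = λ₂/λ₃,  ν = exp(−Rb²) · exp(−Ra²),

which is ≈ e⁻² ≈ 0.135 for a sphere, ≈ 0.37 for a plate, and → 1 for a
long cylinder. Objects with `ν > t_v` and `λ₃ > t_s` are re-admitted as
false negatives; everything else is discarded.

### Quantification

Skeletonization is sequential simple-point thinning (Malandain–Bertrand
characterization) with endpoint protection, run in three phases: border
directions × 8 checkerboard subfields (no two voxels of a subfield are
26-adjacent, which stops thin grid-aligned runs from unravelling), a
plain directional sweep, and a final sweep that requires only object
connectivity (C* = 1) so the one-voxel-thick medial surfaces that
homotopic deletion must leave inside thick bumpy tubes dissolve into
curves. The voxel skeleton is reduced to a spanning forest (igraph MST
with Euclidean 1/√2/√3 step weights), terminal branches shorter than
1.5× the junction's inscribed radius + 3 voxels are pruned (radial arms
left by thinning; genuine laterals are much longer than their parent's
radius), tips are re-grown along the distance ridge to undo the end
erosion of thinning, and every voxel is laterally re-centered on the
distance-transform ridge. Branch lengths are measured on smoothed path
polylines whose smoothing window grows with the local radius —
centerline wiggles shorter than the tube radius are digitization noise,
and raw voxel-step sums would overestimate a straight run by up to 30%.

Local thickness assigns each voxel the diameter of the largest inscribed
sphere containing it (sphere painting over the exact Euclidean distance
transform; diameter `2·EDT − 1`, the surface-to-surface convention).
Sampling thickness *on the skeleton only* prevents thick roots from
out-voting thin ones; each skeleton voxel contributes its Euclidean step
length to the 1-voxel (45 µm) diameter class of its local thickness, and
lengths are normalized by soil volume into RLD.

## Parameters

Ten parameters are considered tunable (they need recalibration for a new
dataset); `q`, `f_s` and `d_r_inc` are quasi-fixed.

| parameter | default | unit | meaning |
|---|---|---|---|
| `t_con` | 60 | GV | non-local-means strength (≈ 4× the noise sd; decay `h = 0.4 t_con`) |
| `blur_radius` | 0.9 | voxels | unsharp-mask Gaussian sd |
| `mask_weight` | 0.8 | — | unsharp-mask strength |
| `f_r` | 0.18 | — | root gray-value factor between P1 and P2 |
| `R_r` | 70 | GV | root gray-value band width |
| `d_r_min` | 4 | voxels | smallest targeted root diameter |
| `d_r_max` | 28 | voxels | largest targeted root diameter |
| `median_kernel` | 2 | voxels | median ball radius |
| `t_s` | 25 | voxels | recovery size threshold on λ₃ |
| `t_v` | 0.9 | — | recovery vesselness threshold |

Quasi-fixed: `q = 0.5`, `d_r_inc = 4`, `crossover_d = 8`,
`t_high = 200`. The defaults are the published clean-scenario
calibration; the noisy-scenario column (`t_con` 60, blur 1.0, weight
0.7, `f_r` 0.10, `R_r` 65, median 3, `t_v` 0.85) is reached by changing
the corresponding arguments.

For *phantom* runs the unsharp mask weight is 0.5: the phantom's
point-spread (σ = 0.5 voxels) is crisper than real scans, and the
published weight 0.8 — calibrated on blurrier data — overshoots so
strongly on crisp fine roots that their centers leave the ADT band.
This mirrors the method's own prescription that the preprocessing
parameters are calibrated per dataset on a representative image.

## The phantom: what it emulates and what it does not

`phantom_spec()` describes a miniature repacked-soil scan: a pot wall at
gray value 60 thick enough to fill the 50-voxel extended-ROI annulus (so
the histogram shows the wall peak), soil matrix at 150 with blurred
granular texture (sd 6), dark pores (GV 20, 5% of the soil), and six
branching root tubes of 4–28 voxel diameters at gray value
`P1 + 0.18 (P2 − P1) ≈ 76`, rasterized with anti-aliased partial-volume
edges, plus a 0.5-voxel detector blur and optional global noise. Roots
grow as spline-smoothed biased random walks with collision avoidance
(real roots are solid and do not interpenetrate) and a reflective bounce
at the wall; entries spread over the pot area because the 256³
desk-scale pot is ~10× smaller than a real pot while the roots are
real-sized — clustering all entries centrally would crowd the roots far
beyond the emulated geometry.

What a green end-to-end test establishes: the chain recovers ≥ 90% of
the true centerline length within 2 voxels and ≤ 10% surplus on a
noise-free phantom, and degrades gracefully under 10-GV global noise.
What it does not establish: performance on real CT artifacts (beam
hardening, rings, cupping), on field soil heterogeneity, or against
washed-root references — the published recoveries on real benchmarks
(73% noisy / 114% clean scenario) are not desk-reproducible and are not
asserted here.

Truth matching: a skeleton voxel matches a truth centerline point within
2 voxels whose diameter is compatible — local thickness within a factor
of two of the truth diameter with one voxel of slack, because digitized
local thickness has a ≈ 2-voxel floor and a downward bias of about one
voxel on thin tubes.

## Numerical choices and degenerate inputs

* Unsharp mask uses `(v − w G_σ v)/(1 − w)`; other normalizations exist
  and would silently change `R_r`'s meaning.
* The histogram peak search smooths with a weighted 3-bin (1, 2, 1)/4
  average: equally robust to single-bin spikes as a flat average, but an
  isolated peak stays on its bin (a flat average creates a three-way tie
  that the lower-GV tie rule would resolve one bin low).
* Hysteresis growth uses the 26-neighborhood — the permissive choice for
  thin diagonal roots.
* Constant volumes: `percentile_stretch` refuses them (the stretch is
  undefined); `tubeness` warns and returns zeros.
* Single-voxel components get ellipsoid semi-axes floored at half a
  voxel; a one-voxel skeleton has zero length.
* The coarse (half-resolution) detection path underestimates the
  diameter of the thickest roots by 2–3 voxels: block-mean downscaling
  widens the partial-volume edge before filtering. The same
  underestimation (≈ 4 voxels at the thick-root diameter peak) is
  reported for the benchmark implementation of this workflow; it is
  reproduced behavior, not a regression.

## Known limitations

* Thinning-based skeletons of perfectly grid-symmetric even-diameter
  cylinders are degenerate for every sequential algorithm of this family
  (the reference implementations collapse them entirely); the subfield
  scheme here keeps them, at the price of a ≈ ±2-voxel centerline wobble
  that the ridge re-centering largely removes.
* Roots running closer than their combined radii plus the mask's ≈ 2-voxel
  surface halo merge into one object; their skeletons then share a
  medial path. Real scans show the same failure mode.
* Out-of-core processing of full-size (≈ 8.6 GB) stacks is not
  implemented; volumes must fit in memory. Chunked processing is future
  work.
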