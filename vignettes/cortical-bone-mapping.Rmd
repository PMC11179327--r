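---
title: "Cortical bone mapping and tibial morphometry: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cortical bone mapping and tibial morphometry: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cbtmorph)
```

This vignette is the package's own account of the science it implements:
the measurement model, the anatomical constructions, the statistical layer,
and — most importantly — the choices we had to make where a published
description leaves the geometry or the numerics open.

## The thickness measurement model

A CT image of a cortical shell is, locally, a one-dimensional problem: the
intensity along a line perpendicular to the cortex is a three-level step
(soft tissue $y_0$, cortex $y_1$, trabecular bone $y_2$, in HU) convolved
with the scanner point-spread function, modeled as a Gaussian of width
$\sigma$:

$$y(x) = y_0 + (y_1 - y_0)\,\Phi\!\left(\frac{x - x_0}{\sigma}\right)
             + (y_2 - y_1)\,\Phi\!\left(\frac{x - x_1}{\sigma}\right),$$

with $x$ in mm along the line, oriented positive inward so that $y_0$ is
always the outside level, edges at $x_0$ (periosteal) and $x_1$
(endosteal), and thickness $t = x_1 - x_0$. When $t \lesssim 2\sigma$ the
cortex never reaches its true density in the image (the classic
overestimation regime of threshold-based measurements), but if $y_1$ is
*known* the blurred model still pins both edges — this is why the fit runs
twice:

1. **Free pass**: all six parameters fit per profile.
2. **Global density**: the median of per-line $\hat y_1$ over
   high-confidence lines ($\hat t \ge 3\hat\sigma$, where $y_1$ is
   identifiable), one number per bone.
3. **Fixed pass**: every profile refit with $y_1$ fixed at the global
   value.

The density levels enter the model linearly given $(x_0, t, \sigma)$, so
the optimiser (Levenberg–Marquardt with box bounds, `minpack.lm`) runs over
the three nonlinear parameters only and the densities are solved by linear
least squares at every step (variable projection). Initialisation takes
$x_0$/$x_1$ from the extreme gradients of the lightly smoothed profile,
with two fallback thickness starts (1 and 4 mm) to escape the occasional
local minimum of very thick or very thin cortices.

Tunable parameters, defaults, and rationale:

| parameter | default | why |
|---|---|---|
| profile half-length | 9 mm | covers $x_0 + t + 3\sigma$ for shaft cortices up to ~6 mm |
| profile spacing | 0.3 mm | ~2–3 samples per voxel: interpolation-limited, not sampling-limited |
| bounds on $t$ | [0.3, 15] mm | physical cortical range |
| bounds on $\sigma$ | [0.2, 3] mm | clinical-CT PSF range; widen when fitting sharper data |
| density ratio for global $y_1$ | $t \ge 3\sigma$ | beyond this the peak reaches $\approx y_1$ |

A fit is reported unconverged when the optimiser fails or stops on a bound;
unconverged vertices carry `NA` thickness and are excluded from regional
means (their counts are reported, so the exclusion is visible).

## The phantom: what it emulates, and what it does not

Because no patient data ships with the package, every downstream contract
is exercised against a synthetic tibia with known ground truth: a tapered
circular tube along z (distal articular surface at $z=0$, plateau at
$z=L$), cortical thickness varying over height and azimuth, three density
levels (defaults 0/1200/300 HU), Gaussian PSF ($\sigma$ = 0.9 mm),
anisotropic voxels (0.7 × 0.7 × 1.0 mm, the clinical acquisition scale) and
i.i.d. Gaussian voxel noise (20 HU). Defaults: length 350 mm (an adult
tibia at the cohort's stature), 7° constructed varus, plateau tilt 12.2°
(the OA-scale coronal inclination).

The blur is applied *analytically along the surface normal*: for a locally
planar interface, isotropic 3D Gaussian blur equals 1D blur along the
normal, so voxels receive the closed-form blurred profile evaluated at
their radial distance. This keeps the voxel model exactly consistent with
the fit model; the neglected curvature correction is $O(\sigma/R)$ at shaft
radii ($R \approx 11$ mm, $\sigma \approx 0.9$ mm). The design decision to
allow elliptical sections was dropped in favour of circular sections —
every downstream contract (iso-contours, normals, frames, regions, axes)
is exercised identically, and circularity keeps the radial closed form
exact.

What the phantom does **not** emulate: trabecular texture, marrow
heterogeneity, beam hardening, metal artifacts, cortical porosity, and
partial-volume effects at the plateau and malleoli. Passing tests therefore
demonstrate correctness of the *measurement chain* under the stated imaging
model, not robustness to every clinical artifact.

Plateau digitization is emulated by `generate_mct_points()`: eight points
along the outer and inner rims of the medial compartment (two
anterior–posterior rows), with optional in-plane jitter and z noise. The
rim layout mirrors how a plateau is digitized in practice — the concave
centre is avoided — and maximises the baseline of the plane fit; with
0.5 mm z noise it keeps the mean absolute coronal-angle error within the
1.1° measurement precision used as the property bound in the tests. The
in-plane footprint (x 6–25 mm medially, y ±12 mm) is a module choice; no
published coordinates exist for it.

The cohort generator draws per-group Gaussians at the published group
moments (regional SDs back-computed from 95% CIs as
$\sqrt{n}\,\mathrm{halfwidth}/1.96$), with the MCT angle and the
most-proximal-medial standardized CBT jointly Gaussian at the group's
correlation (defaults 0.594/0.554 in the OA groups, 0 in healthy). Margins
are truncated to wide physical ranges by resampling; the bounds sit ≥4 SD
from every mean, so the moment distortion is far below the 1% tolerance the
tests check. Only this single pairwise correlation is modelled; real
regional thicknesses are strongly mutually correlated, which the generator
deliberately omits (the statistics layer treats regions marginally).

## The anatomical frame

Construction order: temporal z-axis through the centres of least-squares
circles fitted in two transverse diaphyseal sections; y-axis from the PCL
attachment to the medial edge of the tibial tuberosity, projected
orthogonal to the temporal axis (anterior positive); the triad completed
right-handed; origin where the true z-axis meets the distal articular
surface.

Three decisions were genuinely open:

- **Where the two sections lie.** We default to 30% and 70% of the mesh
  long-axis extent — the ends of the diaphysis as defined for the regional
  analysis — and expose `section_fracs`.
- **The cross-product order.** Taken verbatim, "x = temporal z × y" gives
  an x-axis pointing *left* when y is anterior and z superior, which
  contradicts the stated "positive right" and right-handedness. We
  implement the only triad consistent with the stated signs:
  $x = y \times z_{temp}$, $z = x \times y$, with $y$ re-derived as
  $z \times x$; anyone comparing numerically against other implementations
  of this construction should check the sign of x first.
- **Side handling.** The frame is always built x-positive-right; left/right
  mirroring happens at sector assignment (medial = $-x$ for a right tibia,
  $+x$ for a left one), not by flipping the frame.

The initial long axis for sectioning comes from the vertex PCA, oriented
distal→proximal by the eminence/talar landmarks, which makes the whole
construction equivariant under rigid motion (verified numerically to
1e-6).

## Regions, bands, and ratios

Height fraction is measured along the true z-axis from the talar-dome
midpoint, divided by tibial length (eminence midpoint to talar midpoint).
Bands are half-open — [0.30, 0.37), …, [0.57, 0.63), with the top band
closed [0.63, 0.70] — and sectors are 90° wedges with half-open
counter-clockwise boundaries (an azimuth exactly on the medial/anterior
boundary is anterior). On phantom meshes fewer than 0.2% of vertices sit on
a boundary, so the convention is immaterial but fixed. Regions with fewer
than 20 converged points (the smallest per-region count observed in
practice) are flagged `low_count` rather than dropped. Whether regional
averages should include unconverged points is unknowable from the method
description; we exclude them and report counts.

Standardized thickness is actual/L × 10³ — an identity the tests check to
1e-9 because downstream group comparisons run on the standardized scale.

## FTA sign convention

The angle is anchored at 180° for a collinear limb and computed as the
signed coronal deviation of the distal tibial direction from the prolonged
femoral axis, positive when the distal tibia deviates toward the body
midline (varus). The anchor and sign follow from the group magnitudes the
measurement is meant to reproduce (healthy ≈ 175–179°, varus OA ≈
187–189°) and from "larger = more varus". The femoral frame and axis are
inputs (the phantom supplies them); this package does not construct femoral
anatomy.

## Statistics layer

- Normality gate at 0.05 per margin/residual set (the gate level is not
  published; 0.05 is the conventional choice and is exposed as
  `gate_level`). Zero-variance residuals (perfectly additive data) carry no
  normality evidence and route to the parametric branch, which handles them
  exactly.
- Repeated-measures ANOVA is fit as the balanced randomized-block
  `aov(value ~ area + subject)` — the identical F test for this one-within
  design — so base `TukeyHSD` applies. The nonparametric branch is Friedman
  with pairwise paired Wilcoxon, Holm-adjusted.
- After Kruskal–Wallis the post hoc is Dunn's rank-mean z test with Holm
  adjustment (hand-coded; the published description says only "post-hoc").
- ICC forms: intra-observer = two-way mixed, consistency, single
  measurement, ICC(3,1); inter-observer = two-way random, absolute
  agreement, ICC(2,1). The published protocol does not name its forms;
  these are the standard choices for "same rater twice" and "different
  raters" respectively, computed from the two-way ANOVA mean squares.
- Sample size for a correlation uses the *exact* sampling density of the
  correlation coefficient under bivariate normality (Hotelling's form, with
  the Gaussian hypergeometric factor evaluated by series and the rejection
  region from the t-test of zero correlation), integrated numerically to
  1e-10. The Fisher-z approximation is provided as a cross-check and
  typically lands within one subject.

## Numerical choices and degenerate inputs

- Surface extraction: per-slice sub-pixel iso-contours
  (`grDevices::contourLines`, largest contour per slice, linear
  interpolation between voxel centres), resampled to equal angular spacing
  and stacked into a ring mesh; normals are in-plane outward
  perpendiculars, matching the in-plane profile geometry. The default
  threshold is the midpoint of the background and densest-material levels
  from the volume histogram.
- Trilinear interpolation truncates profiles that leave the volume (flagged)
  and errors only when a line is fully outside.
- Circle fit: algebraic (Kasa) least squares; degenerate (<3 or collinear
  points) inputs are rejected. Axis and plane fits are total least squares
  via SVD with explicit orthogonal residuals.
- Ray–patch intersection for the frame origin uses Möller–Trumbore over the
  articular patch triangles, keeping the most distal hit.
- Every stochastic component takes an explicit seed; identical seeds
  reproduce volumes, meshes, maps, cohorts and CSV outputs byte-for-byte.

## Problem sizes

The shipped analyses and tests use: a 350 mm default phantom mapped at
~900 diaphyseal vertices (every 4th slice, 24 azimuths — the same order as
the low end of per-subject measurement-site counts in clinical use); a
500-profile accuracy benchmark; 10³ replicates for plateau-noise
properties; 10⁴ replicates for type-I-error checks; and n = 10⁵ cohorts
for moment-recovery checks. Vertex density is configurable
(`slice_step`, `n_azimuth`) because no decimation rule is published for the
clinical point counts.

## Known limitations

- The mapping assumes a locally planar cortex; strongly curved metaphyseal
  regions (outside the 30–70% band) would need curvature-aware profiles.
- Ring meshing assumes star-shaped sections (true for tibial shafts, not
  for arbitrary topology), and section centroids assume the same.
- The cohort model is marginal-plus-one-correlation, not a full covariance
  model of 24 regions.
- CT calibration to physical density (mg/cm³), femoral anatomy
  construction, and registration to weight-bearing radiographs are out of
  scope; poses and femoral axes are inputs.
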