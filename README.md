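# cbtmorph

Cortical bone thickness (CBT) morphometry of the tibia from clinical CT.

Varus knee osteoarthritis concentrates load on the medial compartment of
the proximal tibia, and the cortical shell remodels in response. Studying
that remodeling requires measuring a cortex that is often thinner than a CT
voxel, an anatomical coordinate system that makes regions comparable across
subjects, and alignment angles defined in 3D rather than on a radiograph.
`cbtmorph` implements that entire measurement chain for researchers in
skeletal imaging and knee biomechanics, driven end-to-end by a synthetic
phantom and cohort generator with known ground truth, so the pipeline is
fully testable without patient data.

## What it computes

**Sub-voxel thickness estimation.** CT intensity along a line crossing the
cortex is modeled as a three-level density step blurred by the scanner
point-spread function,

    y(x) = y0 + (y1 - y0) Φ((x - x0)/σ) + (y2 - y1) Φ((x - x1)/σ),

where `y0`, `y1`, `y2` are the soft-tissue, cortical and trabecular levels
(HU), `x0`/`x1` the periosteal/endosteal edges, `t = x1 - x0` the cortical
thickness, `σ` the blur, and `Φ` the standard normal CDF. Profiles are
sampled along surface normals of a sub-voxel iso-contour mesh and fitted by
bounded nonlinear least squares in two passes: a free-density pass, a
robust global estimate of cortical density over wide-cortex lines, then a
refit with density fixed (the constant-density assumption that makes thin
cortices identifiable below the sampling resolution).

**Anatomy and regions.** The anatomical tibial frame is built from
least-squares circles in two diaphyseal cross-sections (temporal z-axis),
the PCL-attachment-to-tibial-tuberosity line (y-axis, anterior), and a
right-handed completion (x right, true z superior), with the origin on the
distal articular surface. The diaphysis (30–70% of tibial length) is split
into 6 height bands × 4 axial sectors = 24 regions; regional means are
reported in mm and standardized by tibial length (×10⁻³), with
medial/lateral and anterior/posterior ratios.

**Alignment morphometry.** The femorotibial angle (FTA) is the coronal
angle between total-least-squares anatomical axes through cross-sectional
centroids (10 femoral, 12 tibial), anchored at 180° and increasing with
varus. The medial-plateau (MCT) coronal inclination is the minimum 3D angle
between the tibial x-axis and the line where the least-squares plateau
plane crosses the tibial coronal plane.

**Statistics.** Shapiro–Wilk-gated test selection (repeated-measures
ANOVA/Tukey vs Friedman; one-way ANOVA vs Kruskal–Wallis/Dunn; Pearson vs
Spearman), variance-components ICC for test-retest reliability, and
sample-size calculation from the exact sampling distribution of the
correlation coefficient under bivariate normality.

## Worked example

Fit one noisy blurred profile across a 3 mm cortex with the cortical
density held at its global estimate:

```r
library(cbtmorph)
p <- generate_line_profile(t = 3, sigma = 0.9, spacing = 0.7,
                           half_length = 9, noise_sd = 20, seed = 7)
f <- fit_profile(p, fixed = list(y1 = 1200))
round(c(thickness_mm = f$t, sigma_mm = f$sigma, rms_hu = f$residual), 3)
#> thickness_mm     sigma_mm       rms_hu
#>        3.052        0.933       19.906
```

The estimate lands within 0.06 mm of the true 3 mm despite 0.7 mm sampling
and 20 HU noise; the residual RMS matches the injected noise level. The
full pipeline on the default phantom (350 mm tibia, 7° varus, 12.2°
plateau tilt; `analysis/01_phantom_pipeline.R`) prints:

```
Synthetic tibia: 350 mm, 936 diaphyseal measurement sites, 936 converged fits
Estimated global cortical density: 1200 HU (true 1200)
Per-vertex thickness MAE vs ground truth: 0.0307 mm
FTA: 187 deg (constructed 187 )
MCT coronal angle: 12.2 deg (constructed 12.2 )
```

i.e. the map recovers the spatially varying ground-truth thickness to
0.03 mm on average and both alignment angles to within 0.1°. The exact-power
sample size for detecting a correlation of 0.554 at α = 0.05 and power
0.80:

```r
sample_size_for_correlation(0.554)
#> [1] 23
```

The `analysis/` scripts run the stages in order (phantom pipeline, profile
accuracy benchmark, cohort statistics, power analysis, reliability) and
write their tables under `results/`.

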