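---
title: "Photogrammetric thoracoabdominal volumetry: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Photogrammetric thoracoabdominal volumetry: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(photoresp)
```

## The measurement model

`photoresp` implements a single-camera photogrammetric model of
thoracoabdominal kinematics during a forced-breathing maneuver performed in
the supine position. Five circular adhesive markers of known diameter
(13 mm) are placed over anatomical landmarks along the trunk midline:
the manubrium sterni (MEd), the xiphoid process (AXd), the inferior angle
of the 10th rib (ACd), the umbilicus (COd) and the right anterior superior
iliac spine (EId). A lateral video of the maneuver supplies two frames —
one at maximal expiration, one at maximal inspiration — and everything
downstream is computed from the marker positions in those two frames.

The chain is:

1. **Detection.** Markers are segmented by Otsu thresholding, labeled as
   connected components, filtered by circularity ($4\pi A/P^2 \ge 0.6$),
   and ranked by circularity x area so the five full-size markers win over
   specks and partial blobs. Centers and diameters are computed at
   sub-pixel resolution: partial edge-pixel coverage of an imaged disc is
   encoded in pixel intensity, so darkness-weighted sums over a slightly
   dilated bounding box give the blob's effective area and centroid.
2. **Calibration.** The physical scale is
   `mm_per_px = 13 / median(detected diameters)`. The median makes the
   scale robust to one misshapen detection.
3. **Landmark assignment.** The five detections are sorted along the
   craniocaudal image axis and labeled MEd through EId. Pixel coordinates
   become physical sagittal coordinates: x in cm from the MEd foot,
   y in cm above the support surface (the image row direction is flipped,
   since rasters grow downward and heights grow upward).
4. **Compartment areas.** The trunk profile is partitioned into four
   compartments, each a quadrilateral bounded above by the straight
   segment joining two adjacent landmarks, below by the support-surface
   baseline (y = 0), and laterally by vertical feet: upper thorax
   (MEd-AXd), lower thorax (AXd-ACd), upper abdomen (ACd-COd), lower
   abdomen (COd-EId). Areas come from the shoelace formula.
5. **Extrusion.** Each area is swept through one uniform depth — the
   caliper-measured thorax length — giving volumes in litres
   ($V = A_{cm^2} \cdot L_{cm} / 1000$), plus the totals TT = UT + LT,
   TA = UA + LA and their sum, the thoracoabdominal volume.
6. **Mobility.** The total volumetric mobility is the thoracoabdominal
   volume at maximal inspiration minus that at maximal expiration. It is
   the kinematic predictor of the regression layer.

### Prediction equations

The package ships two read-only reference equations relating spirometric
outcomes (litres) to height (m), thorax length (cm) and mobility (l),
developed on a cohort of 40 adolescents (14-17 years) screened to a
Tiffeneau index (FEV1/FVC) of at least 0.80:

$$\widehat{FVC} = -8.572 + 5.108\,h + 0.138\,t + 0.120\,m$$
$$\widehat{DI} = -6.373 + 3.751\,h + 0.122\,t + 0.163\,m$$

`fit_mobility_model()` refits the same model form on new cohorts by
ordinary least squares and reports the multiple correlation R, R², and the
standard error of the estimate SEE = sqrt(RSS/(n-4)). The published DI
model's printed correlation and R² are mutually inconsistent at the third
decimal; the shipped JSON stores the self-consistent pair (R = 0.881,
R² = 0.776). The agreement layer provides Pearson correlation tables,
Bland-Altman analysis (bias, n-1 SD of differences, limits at
bias ± 1.96 SD, and a two-sided one-sample t-test of zero bias), and
cohort summary tables. Statistical significance is read at α = 0.05
throughout.

## Geometric design choices

The source protocol leaves the closing boundary of the profile and the
meaning of the extrusion depth open; the package fixes them as follows.

- **Baseline closure.** Compartments are closed on the support surface.
  In the supine position the bed is the only physically motivated
  reference line; it also makes volumes monotone in marker height, which
  a chord-closed profile would not be. The baseline row must be supplied
  with the frames (the synthetic generator records it in its frame
  index); it is a property of the rig, not of the image content.
- **Uniform extrusion depth.** One thorax length extrudes all four
  compartments. No per-compartment depth exists in the protocol, and the
  model makes no anatomical claim about whether the depth is
  anteroposterior or transverse — it is the single metric depth available.
- **Straight segments between markers.** Five points cannot constrain a
  higher-order skin profile; the piecewise-linear profile is the model,
  not an approximation of a known curve.
- **Degenerate inputs.** Zero-height profiles give zero areas; two
  markers within 2 px along the body axis make the craniocaudal ordering
  ambiguous and raise an error rather than guessing; self-intersecting
  polygons are rejected.

## The synthetic-data generator

No recorded video or raw cohort data are distributed, so the generator is
the package's test bed and defines its study conditions.

- **Anthropometrics.** Age, body mass, height and thorax length follow
  truncated normal distributions with the reference cohort's printed
  mean/SD, hard-bounded at the printed min/max. The printed moments
  describe the *observed* (bounded) cohort, so the sampler calibrates each
  variable's location and scale (by quadrature over the latent factor
  below) such that the realized truncated population reproduces the
  printed mean and SD; naive truncation of N(mean, SD) would bias the
  means and shrink the SDs by 15-20%.
- **A shared body-size factor.** Body mass, height, thorax length and
  mobility load on one latent factor with realized pairwise correlation
  0.85. Anthropometrics of real adolescents are strongly correlated, and
  this value is what the reference cohort implies: its mobility-FVC
  correlation (0.812) together with the FVC model's multiple correlation
  (0.931) put the mobility-linear-predictor correlation near 0.87, and
  the resulting synthetic cohorts reproduce the reference outcome
  dispersion (FVC SD ≈ 0.9 l) and refit R² ≈ 0.87. With independently
  sampled predictors the linear predictor's variance would be ~0.40 l²
  and no refit could reach the reference R² at the reference noise level —
  the correlation structure is a property of the population, not a free
  dial.
- **Mobility.** Truncated normal, mean 3.75 l (the difference of the
  printed inspiration and expiration thoracoabdominal means), SD 1.2 l,
  bounded to [1.2, 7.5] l: forced maneuvers always recruit volume, and
  the upper bound keeps the inverse geometry feasible for all sampled
  anthropometries. The SD is a package choice; the protocol does not
  print a mobility SD.
- **Inverse kinematics.** `make_kinematics()` places markers so that the
  package's own forward volumetry reproduces a requested mobility to
  1e-9 l. Expiration compartment volumes are proportioned as the printed
  expiration means (2% log-normal jitter), scaled by height² x thorax
  relative to the cohort means; the mobility is distributed over
  compartments proportionally to the printed inspiration-expiration
  increments (greatest recruitment in the thorax). Only marker heights
  change between phases — supine breathing displaces the anterior wall
  essentially perpendicular to the bed. Landmark x spacing allocates a
  stature-scaled span (40 cm at mean height) to compartment widths
  proportional to area^0.85, which keeps profile heights gently varying
  and strictly positive.
- **Spirometry.** Measured FVC and DI are the reference equations
  evaluated at the subject's true mobility plus Gaussian scatter with the
  equations' SEEs (0.353 and 0.451 l); FEV1 is FVC times a Tiffeneau
  ratio drawn uniformly in [0.81, 0.95] for retained subjects,
  [0.60, 0.78] for obstructive patterns; restrictive patterns get FVC in
  [1.2, 1.8] l. Cohort defaults reproduce the reference screening
  composition: 50 assessed, 7 obstructive, 3 restrictive, 40 analyzed;
  retained FVC is bounded to the analyzed cohort's printed range.
- **Rendering.** Frames are light-background rasters with five filled
  dark circles of diameter 13 mm / mm_per_px, anti-aliased by analytic
  pixel coverage, with optional additive Gaussian noise (8-bit gray
  levels) and a deterministic seed. The ground-truth scale is drawn
  uniformly in [0.55, 0.85] mm/px, the range a tripod-mounted HD camera
  about 2 m from a supine subject produces.

**What the generator does not emulate** — and what passing tests therefore
do not show about real recordings: skin texture, shadows and uneven
illumination; perspective and lens distortion; motion blur; marker
occlusion or detachment; operator variability in frame selection; and any
within-subject trial-to-trial variability of marker placement. The
detector is validated on flat, high-contrast discs; real video frames may
need the manual-coordinate bypass (`read_marker_coordinates()`), which was
the original protocol's digitization mode.

## Numerical choices

- All geometry is double precision; volumes are rounded to 2 decimals
  only in written CSVs, percentages to one decimal at the reporting
  surface (`variability_percent()`, `compartment_share()`).
- Detection ties (equal circularity x area) break toward the smaller
  image x, for determinism.
- The Bland-Altman bias test returns NA instead of a t-statistic when the
  differences are numerically constant (SD below 1e-10 relative).
- Every sampling function takes an explicit integer seed and restores the
  caller's RNG state; cohort-level functions derive per-subject child
  seeds below 2^31 from one master seed.
- The truncated-sampler calibration solves for location/scale by
  Nelder-Mead on a 401-point latent-factor quadrature grid, cached per
  variable; the factor loading solves the realized-correlation equation
  by uniroot to 1e-6.

## Problem sizes used by the test suite

Unit oracles run at small sizes (10-50 random marker sets against a
brute-force rasterized profile at 2000 x 800 grid resolution; one
million Monte-Carlo points for the shoelace check). Statistical claims use
the study scale: cohorts of 40-50 subjects, 500 replicate refits for
coefficient recovery and for the Bland-Altman bias-significance rate, and
1000-subject draws for population-moment checks. The end-to-end imaging
check renders and measures 20 subjects at noiseless settings.

## Known limitations

- The 2D-profile x uniform-depth model is not a surface reconstruction;
  absolute volumes are geometric indices, not gas volumes, and are only
  meaningful comparatively (between phases, within subject) and through
  the calibrated regression layer.
- The reference equations are valid for supine adolescents aged 14-17
  screened free of obstruction/restriction; the package warns on
  out-of-domain (non-positive) predictor values but does not police age.
- The restriction screen requires a user-supplied FVC lower limit; the
  package deliberately ships no reference-value equation for it.
- Detection assumes the five markers are the only dark circular blobs of
  their size class in the frame; a cluttered scene defeats the ranking.
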