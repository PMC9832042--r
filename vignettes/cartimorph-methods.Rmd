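---
title: "Quantifying cartilage aging from histology and immunofluorescence images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cartilage aging from histology and immunofluorescence images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cartimorph)
```

# Overview

Articular cartilage ages in ways that are visible in routine imaging long
before frank degeneration: the articular surface becomes irregular, the
chondrocyte nuclei elongate, and the expression of protective markers such
as α-Klotho declines. `cartimorph` implements a pipeline of image-derived
statistics that quantify these three axes and the associations between
them:

1. a **surface-roughness index** computed from the residuals of a quartic
   fit to the extracted cartilage surface contour;
2. a fixed **53-descriptor nuclear morphometry** vector per segmented
   nucleus, with moments eccentricity as the headline aging marker;
3. **per-cell fluorescence quantification** (integrated density divided by
   cell count, negative-control thresholding, random image selection,
   per-sample averaging);
4. **phenotype statistics**: z-scoring, PCA whose loadings are defined as
   Pearson correlations between the original variables and the component
   scores, top-contributor ranking, silhouette-based group separation, and
   the sample-level regressions `outcome ~ age` and
   `marker ~ age + eccentricity` with a last-added partial R².

Because no public image set accompanies the proteomics deposition for this
kind of study, the package ships a **synthetic cohort generator** that
emulates the statistical structure of the real data — surface masks whose
roughness grows with age group, DAPI images whose nuclear eccentricity
shifts upward with age, and a marker channel whose per-cell intensity
declines with both age and eccentricity — together with exact ground-truth
tables. Every statistical claim the package makes about itself is a claim
about recovery of these programmed effects.

# The surface-roughness index

The tissue mask of the medial tibial cartilage is reduced to a surface
contour: for each column inside the horizontal span of the largest
connected tissue component, the topmost foreground row (the articular
surface faces the joint space at the top of the image). Columns with no
tissue inside the span — torn sections — are excluded rather than
interpolated, so the fit never sees invented surface.

A polynomial of degree exactly 4 is fitted to the contour by ordinary
least squares. Degree 4 is the lowest degree that follows the natural
double curvature of a tibial plateau without chasing local irregularity.
The abscissa is centred and scaled before solving (a raw degree-4
Vandermonde on pixel columns is numerically ill-conditioned) and the
coefficients are mapped back to the pixel domain.

The roughness statistic is

$$R = \frac{E}{L}, \qquad
  E = \frac{1}{n}\sum_i |y_i - \hat y(x_i)|,$$

where $E$ is the mean absolute deviation of the contour from the fitted
curve (an RMS variant is available behind `metric = "rms"` for
sensitivity analysis) and $L$ is the Euclidean distance between the two
contour endpoints — the edges of the measured plateau — so that $R$ is
dimensionless and invariant under uniform image rescaling. Mean absolute
deviation was chosen over RMS because the statistic is defined as a *mean
discrepancy*; the tests verify both metrics against a brute-force
least-squares oracle.

Sample-level inference regresses the per-sample mean $R$ on the ordinal
age-group code (young = 0, middle = 1, aged = 2) by OLS.

# Nuclear morphometry

Nuclei are segmented from the DAPI channel by global Otsu thresholding,
hole filling, connected-component labeling and an area filter
(`min_area`–`max_area`, default 50–5000 px²). Watershed declumping is
deliberately not applied: chondrocytes are sparse in cartilage sections
and the synthetic nuclei never touch, which keeps segmentation from
confounding the morphometry under test. Border-touching objects are
flagged but retained.

Each labeled nucleus is summarised by **exactly 53 descriptors**, frozen
in name and order (`nuclear_feature_names`): 23 geometry descriptors —
area, perimeter, form factor $4\pi A/P^2$, solidity, extent, Euler
number, eccentricity, major/minor axis length, orientation, compactness,
equivalent diameter, max/mean/median radius, min/max Feret diameter,
bounding-box area and aspect ratio, centroid, convex area, circularity
complement — plus 30 Zernike moment magnitudes (orders $n = 0..9$, all
valid repetitions, computed on the binary object mapped to the unit disk
circumscribing its bounding box). This roster matches the size-and-shape
family of descriptors produced by CellProfiler-style object measurement;
texture and intensity features are out of scope by design.

Numerical conventions that matter:

* **Eccentricity** comes from the second central moments: with covariance
  eigenvalues $\lambda_{max} \ge \lambda_{min}$,
  $e = \sqrt{1 - \lambda_{min}/\lambda_{max}}$; 0 for a circle,
  approaching 1 for a line. Collinear (degenerate) objects return
  $1 - 10^{-9}$ and are flagged; the minor axis length is floored at
  $10^{-6}$ px so the vector stays finite. Near $e = 0$ the statistic is
  hypersensitive to pixelation ($e \approx \sqrt{2\delta}$ for a relative
  moment perturbation $\delta$), so small off-grid disks measure
  $e \approx 0.1$; this is a property of the estimator, not an error.
* **Perimeter** uses the four-direction Crofton (pixel-configuration)
  estimator, the same family used by modern CellProfiler/scikit-image.
  Naive pixel-edge counting would overestimate circle perimeters by ~27%
  and destroy the form factor. Crofton can slightly *under*estimate a
  discrete disk's boundary, which would push $4\pi A/P^2$ marginally
  above 1, so the form factor is clamped to 1. Single-pixel objects use
  the convention perimeter = 1.
* **Convex area** counts pixel centres inside or on the convex hull of
  the object's pixel centres, which guarantees solidity ≤ 1.
* **Radii** (max/mean/median) are Euclidean distance-map values inside
  the object; **Feret diameters** are hull-projection widths over 1°
  steps plus one pixel of extent.
* **Orientation** is reported in degrees in $(-90, 90]$, measured from
  the x-axis with y increasing downward.

All moment-based features are verified against an independent per-pixel
double-loop oracle to $10^{-10}$, and rotation/translation invariances
are property-tested.

Sample aggregation follows the study's averaging rule: per-image mean of
each descriptor over the image's nuclei, then per-sample mean over
images. All downstream inference is sample-level ($n$ = animals/donors);
nuclei are never pooled as independent observations.

# Per-cell fluorescence quantification

For each marker image, the **integrated density** is the sum of all pixel
values strictly above a background threshold, over the whole image; it is
divided by the number of cells (segmented DAPI nuclei in the paired
image) to give intensity per cell. The threshold is fixed for the whole
experiment as a high quantile (default 0.999) of a negative-control image
(primary antibody omitted); quantile thresholding operationalises the
standard negative-control practice with a single tunable number. Whole-
image integration (rather than within-mask) matches the conventional
integrated-density readout; a `within_cells` mode is provided as the
alternative. A fixed number of images per sample (default 5, emulating
random field selection at ×20; 10 would correspond to ×63) is selected by
seed-deterministic uniform sampling without replacement, and records are
averaged within samples.

Two exact invariants are tested: linearity (scaling the image by $c$
scales every record by exactly $c$) and additivity over disjoint tiles.

# PCA, loadings, and group separation

The 53 descriptors mix units (px, px², dimensionless), so PCA operates on
the correlation scale: features are z-scored (denominator $n-1$),
zero-variance columns dropped with a warning, and the centred matrix
decomposed by SVD. The **loading matrix is defined as the Pearson
correlation between each original variable and each component score** —
not the eigenvector weights — and variables are ranked per component by
absolute loading (top 10 by default, signs reported alongside). Each
component is oriented so that its largest-|loading| variable loads
positively, making results deterministic despite SVD sign ambiguity. The
closed-form equivalence (loadings = eigenvectors × $\sqrt{\lambda}$ /
column SD on z-scored input) is verified in the tests.

Group separation is summarised by per-group centroids, 95% confidence
ellipses on PC1–PC2, and the mean silhouette coefficient. Two row units
are meaningful and the package computes both:

* **nuclei-level** rows for loading analysis — correlations need many
  observations, and the contributor ranking (is eccentricity a top-10
  driver of PC1?) is asked of the nucleus cloud;
* **sample-level** rows (per-sample mean features) for the separation
  claim — "young and aged animals separate" is a statement about animals,
  consistent with the per-sample averaging rule used for all inference.
  At the default effect size (a 2 pooled-SD eccentricity shift), the
  nuclei-level silhouette has a structural ceiling near 0.3 — two
  unit-variance clusters two SDs apart cannot exceed it — while the
  sample-level silhouette, after averaging ~35 nuclei per animal, is
  ≈ 0.7. The pipeline report carries both numbers.

# Association regressions

Age trends are OLS on the ordinal group code. The marker association
model is the additive sample-level regression

$$\text{marker} \sim \text{age} + \text{eccentricity},$$

chosen over specifications with interactions because no more specific
functional form is defensible at $n$ = animals. The *independent
contribution* of nuclear shape beyond chronological age is
operationalised as the **last-added partial R²**:
$\Delta R^2 = R^2(\text{full}) - R^2(\text{age only})$, reported for both
predictors, with the decomposition identity tested exactly. Predictors
with $|\text{cor}| > 0.99$ are refused as collinear. No multiple-testing
correction is applied anywhere (outcomes are few, pre-specified, and
highly correlated).

# The synthetic cohort generator

`cohort_config()` freezes the study conditions; `generate_cohort()`
renders them to disk (masks as 8-bit PNG, channels as lossless 32-bit
float TIFF, metadata and ground truth as CSV) and
`simulate_cohort_truth()` draws only the tabular ground truth for
simulation studies that need hundreds of replicate cohorts. Identical
config and seed give byte-identical output.

**Surfaces.** A quartic baseline arc plus an i.i.d. Gaussian per-column
perturbation, optionally smoothed by a short moving average (default 3
columns) and variance-renormalised, with SD scaled so the *expected mean
absolute* perturbation equals the requested amplitude; the realised mean
absolute perturbation is stored as truth. Defaults: 1 / 2 / 4 px for
young / middle / aged. The spatial frequency content of real age-related
surface irregularity is unknown, so the smoothing window is exposed as a
parameter rather than fixed.

**Nuclei.** Filled rotated ellipses with semi-major axis uniform on
12–18 px, analytic eccentricity drawn from a truncated normal
(means 0.625 / 0.70 / 0.775 for young / middle / aged, SD 0.075 — a
2 pooled-SD young-to-aged shift, placed low enough on the $e$ scale to
stay clear of the $\sqrt{1-e^2}$ saturation region), uniform orientation,
non-overlapping by construction (rejection sampling with a conservative
boundary gap; chondrocytes are sparse in sections, and this isolates
segmentation from the morphometry under test). Each boundary additionally
carries a small zero-mean radial harmonic irregularity (angular
frequencies 3–6, SD 7% of radius). This irregularity is deliberate and
load-bearing: with mathematically perfect ellipses, all 53 descriptors
are deterministic functions of a single latent axis-ratio factor, and a
dozen of them are strictly more linear in that factor than eccentricity
itself, so eccentricity could never rank among the top PC1 contributors —
an artifact of over-idealised data, not a property of the method. Real
nuclei are irregular, and it is exactly that irregularity that
decorrelates the contour-sensitive descriptors (form factor, Zernike
magnitudes) from the elongation axis. Frequency 2 is excluded from the
harmonics because a $\cos 2\varphi$ radial term *is* elongation: it would
silently perturb the true second-moment eccentricity that the truth table
records. Measured eccentricity stays unbiased (group-mean recovery within
2 SE is part of the test suite).

**Marker channel.** Per-nucleus intensity
$I = \text{intercept(group)} + \text{slope}\cdot e + \varepsilon$, with
defaults 1200 / 1000 / 800 a.u. (linear in the age code so the additive
regression model is well-specified), slope −400 a.u. per unit
eccentricity, and noise SD 50 a.u. Each nucleus is painted uniformly so
that its pixel sum equals $I$ exactly (float TIFF; arbitrary units are
pixel value × `marker_gain`). The background is folded-normal noise, and
a negative-control image drawn from the same background model accompanies
every cohort.

**Cohort layout.** Three ordered groups × 5 samples × 5 fields, 6–8
nuclei per field (30–40 nuclei per sample), 256×256 px fields, 360×160 px
surface masks — sizes at which the full pipeline runs in seconds while
every group contrast is detectable at conventional power.

What the generator does *not* emulate: staining colour and chromatin
texture, overlapping or touching nuclei, out-of-focus fields, uneven
illumination, tissue autofluorescence gradients, and cartilage-vs-bone
segmentation (inputs are pre-made masks). Passing tests therefore
demonstrate correctness of the statistics and recovery of programmed
effects under idealised imaging, not robustness to real-world acquisition
artifacts.

# Reproducibility and problem sizes

A single master seed fans out to per-stage sub-seeds, so any stage can be
re-run in isolation; two runs with the same config produce byte-identical
`report.json` (the provenance block hashes the scientific configuration,
excluding run paths). The test suite exercises: oracle equivalence on 50
random contours; roughness amplitude recovery over amplitudes
{0.5, 1, 2, 4, 8} px × 20 masks; 100-replicate null calibrations for the
trend CI and silhouette; 200-replicate coefficient recovery for the
marker regression (~21 samples, ~10 nuclei per sample, so that per-sample
eccentricity retains sampling noise and the age/eccentricity design stays
estimable); and 100-replicate power for the young-vs-aged intensity
contrast at n = 5 samples/group. Replicated simulations use the tabular
truth generator; the image route is verified once per property on
rendered cohorts.

# Known limitations

* The 53-descriptor roster is a declared convention: the upstream
  tooling's exact feature list and version-dependent perimeter/Zernike
  conventions are not recoverable from any public source, so agreement is
  validated by count, by analytic shape limits, and by oracle equivalence
  of the moment machinery — not descriptor-for-descriptor against another
  implementation.
* Whether the original analysis integrated density whole-image or within
  cell masks, and whether its separation PCA used nuclei or animals as
  rows, are not stated; both choices are exposed as modes and the
  defaults documented above.
* Physical pixel size is not modelled; all lengths are in pixels and the
  roughness index is scale-free by construction.
* The linear mixed-effects alternative to per-sample averaging is out of
  scope; with 30–40 nuclei per sample the averaging rule loses little
  efficiency and matches the original inference unit.
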