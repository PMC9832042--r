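# cartimorph

Quantitative histomorphometry of aging articular cartilage.

Aging cartilage changes in three ways that are measurable from routine
images: the articular surface roughens, chondrocyte nuclei elongate, and
protective markers such as α-Klotho fade. `cartimorph` is an R package for
researchers who want to quantify these axes from 2-D microscopy — tissue
masks, DAPI nuclei images, and paired immunofluorescence channels — and to
test the associations between them at the level of independent samples
(animals or donors).

## What it computes

**Surface-roughness index.** From a binary tissue mask, the surface contour
(topmost tissue pixel per column of the largest component) is fitted with a
polynomial of degree exactly 4; the index is

```
R = E / L,   E = mean |y_i - yhat(x_i)|,   L = ||endpoints||
```

the mean absolute deviation of the surface from the fitted curve,
normalised by the straight-line length of the measured plateau. `R` is
dimensionless and invariant under uniform rescaling.

**53-descriptor nuclear morphometry.** Nuclei segmented by Otsu
thresholding + hole filling + size filtering are each summarised by a
frozen vector of 53 shape/geometry descriptors (23 geometric — including
moments eccentricity `e = sqrt(1 - λmin/λmax)`, Crofton perimeter, form
factor `4πA/P²`, solidity, Feret diameters — plus 30 Zernike moment
magnitudes, orders 0–9). Eccentricity is the headline aging marker: 0 for
a round nucleus, approaching 1 as it elongates.

**Per-cell fluorescence.** Integrated density (sum of above-threshold
pixels, threshold fixed from a negative-control image) divided by the cell
count of the paired DAPI image; a seed-deterministic random subset of
fields per sample; per-sample averaging, so `n` is always the number of
independent samples.

**Phenotype statistics.** Column z-scoring; PCA whose *loadings are the
Pearson correlations between original variables and component scores*,
with top-k contributor ranking per component; silhouette-based young/aged
separation; OLS age trends on the ordinal group code; and the sample-level
association `marker ~ age + eccentricity`, where the "independent
contribution" of nuclear shape is the last-added partial R².

**Synthetic cohort generator.** No public image set exists for this kind
of study, so the package ships a fully seeded generator
(`cohort_config()`, `generate_cohort()`, `simulate_cohort_truth()`)
producing surface masks, DAPI/marker image pairs, a negative control, and
exact ground-truth tables with the programmed age structure: rougher
surfaces, more eccentric nuclei, and dimmer marker in aged groups. All
package-level validation is parameter recovery against this truth.

## Worked example

The default configuration is a complete synthetic study — 3 age groups ×
5 samples × 5 fields, 6–8 nuclei per field:

```r
library(cartimorph)

cfg <- pipeline_config(cohort = cohort_config(seed = 7), seed = 7,
                       out_dir = file.path(tempdir(), "demo"))
report <- run_pipeline(cfg)
```

which writes all stage tables (`roughness.csv`, `nuclei_features.csv`,
`sample_features.csv`, `intensity.csv`, `sample_intensity.csv`,
`pca_scores.csv`, `pca_loadings.csv`, `top_contributors.csv`,
`regressions.json`, `report.json`) under `out_dir` and returns the report:

```
samples: 15   nuclei: 525
roughness ~ age:    slope = 0.00422, p = 1.03e-09
eccentricity ~ age: slope = 0.0729, p = 6.77e-09
PC1 explains 33.4% of nuclear-shape variance; eccentricity in top-10 loadings: TRUE
young vs aged silhouette (animals on PC1-PC2): 0.66
marker intensity/cell, group means: young 955, middle 718, aged 493 (a.u.)
marker ~ age + eccentricity: b_ecc = -683, b_age = -181, R2 = 0.998
```

Reading these numbers: the roughness index climbs ~0.004 per age step
(young → middle → aged) with the generator's 1/2/4 px amplitudes; mean
nuclear eccentricity climbs ~0.073 per step, matching the programmed
0.075; nuclei-level PCA puts eccentricity among the top-10 contributors to
the main shape axis; young and aged animals separate cleanly on the
sample-level PC plane (silhouette 0.66); and per-cell marker intensity
falls with age and with eccentricity — the eccentricity coefficient is
estimated holding age constant, with its partial R² quantifying the
contribution beyond chronological age.

Individual stages are plain functions if you bring your own images:
`extract_surface_contour()` → `compute_roughness()`;
`segment_nuclei()` → `measure_features()` → `aggregate_nuclei_by_sample()`;
`threshold_from_negative_control()` → `intensity_per_cell()` →
`aggregate_intensity_by_sample()`; `zscore_features()` → `run_pca()` →
`group_separation()`; `regress_trend()`, `regress_marker_on_morphology()`.

## Documentation

The methods vignette (`vignettes/cartimorph-methods.Rmd`) documents the
model and its assumptions, all numerical conventions (perimeter estimator,
degenerate-object handling, PC sign fixing), the generator's design and
the features of real data it deliberately does not emulate, and known
limitations.
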