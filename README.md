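# axonmetry

Single-axon morphometry of white-matter cross-sections, with a
ground-truth synthetic-tissue generator that makes every stage of the
pipeline verifiable at the desk.

The package is aimed at quantitative neuroanatomy: studies that measure
myelinated axons one profile at a time in electron- or light-microscopic
cross-sections of white matter — for example comparing the superficial
white matter (SWM, short/medium-range axons with heterogeneous
trajectories) and deep white matter (DWM, parallel long-range fibers)
below a cortical area, across diagnostic groups and across development.

## What it computes

* **Profile morphometry** — segment dark myelin annuli
  (Otsu/fixed threshold, hole filling, border exclusion) and measure each
  profile: maximum-caliper (Feret) major diameter; outer and inner
  diameters perpendicular to the major axis (subpixel moment estimates);
  myelin thickness; g-ratio (inner/outer, conduction-optimal near 0.6);
  aspect ratio `AR = major/minor`; axial orientation angle. Areal-fraction
  density ("relative axon density") in mask and profile-sum variants.
* **Size classes** — exact 1-D k-means (dynamic program over contiguous
  partitions; globally optimal within-cluster SSE) into thin / medium /
  thick / extra-large, or classification by the fixed reference
  boundaries 0.83 / 1.51 / 2.65 μm; the 16-dimension morphometric
  feature vector per case × compartment.
* **Orientation anisotropy** — the trajectory-variability statistic:
  keep elongated profiles (`AR >= 3`), align the modal 10° angle bin to
  90°, take the per-image SD, and weight per-image SDs by the
  elongated fraction; paired SWM-vs-DWM t-test per case.
* **Stereology** — optical-fractionator cell-density estimation with
  systematic random counting frames, inclusion/exclusion edge rule,
  guard zones and disector height, and both noise
  (`sqrt(ΣQ)/ΣQ`) and Gundersen–Jensen coefficients of error.
* **Cohort statistics** — one-way ANOVA within age bands, developmental
  ANCOVA `feature ~ group * age` with per-group slopes, and a covariate
  screen (sex, post-mortem interval, secondary diagnoses).
* **Synthetic tissue** — 3-D axon populations (Watson-mixture
  orientations with optional `|cos θ|` flux weighting, two-population
  diameter law, size-dependent g-ratio), cylinder–plane intersection,
  non-overlapping rendered micrographs with exact ground truth,
  simulated developmental cohorts, and homogeneous 3-D cell populations
  for stereology validation.

## Worked example

```r
library(axonmetry)

## 1. generate a superficial-white-matter micrograph with known truth
params <- tissue_preset("CTR-SWM", seed = 7)
pop <- sample_axon_population(params)
img <- render_micrograph(pop, params, id = "ctr_swm_demo")
pop
#> <axon_population> 60 axons
#>   areal fraction: target 0.34 achieved 0.3394

## 2. segment and measure every myelinated-axon profile
m <- measure_image(img)
m
#> <morphometry> 60 profiles; areal fraction 0.3394 (mask), 0.34 (profile sum)
head(m$profiles[, c("outer_diameter", "inner_diameter", "g_ratio",
                    "ar", "angle_deg")], 3)
#>   outer_diameter inner_diameter   g_ratio       ar angle_deg
#> 1      1.5817611      0.9485149 0.5996575 2.825367 115.13179
#> 2      0.2674904      0.1466492 0.5482408 2.791328 104.10822
#> 3      0.2458590      0.1466455 0.5964618 2.353746  63.13987

## 3. thickness classes (reference boundaries 0.83 / 1.51 / 2.65 um)
round(class_proportions(m$profiles$outer_diameter), 3)
#>        thin      medium       thick extra_large
#>       0.717       0.000       0.267       0.017

## 4. orientation dispersion of elongated profiles (AR >= 3)
s <- filter_elongated(m$profiles)
round(orientation_sd(align_peak_to_90(s$angles)), 1)
#> [1] 56.8

## 5. fractionator density on a simulated 40,000 cells/mm^3 population
cells <- generate_cell_population(c(2000, 2500, 12), c(neuron = 40000),
                                  seed = 7)
fp <- fractionator_params(frame_side = 55, disector_height = 5,
                          guard_zone = 2, grid_spacing = 150,
                          section_thickness = 12)
density_from_counts(fractionator_counts(cells, fp))
#> <stereo_estimate> 45137 cells/mm^3 ( sum Q = 142 )
#>   CE: 0.0839 (noise), 0.0841 (Gundersen-Jensen)
```

Reading the output: the measured areal fraction (0.3394) reproduces the
generator's ground truth exactly; measured g-ratios sit near the
conduction-optimal 0.6 the generator encodes; the per-image orientation
SD of ~57° reflects the heterogeneous superficial-compartment preset
(the deep-compartment preset gives ~7°); and the single-contour
stereological estimate (45,137 cells/mm³ against a true 40,000) deviates
by about 1.5 of its own ~8.4% coefficient of error — which is exactly
why the protocol tracks CE per contour.

The methods vignette (`vignettes/axonmetry-methods.Rmd`) documents the
generative models, measurement conventions, numerical choices and
limitations.

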