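---
title: "Single-axon white-matter morphometry: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-axon white-matter morphometry: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(axonmetry)
```

## Scope

`axonmetry` implements a complete desk-verifiable pipeline for single-axon
morphometry of white-matter cross-sections: a ground-truth tissue
generator, profile segmentation and measurement, thickness classification,
orientation-anisotropy statistics, optical-fractionator stereology, and
developmental-trajectory statistics. Every analysis stage can be driven by
synthetic micrographs whose per-axon truth is known, so measurement
accuracy, estimator bias and statistical calibration are all testable
without any external data.

This vignette documents the generative models, the measurement
conventions, the numerical choices, and the places where the design was
genuinely open — with the reasoning behind each decision.

## The tissue model

### Axons as tilted cylinders

Axons are modeled as straight circular cylinders crossing the section
plane. Sections are thin (50 nm–1 μm) relative to axonal curvature, so
curvature within the section is ignored and each myelinated axon appears
as an elliptical annulus. A cylinder of outer diameter $d$ whose axis
makes angle $\theta$ with the section normal intersects the plane in an
ellipse with

* minor axis $= d$ (exactly),
* major axis $= d/\cos\theta$, and
* aspect ratio $AR = 1/\cos\theta$.

The aspect ratio is capped at `cap_ar = 10`: a real section has finite
thickness, which truncates near-in-plane profiles to finite elongated
shapes rather than unbounded ellipses.

### Orientation law

Axis orientations follow a mixture of Watson-type axial concentrations.
Each component has a mean axis (polar tilt from the section normal plus
in-plane azimuth) and a concentration $\kappa \ge 0$; $\kappa = 0$ is the
isotropic axial law (direction cosine $u = \cos\theta$ uniform on
$[0,1]$). Sampling uses a dense-grid inverse CDF of
$f(u) \propto e^{\kappa u^2}$, with the grid restricted to the
non-negligible mass region so concentrations up to $10^7$ retain
resolution.

An early design used a single Watson component about the section normal
for parallel deep-white-matter fibers. That law cannot produce the
superficial-vs-deep anisotropy contrast at all: with the mean axis along
the normal, the in-plane azimuth of every elongated profile is uniform,
so the per-image angle dispersion is $\approx 52°$ regardless of
$\kappa$. The compartment presets therefore tilt the mean axis away from
the normal:

* **DWM** (deep white matter, parallel long-range fibers): one component,
  tilt 69°, $\kappa = 45$ — elongated profiles share a common in-plane
  direction, per-image SD $\approx 6$–8°.
* **SWM** (superficial white matter, heterogeneous short-range fibers):
  three components at azimuths 0°, 55°, 120°, tilts 71–75°,
  $\kappa = 7$ — elongated profiles spread over many directions,
  per-image SD $\approx 45$–48°.

Tilts were chosen so that roughly 30% of profiles are elongated
($AR \ge 3$), matching the elongated fraction reported for this tissue;
the presets reproduce the *ordering* SD(SWM) > SD(DWM), not any absolute
dispersion value, which the literature does not constrain.

**Flux weighting.** A plane sample of a line process intersects a fiber
with probability proportional to $|\cos\theta|$; the generator applies
this weighting by default (`flux_weighting = TRUE`) via rejection. For
isotropic axes the closed forms are $P(AR \ge k) = 1/k$ without and
$1/k^2$ with flux weighting; both are verified by Monte Carlo at
$n = 10^5$ in the test suite.

### Diameter law

Published summaries for this tissue report a mean outer diameter near
0.77–0.93 μm per compartment *and* ~30% of axons thicker than 1.51 μm.
No unimodal log-normal satisfies both: with mean 0.77 μm at most ~12% of
mass can lie above 1.51 μm. The generator therefore uses an explicit
two-population law mirroring the short-range/long-range fiber
composition of subcortical white matter:

* a **thin/medium component** — log-normal (log-SD 0.38), truncated to
  [0.1, 1.51] μm — representing short/medium-range axons, and
* a **thick/extra-large component** — $1.51 + \mathrm{Weibull}(0.9, 0.30)$
  μm, truncated above at 9.7 μm — representing long-range axons.

The mixture weight *is* the thick-class fraction, and the thin-component
mean is solved in closed form from the target population mean
(`solve_diameter_law()`), so mean caliber and thick fraction are
controlled independently — which is exactly what the developmental cohort
simulation needs. Diameters span 0.1–9.7 μm, the observed biological
range.

### g-ratio law

Per-axon g-ratio (inner/outer diameter) is Normal(0.6, 0.05) with a
size slope of +0.02 per μm of outer diameter about the population mean
diameter, clipped to (0.3, 0.95) — thicker axons have relatively thinner
myelin, and the population average sits near the conduction-optimal 0.6.

### Placement and rendering

Cross-section ellipses are positioned by random sequential
("dart-throwing") placement on the pixel grid: candidates are drawn
uniformly, rasterised with a 2-px exclusion margin, and rejected on any
overlap, largest-first, until the occupied areal fraction reaches the
target. The margin keeps neighbouring annuli separable by
connected-component labelling. Profiles whose capped ellipse cannot fit
the field (near-in-plane thick axons, which a real bounded micrograph
would only show clipped) or that find no free position within the
attempt budget are skipped, counted in the ground truth
(`n_oversize`, `n_unplaced`), and replaced by further draws; generation
fails with the achieved fraction named only if the target remains
unreachable. Skipping slightly truncates the extreme elongated-thick tail
in small fields — one reason the presets keep target fractions below the
random-sequential jamming regime (< 0.6).

Rendering paints a dark myelin annulus (intensity 0.15) between the outer
and inner ellipses, a lighter lumen (0.70) and a light background (0.85),
with optional Gaussian blur and additive noise (both off by default so
tests are exact). Myelin thinner than ~1 px — possible at
light-microscope pixel sizes — would rasterise as a broken ring; the
renderer shrinks the painted lumen to keep a closed ≥ 1.2 px annulus,
mimicking stain saturation of thin sheaths. The ground-truth areal
fraction is the exact occupied-pixel fraction of the placement mask, so
segmentation round-trips are checked against truth at pixel accuracy.

Pixel-size presets: EM-like 0.01 μm/px, LM-like 0.1 μm/px (with the
minimum generated diameter raised to 0.25 μm, the practical LM
resolution limit).

## Measurement conventions

Segmentation inverts the image, thresholds (Otsu by default; fixed
threshold available for constant-exposure protocols), fills lumens,
labels connected components, discards regions below `min_area`
(default: the area of a 0.1 μm circle) and excludes border-touching
profiles by default (unbiased counting-frame logic; switchable).

Per profile:

* **major diameter** — maximum caliper (Feret) of the filled region, via
  the convex hull of pixel centres + 1 px for the half-pixel extents;
* **outer / inner diameter** — the width of the profile and of its lumen
  perpendicular to the major axis through its centre. For elliptical
  profiles this line is exactly the minor axis, so both are computed from
  second central moments ($4\sqrt{\lambda_2}$, with a $1/12$ per-pixel
  variance restoration). A naive pixel-chord reading of the same
  definition carries ±0.5 px endpoint error — up to ~2.5% on a 40 px
  profile — while the moment estimate is subpixel-accurate (worst case
  ~0.2% and ~0.4° over 500 random noiseless ellipses at 0.05 μm/px);
* **aspect ratio and angle** — from the moment ellipse
  ($\sqrt{\lambda_1/\lambda_2}$, axial angle in $[0°, 180°)$ measured
  counterclockwise from the image x-axis). For a true ellipse the moment
  AR equals the caliper ratio, and the suite asserts their agreement on
  noiseless renders. Angles of near-circular profiles ($AR \to 1$) are
  intrinsically undefined; accuracy assertions use $AR \ge 1.3$;
* **myelin thickness** — $(outer - inner)/2$; a fully collapsed lumen
  yields inner diameter 0 with a `collapsed_lumen` flag (kept — such
  profiles still count for density);
* **areal density** — myelin-inclusive, in two variants: the
  thresholded-pixel *mask* fraction of retained profile regions, and the
  *profile-sum* $\sum \pi \cdot major \cdot minor / 4$ over measured
  profiles. Both are reported because the original light-microscopy
  protocol is ambiguous between them; on clean non-overlapping renders
  they agree within 0.01.

## Size classes

Axons are classified by outer diameter into thin, medium, thick and
extra-large. Default classification uses the fixed published boundaries
0.83 / 1.51 / 2.65 μm with half-open intervals (0.83 μm is thin,
0.84 μm is medium), which keeps results reproducible across cohorts.
Re-clustering a new cohort is an explicit choice via `kmeans_1d()`.

`kmeans_1d()` defaults to the exact dynamic program over contiguous
partitions of the sorted diameters — in one dimension the globally
optimal k-means clusters are contiguous, so the global optimum is
computable in $O(kn^2)$. The classic maximin-initialised Lloyd heuristic
(initial centers chosen to maximise between-cluster distances) is
available as `method = "lloyd"`, but on skewed diameter data it stalls in
local optima in the majority of random trials, so the exact method is the
default; the suite checks DP optimality against an independent
enumeration oracle. Class boundaries are midpoints between adjacent final
means: published class ranges are contiguous (…–0.83, 0.84–…), implying
data-gap boundaries, and midpoints are their reproducible analogue.

The 16-dimension feature vector per case × compartment comprises: areal
density (all profiles), areal density (elongated profiles only), mean
outer, inner and major diameters, orientation dispersion (per-case mean
of per-image SDs), mean myelin thickness, mean g-ratio, the four class
proportions, and mean myelin thickness within each class (`NA` marks an
empty class).

## Orientation anisotropy

The trajectory-variability statistic follows the aspect-ratio-filtered,
peak-aligned convention:

1. keep elongated profiles ($AR \ge 3$; near-circular profiles carry no
   reliable direction), recording the kept/total ratio as the image
   weight;
2. align the modal 10°-bin of the axial angle histogram to 90° (ties
   break toward the lowest bin; below 10 angles alignment is skipped and
   flagged). Bins are edge-aligned at 0° so a bin centre is shifted
   exactly onto 90°; alignment is a pure axial shift, so all pairwise
   axial distances — hence the spread — are preserved, including clusters
   wrapping through 0°/180°;
3. per-image dispersion is the plain linear sample SD (n−1
   normalisation) of the aligned angles — mirroring the original plain-SD
   convention; a circular axial SD is provided as an optional column. For
   uniform axial angles the SD approaches $180/\sqrt{12} \approx 51.96°$;
4. case-level summaries: the case SD is the unweighted mean of per-image
   SDs, and the case weighted SD is
   $\sum w_i \mathrm{SD}_i / \sum w_i$ with the elongated-fraction
   weights. The published description of the weighted statistic is
   ambiguous between weighting per-image SDs and weighting angles within
   a pooled SD; this package defines it as the weighted average of
   per-image SDs, which keeps the image as the unit of acquisition;
5. compartments are compared by a paired t-test on per-case SD and on
   weighted SD, both tails reported. Degenerate all-zero differences
   return $t = 0, p = 1$ rather than NaN.

Exact reproduction of the original per-case p values (0.011974, 0.01514)
is out of reach without the raw per-case data; the suite instead verifies
the direction (SD(SWM) > SD(DWM) in every simulated case) and the
detectability at the preset effect size (paired p < 0.05 at n = 10 in
well over 80% of simulations).

## Stereology

`fractionator_counts()` lays a systematic grid of square counting frames
(default 55 μm side, 150 μm spacing) from a uniformly random offset and
counts cells by the unbiased counting-frame rule — inside the frame or on
its inclusion edges (left and top), never on its exclusion edges (right
and bottom) — implemented as the half-open square
$x \in [x_0, x_0+s), y \in (y_0, y_0+s]$, so adjacent frames tile the
plane and count each cell exactly once (asserted exhaustively in the
tests). Cells count only if their z lies within the disector (default
5 μm) between guard zones (default 2 μm top and bottom, protecting
against sectioning damage). Only frames entirely inside the ROI polygon
are used: the alternative origin-inside rule undersamples the edge of a
bounded population. Cells are treated as labelled points (nucleus
centroids); cytologic classification is upstream of this package, and
label filters (e.g. excluding microglia) are plain subsetting. Section
shrinkage is ignored — simulated sections are generated at final
thickness — with a thickness argument as the rescaling hook.

Density is $\Sigma Q / (n \cdot s^2 \cdot h)$ converted exactly to
cells/mm³. Two coefficients of error are always reported, because
protocols often say only "coefficient of error": the Poisson/noise CE
$\sqrt{\Sigma Q}/\Sigma Q$ and the Gundersen–Jensen systematic-sampling
CE (smoothness class m = 1 by default, m = 0 available) computed along a
serpentine frame ordering. Under the published sampling parameters on a
homogeneous 40,000 cells/mm³ population, the mean per-contour CE is
≈ 8.8–8.9%, inside the < 10% protocol bound.

## Cohort simulation and statistics

`generate_cohort()` draws cases in three age bands — children 3–10 y,
teens 14–15 y, adults 30–67 y — with per-group linear age laws for the
four generator-controlled tissue parameters (areal fraction, mean outer
diameter, thick-class fraction, mean g-ratio), per compartment, plus
case-level Gaussian noise. Default band sizes (9 children, 2 teens,
6 adults per group) mirror the cohort structure of the post-mortem study
the generator emulates. The default laws encode the opposite-trajectory
signature: the control group flat in caliber and g-ratio with mildly
rising density and thick fraction; the contrast (ASD-like) group starting
from similar childhood calibers but a lower superficial density, then
declining with age in mean diameter (−0.0035 μm/y), thick fraction
(−0.0018/y) and g-ratio (−0.0009/y). Intercepts reproduce the published
compartment means when pooled over the cohort ages. Each case gets 2–3
images per compartment, either as ground-truth profile tables (fast
`"table"` mode; a nominal field area consistent with the true areal
fraction is attached so density features are defined) or as rendered and
re-measured micrographs (`"render"` mode, exercising the full image
chain; default 30 μm fields at 0.05 μm/px, several hundred profiles per
image — sizes chosen to keep a full cohort round-trip in the order of a
minute).

Statistics follow the original analysis plan: one-way ANOVA on per-case
values within an age band (teens excluded from band comparisons and
described only); ANCOVA `feature ~ group * age` by OLS with treatment
coding, the interaction testing slope differences, with per-group OLS
slopes reported alongside; a covariate screen (Pearson correlation for
continuous covariates, t-test/ANOVA for categorical) with unadjusted
per-test p < 0.05 as in the original analysis and a Benjamini–Hochberg
option off by default. A Kolmogorov–Smirnov gate warns (not fails) on
non-normal inputs before parametric tests. Collinear designs (a group
observed at a single age) are rejected with a diagnostic.

Power properties verified by simulation at the design effect sizes: the
interaction type-I error is 0.05 (calibrated within ±0.02 over 1000 null
cohorts) and power exceeds 0.8 for a −0.005 μm/y slope difference at
residual SD 0.05 μm with 8+8 cases on a fixed uniform 4–67 y age design.
Power is computed on the fixed design, the standard design-power
convention; with ages re-drawn randomly each replicate the quantity
becomes expected power over random designs, which is slightly lower.

## What the synthetic data does and does not show

The generator emulates: annular myelin profiles with correct cylinder
geometry, flux-weighted plane sampling, compartment-specific orientation
structure, realistic diameter/g-ratio laws, areal fractions, cohort age
structure and group trajectories, and homogeneous 3D cell populations.

It does not emulate: organelle texture, unmyelinated axons, glia or
vasculature clutter, touching/overlapping profiles, staining gradients,
section compression, or spatially inhomogeneous cell distributions.
Passing tests therefore demonstrate the correctness and calibration of
the *estimators* on clean geometry, not robustness to the full noise
structure of real micrographs; watershed separation of touching profiles
in real EM montages is explicitly out of scope.

## Numerical choices, in brief

* Moment axes carry a +1/12 px² variance restoration; Feret gets +1 px.
* Otsu on a flat image returns no foreground (warning, empty result),
  not an error.
* k-means boundaries are midpoints between adjacent means; ties in the
  peak-alignment histogram break toward the lowest bin.
* Paired t on identical vectors returns t = 0, p = 1 (not NaN).
* Gundersen–Jensen variance is floored at 0 before the square root.
* All generators accept a seed and are byte-reproducible under it.
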