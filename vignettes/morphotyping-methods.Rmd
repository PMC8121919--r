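---
title: "Morphotyping marine snow: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphotyping marine snow: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snowmorph)
library(dplyr)
```

## The problem

Marine snow — large (> 500 µm) composite detrital particles — carries most
of the vertical carbon flux out of the surface ocean, yet in-situ imaging
pipelines usually reduce each particle to a size measurement. Profiling
cameras such as the Underwater Vision Profiler (UVP) store a greyscale
*vignette* of every detected object, and those images carry far more
information: darkness, shape, boundary complexity, internal heterogeneity.
`snowmorph` implements an objective route from raw vignettes to a small set
of ecologically interpretable *morphotypes* — dark, elongated, flake,
fluffy and agglomerated — and then to the particle-ecology metrics used to
study export: depth-binned concentration profiles, size-spectrum slopes,
Martin-type attenuation exponents, Shannon morphotype diversity and bulk
sinking rates estimated from the deepening of concentration peaks.

## The processing chain

1. **Segmentation** (`binarize()`): foreground = pixels strictly darker
   than a grey threshold (default 240 on a 0–255 scale, particles being
   dark on a light background); if thresholding yields several 8-connected
   components only the largest is kept, so each vignette contributes
   exactly one object. Vignettes with no pixel below the threshold raise a
   distinct "empty object" condition and are skipped (and logged) in batch
   extraction.

2. **Descriptors** (`extract_features()`): 24 per-object quantities in
   four groups — size (area, perimeter, equivalent spherical diameter,
   major/minor axis, convex area), grey intensity (mean/median/min/max,
   integrated grey, darkness = 255 − mean grey), shape (elongation,
   circularity, eccentricity, two reflection symmetries, solidity) and
   structure (grey sd/skewness/kurtosis, grey range, perimeter/area,
   log-perimeter/log-area). The exact membership of descriptor sets varies
   between imaging pipelines; this set follows standard particle-imaging
   conventions while spanning the four groups, and every member is
   documented in `?descriptor_names`.

3. **Trimming** (`trim_extremes()`): for each descriptor, objects outside
   the central `1 − f` quantile interval are removed (default
   `f = 0.001`, i.e. the 0.1 % most extreme values per measurement);
   removal is row-wise — an object extreme in any descriptor is dropped
   once. Trimming removes whole objects rather than winsorizing because
   the extremes are typically segmentation artefacts, not noisy
   measurements of usable objects. The stored bounds are reused at
   projection time to *flag* (not drop) out-of-envelope objects.

4. **Transformation**: the right-skewed size-type descriptors (area,
   perimeter, ESD, convex area, integrated grey, perimeter/area) are
   mapped through `log10(1 + x)`; then every descriptor is centred and
   scaled by constants learned at fit time and reused unchanged at
   projection time.

5. **PCA morphospace** (`fit_morphospace()`): a principal component
   analysis of the standardised table (correlation PCA — the descriptors
   have incommensurate units), keeping 4 components by default. Component
   signs are fixed so each component's largest-magnitude loading is
   positive, which makes fits reproducible across BLAS implementations.

6. **Morphotypes** (`fit_morphotypes()`, `name_morphotypes()`): k-means
   (`stats::kmeans`, Hartigan–Wong) on the PC coordinates with `k = 5`,
   best of 10 random restarts under a caller-supplied seed. We use the
   standard library routine with multiple restarts rather than a bespoke
   k-means++ initialisation: with well-populated clusters and 10 restarts
   the best-of-restarts solution is stable, and the stock implementation
   is easier to audit. Cluster indices are arbitrary, so semantic names
   are attached by deterministic rules on cluster medians, applied in
   order with each rule consuming its cluster: largest median perimeter →
   *agglomerated*; then highest darkness → *dark*; then highest
   elongation → *elongated*; of the last two, higher grey heterogeneity →
   *fluffy*, the remaining one → *flake*. The rule order guarantees a
   bijection. With `k ≠ 5` names fall back to `type_1 … type_k`.

7. **Comparison of classifications** (`align_labels()`,
   `agreement_kappa()`): two labelings of the same objects are aligned by
   the bijection maximising the confusion-matrix diagonal (optimal
   assignment via an internal Hungarian solver, checked against
   brute-force permutation search in the tests), then summarised by
   percent agreement and unweighted Cohen's kappa. When both labelings
   are constant and equal, chance agreement is 1 and kappa is reported as
   1 with a `degenerate` flag.

## Export metrics

* **Concentrations** (`bin_concentrations()`): counts per half-open 5-m
  depth bin divided by the sampled volume (ind L⁻¹); sampled-but-empty
  bins are explicit zeros, unsampled bins are absent.
* **Size spectrum** (`size_spectrum_slope()`): OLS of
  `ln n` on `ln d` where `n = count / (volume × bin width)` is the
  normalized abundance and `d` the geometric bin-centre diameter; bins are
  log-spaced, 5 per octave by default. Only non-empty bins enter the fit.
* **Vertical attenuation** (`attenuation_exponent()`): OLS fit of
  `ln n(z)` on `ln(z / 100 m)`, i.e. the power law
  `n(z) = n_100 (z/100)^b`, over depths in (0, 500] m with positive
  concentration. A more negative `b` means faster loss with depth.
* **Diversity** (`shannon_diversity()`): `H = −Σ p log p` (natural log)
  over per-morphotype concentrations treated as "species".
* **Sinking rates** (`peak_depth_series()`,
  `sinking_rate_regression()`): the depth of the maximum-concentration
  bin is tracked through time (ties to the shallowest bin; optional 3-bin
  smoothing, off by default so the estimate stays oracle-checkable), then
  a type I (ordinary least squares) regression of *time on depth* gives a
  slope in d m⁻¹ whose reciprocal is the bulk sinking speed; non-positive
  slopes are flagged `non-sinking` rather than inverted.
  `max_sinking_speed()` is the companion back-of-envelope bound
  `depth / elapsed` for a single displacement (e.g. 900 m in 10 d →
  90 m d⁻¹).

"Type I regression" is read as ordinary least squares (as opposed to type
II / major-axis regression); with time as the dependent variable this is
the convention used for peak-tracking estimates in the particle
literature.

## The synthetic generator

Every estimator above is exercised against data with known truth.

**Vignettes** (`generate_vignette()`, `generate_population()`): five
archetypes drawn on a white canvas — *dark* (small dark disc), *flake*
(small bright disc), *elongated* (rotated high-aspect ellipse), *fluffy*
(radially perturbed blob, rough boundary, strong grey texture),
*agglomerated* (a chained union of 5–9 overlapping discs). The frozen
default parameters (`archetype_specs()`) were chosen once so the classes
reproduce the qualitative field signatures — dark darkest and most
circular, elongated the highest aspect, flake small/bright/smooth, fluffy
grey-heterogeneous, agglomerated by far the largest perimeter — with the
median perimeter ordering flake < dark < fluffy ≈ elongated ≪
agglomerated. On a mixed population of 2000 such vignettes the full
pipeline (features → morphospace → k = 5 → naming) recovers the generator
labels at ≥ 95 % after label alignment; the first four PCs explain ≈ 87 %
of the variance of the 24 standardised descriptors.

**Fields** (`field_spec()`, `generate_field()`): for each morphotype, a
Gaussian concentration peak leaving the surface at its sinking speed `v`
is superposed on a Martin background `bg (z/100)^b`; counts are Poisson
with mean `volume × n(z, t)`. Defaults: 5-m bins to 1000 m, 112 L sampled
per bin per cast (the campaign-average bin volume), 10 casts pooled per
time point, daily sampling over 20 days. The two field-estimated speeds
(38 m d⁻¹ for dark, 7.2 m d⁻¹ for elongated) are built in; the three
types whose field speeds could not be estimated get plausible mid-range
values (15/20/25 m d⁻¹), and attenuation exponents follow the observed
ranking (dark weakest at −0.4, elongated strongest at −1.5). The
background is held constant above 50 m because the raw power law diverges
at the surface; attenuation-recovery runs therefore fit the 50–500 m
range, and use a peak-free (background-only) field so the Gaussian peak
does not contaminate the power law.

What the generator does *not* emulate: optical blur and sensor noise,
fragmentation/aggregation between depths, advection, the continuum of
intermediate forms between archetypes, or correlated (overdispersed)
counts. Passing recovery tests therefore demonstrates the correctness of
the estimators under the stated sampling model, not the field accuracy of
morphotype classification.

## Numerical choices and degenerate cases

* Perimeter is the exact count of foreground pixel edges exposed to
  background. This is deliberately oracle-checkable; the trade-off is a
  lattice bias — a digital disc has Manhattan perimeter ≈ 8r, so disc
  circularity converges to π²/16 ≈ 0.617 rather than 1, and circularity
  can slightly exceed 1 only for near-square small objects. Comparisons
  *between* morphotypes are unaffected.
* Axis lengths come from the second-moment ellipse with the +1/12 unit
  square correction, so a 1 × n pixel bar has elongation exactly n and a
  single pixel elongation 1.
* Zero-variance grey distributions return skewness and kurtosis 0;
  single-pixel objects use perimeter 4 and a boundary index of 1.
* The 24-descriptor set contains exact linear redundancies (darkness
  mirrors mean grey; grey range mirrors min/max), so the correlation
  matrix is singular by construction. PCA handles this naturally; an
  error (listing the aliased descriptors) is raised only if more
  components are requested than the effective rank.
* Quantile trimming uses type-7 empirical quantiles; with fewer than
  ~1000 objects the 0.1 % rule degenerates to clipping the per-variable
  minima and maxima, so small tables should either raise `trim_fraction`
  or skip trimming. Trimming refuses to drop more than 20 % of rows.
* k-means ties in assignment go to the lowest centroid index;
  `assign_morphotypes()` computes distances per centroid with a
  symmetric expression so mirror-symmetric configurations tie exactly.

## Sensitivity of diversity to k

To check that conclusions do not hinge on the choice of five clusters,
`diversity_sensitivity()` refits k-means at k = 25, 50 and 100 and
recomputes per-stratum Shannon diversity. At these finer partitions each
archetype splits into sub-clusters roughly in proportion to its local
mass, which *inflates* the diversity of strata dominated by one abundant
type; on synthetic data this erodes evenness-level contrasts between two
morphotype-rich strata, while richness-level contrasts (how many
morphotypes are present at all) remain stable at every k. The bundled
phase scenario therefore encodes the qualitative contrast that is
ecologically meaningful and robust: a two-morphotype "under-ice" phase
is strictly less diverse than either morphotype-rich open-water phase at
k = 5, 25, 50 and 100.

## Problem sizes

The test-suite and acceptance runs use desk-scale sizes chosen to keep
estimator standard errors well inside the asserted tolerances: 2000
vignettes for the end-to-end benchmark, 10⁵ diameters for the
size-spectrum slope, 90 depth bins × 10 casts for attenuation, 20 time
points for sinking-rate regressions, and 1500 objects across three
phases for the k-sensitivity analysis.

## A worked example

```{r example, eval = FALSE}
cfg <- pipeline_config(pixel_size_mm = 0.08, seed = 1)
pop <- generate_population(2000, seed = 2)
run <- run_pipeline(cfg, vignettes = pop$vignettes)

glance(run$morphospace)   # components, variance explained
tidy(run$model)           # named centroids in PC space
autoplot(run$morphospace) # loadings
plot_morphospace(run$labels)

# agreement between recovered and true classes
lab <- dplyr::left_join(run$labels, pop$truth, by = "object_id")
glance(agreement_kappa(lab$truth, lab$cluster))
```

## Known limitations

* The morphotype names are a deterministic heuristic codified from the
  field cluster signatures; on data whose clusters do not exhibit those
  signatures the names can mislead even though the partition is valid.
* The classification is only as general as its training set: a
  morphospace fitted on Arctic bloom data (or on the synthetic
  archetypes) will not automatically transfer to systems with different
  particle sources.
* Peak tracking uses bin centres without sub-bin interpolation; sinking
  speeds are quantised accordingly (half a bin per time step), which
  matters for slow sinkers tracked over short windows.
* Carbon fluxes are deliberately out of scope: converting concentrations
  to mass flux requires particle density and porosity, which images alone
  do not constrain.
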