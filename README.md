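# snowmorph

Objective classification of marine snow images into functional
morphotypes, and the particle-ecology metrics built on top of them.

## The problem

Marine snow — large (> 500 µm) aggregates, fecal pellets and other
detrital particles — dominates the vertical export of organic carbon, and
its fate depends strongly on particle morphology, not just size.
Underwater imaging systems (e.g. the Underwater Vision Profiler, whose
object exports circulate through EcoTaxa) produce millions of greyscale
particle vignettes per campaign, but that morphological information is
rarely used quantitatively. `snowmorph` is for plankton and particle-flux
ecologists who want to turn those vignettes into a small set of
reproducible, ecologically interpretable categories and into the standard
export diagnostics.

## What it computes

* **24 morphological descriptors** per particle, spanning size, grey
  intensity, shape and structure, with exact, pixel-countable conventions
  (perimeter = exposed foreground pixel edges, 8-connected objects).
* **A PCA morphospace**: per-variable trimming of the 0.1 % most extreme
  values, `log10(1 + x)` transform of the skewed size descriptors,
  standardisation, then correlation PCA (4 components by default).
* **k-means morphotypes** (k = 5) on the PC coordinates, with
  deterministic naming rules that attach the field-established labels
  *dark, elongated, flake, fluffy, agglomerated* from cluster medians,
  and Cohen's kappa / percent agreement (after optimal label alignment)
  to compare alternative classifications.
* **Export metrics**: concentrations per 5-m depth bin (counts / sampled
  volume, ind L⁻¹); the normalized size-spectrum slope `b` in
  `ln n = ln a + b ln d`; the Martin-type attenuation exponent `b` in
  `n(z) = n_100 (z/100)^b`; Shannon–Wiener diversity of morphotype
  composition; and bulk sinking speeds from a type I regression of the
  time of the concentration maximum on its depth.
* **A synthetic generator** for five visually distinct particle
  archetypes and for depth–time concentration fields with known sinking
  speeds, attenuation exponents and size-spectrum slopes, so the whole
  pipeline is testable without field data.

## Worked example

```r
library(snowmorph)

cfg <- pipeline_config(pixel_size_mm = 0.08, seed = 1)
pop <- generate_population(2000, seed = 2)        # 5 archetypes, known truth
run <- run_pipeline(cfg, vignettes = pop$vignettes)

run$morphospace
#> <snow_morphospace> 4 components over 24 descriptors; trained on 1838 objects ('run')
#> explained variance: 46.0%, 18.0%, 17.5%, 5.3% (cumulative 86.7%)

run$model
#> <snow_morphotypes> k = 5 in 4-D morphospace (seed 1, 10 restarts)
#> clusters: dark, elongated, fluffy, flake, agglomerated

lab <- dplyr::left_join(run$labels, pop$truth, by = "object_id")
agreement_kappa(lab$truth, lab$cluster)
#> <snow_agreement> n = 1860: agreement 99.6%, kappa 0.995
```

The morphospace summary says the first four principal components carry
86.7 % of the descriptor variance; the agreement report says that, after
aligning arbitrary cluster indices to the generator's labels, 99.6 % of
particles land in their true class (kappa 0.995, i.e. far beyond chance).

Sinking speed from a simulated deepening concentration peak:

```r
fld <- generate_field(field_spec(), seed = 3)     # dark sinks at 38 m/d
pk  <- peak_depth_series(dplyr::filter(fld$profiles, morphotype == "dark"))
sinking_rate_regression(pk)
#> # A tibble: 1 × 5
#>   speed_m_per_d slope_d_per_m sinking     n r_squared
#>           <dbl>         <dbl> <lgl>   <int>     <dbl>
#> 1          38.0        0.0263 TRUE       20     1.000
```

The regression of peak time on peak depth recovers the generator's
38 m d⁻¹ sinking speed from Poisson-sampled counts.

Plots: `autoplot(run$morphospace)` (loadings),
`plot_morphospace(run$labels)` (PC scatter by morphotype),
`plot_profile_section(fld$profiles)` (depth–time sections),
`plot_vignette(pop$vignettes[[1]])`.

A thin command-line front end with `extract`, `fit-morphospace`,
`assign`, `profile`, `metrics`, `simulate` and `crossval` subcommands is
installed at `system.file("cli", "snowmorph", package = "snowmorph")`.

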