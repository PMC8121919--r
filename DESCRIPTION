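Package: snowmorph
Title: Morphotype Classification and Export Metrics for Marine Snow Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Objective classification of marine snow particle images into
    functional morphotypes, and the particle-ecology metrics derived from
    them. From greyscale vignettes (such as those exported by the Underwater
    Vision Profiler via EcoTaxa) the package extracts 24 morphological
    descriptors covering size, grey intensity, shape and structure; trims
    extreme values, log-transforms skewed variables, builds a PCA
    morphospace, and partitions it with k-means into named morphotypes
    (dark, elongated, flake, fluffy, agglomerated). Downstream it computes
    depth-binned concentration profiles, size-spectrum slopes, Martin-type
    power-law attenuation exponents, Shannon morphotype diversity,
    inter-classification agreement (Cohen's kappa), and bulk sinking rates
    from the deepening of concentration peaks through time. A synthetic-data
    generator produces particle vignettes of five visually distinct
    archetypes and depth-time concentration fields with known ground truth,
    so the full pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    e1071,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
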