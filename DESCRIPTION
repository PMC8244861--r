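Package: chromaform
Title: Representational Similarity Analysis of Joint Color and Form Coding in Layered Vision Models
Version: 0.1.0
Authors@R:
    person("Chroma", "Form Maintainers", email = "maintainers@chromaform.dev", role = c("aut", "cre"))
Description: Tools for measuring how color and object form are jointly encoded
    across the layers of hierarchical vision models. Provides calibrated
    isoluminant/isosaturated stimulus synthesis in CIELUV and a synthetic
    RGB-based hue/saturation/luminance parameterization, an adapter contract
    for extracting flattened unit activations from named layers of any layered
    model (including seeded random-weight toy convolutional networks),
    second-order representational similarity metrics (per-object color
    similarity matrices, color-space vectors, between-object and cross-layer
    correlations, normalized within-object color distances, form-similarity
    comparisons, multidimensional scaling), permutation nulls via color-label
    shuffling, slope regressions over layer depth with one-sample and
    matched-pairs t tests, and a seeded synthetic unit-population generator
    with a controllable interaction strength between color and form tuning
    for ground-truth validation of every metric.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    png,
    jsonlite,
    digest
Suggests:
    testthat (>= 3.0.0),
    farver
Config/testthat/edition: 3
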