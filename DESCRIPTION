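Package: bandsift
Title: Band-Sifting Material Editing of Photographs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Parametric editing of the apparent material properties of
    objects in photographs (gloss, spots, roughness, stains, blemishes,
    shadows, apparent age) for perception-research stimulus construction.
    The lightness channel of an image is log-transformed and decomposed
    into spatial-frequency subbands with an edge-preserving guided filter;
    each subband is sifted by amplitude (against a one-standard-deviation
    threshold) and sign into quadrants, which group into eight band-sift
    features. Multiplying selected features by a strength factor and
    reconstructing yields controlled, reproducible edits. Includes named
    effects, low-level feature selectors, mask-restricted editing,
    deterministic procedural test fixtures, and a batch pipeline with a
    manifest for factorial stimulus sets.
License: MIT
Encoding: UTF-8
Imports:
    png,
    jpeg,
    Matrix,
    jsonlite,
    yaml,
    tools,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
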