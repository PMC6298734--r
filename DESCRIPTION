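Package: nichepart
Title: Spatial and Dietary Niche Overlap from Trawl Survey and Stomach Content Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies resource partitioning between two demersal fish predators
    from bottom-trawl survey and stomach-content data. Fits delta (hurdle)
    generalized additive models of presence and positive catch rate, predicts
    abundance over a uniform projected grid, standardizes and multiplies the
    fields to index spatial overlap, computes Schoener's similarity of
    prey-weight compositions for dietary overlap on the same grid, and tests
    the correlation between the two overlap dimensions. Includes a synthetic
    survey and diet generator with known, recoverable structure for validating
    every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    mgcv,
    vegan,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
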