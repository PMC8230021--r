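Package: bonje
Title: Feature Selection by Neighborhood Joint Entropy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Greedy forward feature selection for decision tables with
    continuous condition attributes, driven by neighborhood joint entropy: an
    uncertainty measure over neighborhood rough set granules that weights a
    credibility/coverage entropy by the neighborhood approximate precision,
    fusing the algebraic and information-theoretic views of attribute
    dependency. Includes the neighborhood rough set primitives (Minkowski
    granules, lower/upper approximations, approximate precision), a radius
    sweep and stratified cross-validation harness with a built-in 3-nearest
    neighbor classifier, a synthetic decision-table generator with known
    relevant features, CSV/ARFF ingestion, and Friedman/Iman-Davenport/Nemenyi
    statistics for comparing feature-selection algorithms across datasets.
License: MIT
Encoding: UTF-8
Imports:
    foreign,
    jsonlite,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
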