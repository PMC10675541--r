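Package: espqsar
Title: Three-Dimensional QSAR Models from Electrostatic-Potential Grid
    Descriptors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds three-dimensional quantitative structure-activity
    relationship (3D-QSAR) models for hERG potassium-channel blockers from
    volumetric electrostatic-potential (ESP) descriptors.  Molecules carrying
    per-atom partial charges are partitioned into molecular-weight subsets,
    rigidly aligned to a per-subset template by maximizing the cross
    correlation between the template ESP and the target charge density over
    Hopf-fibration-sampled rotations and all grid translations (via FFT),
    described by ESP values solved from Poisson's equation on a common grid,
    reduced by principal component analysis, and regressed onto pIC50 with a
    sigmoid feed-forward neural network trained by backpropagation.
    Includes a seeded synthetic-benchmark generator so the full pipeline is
    testable without external quantum-chemistry input.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    withr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
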