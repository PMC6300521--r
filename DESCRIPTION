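Package: ccasem
Title: Confirmatory Composite Analysis
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Specification, identification, estimation and testing of
    composite models, in which theoretical concepts are operationalized as
    weighted linear combinations (composites) of observed indicators rather
    than as common factors. Model-implied covariance matrices are built
    under the rank-one inter-block constraint, degrees of freedom are
    counted by the composite-model rule, weights are estimated by
    Kettenring's maxvar generalized canonical correlation criterion, and
    overall model fit is tested with a Bollen-Stine bootstrap over the
    squared Euclidean distance, the geodesic distance and the SRMR.
    Includes fit indices (SRMR, NFI, RMS_theta), a catalogue of five
    benchmark population models and a Monte Carlo engine for type-I error
    and power studies of the fit test.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    MASS,
    yaml,
    jsonlite,
    parallel
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
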