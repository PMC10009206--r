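Package: paleotroph
Title: Multi-Proxy Quantitative Dietary Inference for Fossil Birds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for inferring the diet and pedal ecology of fossil birds from
    several independent lines of quantitative evidence: body-mass estimation from
    skeletal regressions with Youden-index cut-points, claw (ungual) outer-arc
    morphometrics, jaw mechanical advantage and functional indices, and
    finite-element strain fields summarized by the intervals method with
    compositional log-ratio transforms. Proxies are unified by phylogenetic
    comparative statistics (Blomberg's K and its multivariate generalization,
    permutation-based pairwise comparison of group means) and by ordination
    (correlation-matrix PCA, flexible discriminant analysis, and phylogenetic
    flexible discriminant analysis) in which fossil rows are projected
    independently of the fitted rotation. Includes seeded synthetic-data
    generators so the whole pipeline can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    picante,
    withr
Config/testthat/edition: 3
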