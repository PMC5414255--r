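Package: equimorph
Title: Geometric Morphometrics and Phylogenetic Signal of Equid Cheek Teeth
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the two-dimensional geometric morphometric analysis of
    occlusal enamel patterns in equid mandibular cheek teeth. Reads tpsDig-style
    landmark/curve files, resamples curves into equidistant semi-landmarks,
    performs generalized Procrustes superimposition with thin-plate-spline
    bending-energy sliding, and provides shape-space statistics (PCA with
    variance-threshold retention, permutation shape ANOVA, MANOVA, canonical
    variate analysis with cross-validated classification and predictive
    assignment) together with a phylogenetic comparative layer (Brownian-motion
    phylogenetic covariance, the multivariate K statistic of phylogenetic
    signal, squared-change-parsimony ancestral shapes and phylomorphospace
    projection). Includes a seeded synthetic-study generator that emulates the
    structure of a multi-taxon, multi-tooth dental dataset so the whole
    pipeline is testable without specimen data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
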