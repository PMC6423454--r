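Package: wingmorph
Title: Landmark-Based Geometric Morphometrics for Mosquito Wing
    Size and Shape
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Landmark-based geometric-morphometric analysis of insect wing
    size and shape, built around the classical toolchain used to compare
    Aedes aegypti populations: generalized Procrustes superimposition and
    centroid size, thin-plate-spline partial-warp shape variables and their
    principal components, between-group Mahalanobis distances with
    leave-one-out validated reclassification, non-parametric permutation
    tests for size and shape differences, the repeatability (intraclass
    correlation) index for digitizing error, and neighbor-joining
    phenograms on between-group shape distances. Includes a TPS landmark
    file reader/writer and a synthetic wing-landmark generator that
    emulates a multi-site, two-sex study design with controllable size
    distributions, shape separations and digitizing noise, so the whole
    pipeline is testable without specimen data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    optparse,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
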