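Package: abundicentre
Title: Testing the Abundant-Centre Hypothesis Across Species Ranges
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for testing the abundant-centre hypothesis in geographic
    space: range geometry (minimum convex polygons, centroids, great-circle
    distances, spherical range areas), per-species Spearman correlations
    between abundance and distance to the range centroid with Fisher's Z
    transformation and ln(n) weights, weighted meta-analytic linear models
    (grand means, backward stepwise F-test selection, all-subsets two-way
    interaction AIC dredging, marginal effects, collinearity screening),
    phylogenetic signal in effect sizes (Pagel's lambda maximum likelihood,
    phylogenetic generalised least squares at lambda 0, 1 and fitted), and a
    synthetic-data generator that emulates the statistical structure of
    compiled abundance, trait and phylogeny data so the whole pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    geosphere,
    jsonlite,
    MASS,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    phytools,
    nlme,
    metafor
Config/testthat/edition: 3
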