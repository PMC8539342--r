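Package: nanoshapes
Title: Unsupervised Shape Classification and Size Metrology of
    Nanoparticles in Electron Micrographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An automated pipeline for statistically representative
    nanoparticle metrology from transmission electron micrographs.
    Segments particles under inhomogeneous backgrounds by locally
    adaptive (dynamic) thresholding, extracts closed particle contours,
    rejects aggregates by convexity filtering, parameterizes particle
    shapes with the seven Hu moment invariants, classifies shapes by
    average-linkage hierarchical clustering with automatic selection of
    the number of clusters from the common local extrema of three
    internal cluster validity indexes (Silhouette, Davies-Bouldin,
    Calinski-Harabasz), and reports per-class size, aspect-ratio and
    eccentricity statistics. Includes a synthetic micrograph generator
    with per-particle ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    grDevices,
    utils,
    tiff,
    png,
    yaml,
    Rcpp,
    EBImage
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
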