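Package: drnkit
Title: Dynamically Responsive Networks from Focal Stimulation of
    Two-Scale Brain Network Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds two-scale structural models of the mouse brain
    (Gaussian short-range coupling on triangulated cortical surfaces plus
    delayed long-range area-to-area coupling), simulates focal stimulation
    of delay-coupled two-variable oscillators poised near an
    Andronov-Hopf bifurcation with Heun's method, and extracts
    dynamically responsive networks (DRNs) by principal-component
    decomposition, gap-statistic k-means clustering and Kabsch alignment
    of response eigenspaces.  Includes structural graph statistics,
    functional-template and sensory-pathway embedding scores, a virtual
    voltage-sensitive-dye observer, and an activation-sequence similarity
    measure, together with synthetic-data generators that make the whole
    pipeline testable without an external connectome atlas.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    cluster,
    jsonlite,
    methods,
    stats,
    tools,
    tiff,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    deSolve,
    igraph,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
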