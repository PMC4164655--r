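Package: mcfractal
Title: Wavelet-Transform Modulus Maxima Analysis of Microcalcification Clusters
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Multiscale detection and fractal characterization of
    microcalcification-like singularities in grayscale lesion images with the
    2D wavelet-transform modulus maxima (WTMM) method. Computes the
    gradient-of-Gaussian scale space, maxima chains, the space-scale skeleton
    and per-line Hoelder exponents; partitions skeleton lines into
    microcalcification and background-tissue classes; estimates the
    singularity spectrum and the fractal dimension of the singularity support
    through the canonical (Boltzmann-weight) multifractal formalism; combines
    the two standard mammographic views (CC and MLO) into a fractal-zone
    verdict with Euclidean LINE/SHEET subtyping; and carries out the
    companion Beta-binomial Bayesian analysis (conjugate posteriors, highest
    density intervals, posterior-predictive checks). Includes seeded
    generators for fractional Brownian surfaces, diffusion-limited
    aggregates, and projected 3D point models, plus a box-counting dimension
    oracle.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    tools,
    stats,
    utils,
    igraph,
    jsonlite,
    png,
    tiff,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pracma,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
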