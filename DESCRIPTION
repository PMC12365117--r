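Package: odekinetics
Title: Kinetic Modeling of Genomic Time Series with the Logistic ODE
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Fits a simplified logistic ordinary differential equation to
    short genomic time series (gene expression, chromatin accessibility) to
    extract interpretable kinetic parameters: a growth/decay rate constant k
    and a saturation level b. Classifies kinetic profiles into switchers,
    accelerators and decelerators from the inflection time, triages fit
    quality with a two-component Gaussian mixture, fits peak-shaped profiles
    piecewise with two logistic segments joined by a quadratic B-spline,
    links candidate cis-regulatory elements (cCREs) to nearest genes with
    enhancer/silencer and mono-/poly-pattern annotation, and predicts gene
    expression trajectories from multi-cCRE accessibility tracks with a
    bidirectional recurrent network. Includes preprocessing (batch
    correction, quantile normalization, polynomial time-course testing) and
    synthetic-data generators for all components.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    splines,
    limma,
    minpack.lm,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
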