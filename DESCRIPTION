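Package: pparClock
Title: Clock-Forced Kinetic Modeling and Circadian Rhythm Statistics for
    Hepatic PPARalpha Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing circadian timecourses of hepatic gene
    expression in factorial (maternal phenotype x post-weaning diet) animal
    studies. Provides qPCR standard-curve quantification with reference-gene
    normalization and ChIP-qPCR percent-input enrichment; a 24-h periodic
    BMAL1 forcing function (empirical spline or entrained oscillator); an
    eight-parameter clock-forced differential equation for relative PPARalpha
    mRNA with Monte Carlo plus conjugate-gradient parameter estimation;
    Latin-hypercube PRCC global sensitivity analysis; trapezoidal 24-h
    area-under-curve summaries with delta-method errors, per-timepoint
    t-tests, two-way ANOVA and Student-Newman-Keuls letter groupings; and a
    synthetic-data generator emulating the cross-sectional study design for
    closed-loop validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    deSolve,
    lhs,
    car,
    Rcpp,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pracma,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
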