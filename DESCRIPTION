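Package: nmrASCA
Title: ANOVA Decomposition and Effect-Filtered OPLS-DA for Factorial NMR
    Metabolomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing one-dimensional 1H NMR metabolomics data
    from crossed factorial designs. Provides fixed-width spectral binning,
    probabilistic quotient normalization, two-way ANOVA decomposition of
    the binned intensity matrix into factor-effect submatrices with
    variance accounting (the ASCA/ANOVA-PCA family), effect-filtered
    PLS-DA and OPLS-DA fitted by NIPALS with eightfold cross-validation
    and permutation testing, correlation-coefficient loading profiles,
    and per-bin unpaired t-tests. A factorial synthetic-spectrum
    generator with recorded ground truth supports end-to-end validation
    of the whole workflow.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2), SummarizedExperiment
Imports: methods, stats, utils, S4Vectors, jsonlite, yaml
Suggests: testthat (>= 3.0.0), knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
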