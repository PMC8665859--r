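Package: methrisk
Title: Sex-Biased DNA Methylation, X-Inactivation Calling and Exposure
    Analysis for Methylation Arrays
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for candidate-gene analysis of Illumina-style DNA
    methylation array data: beta/M-value handling, sample and probe
    quality control, per-probe linear models on M-values with
    empirical-Bayes variance moderation and Benjamini-Hochberg FDR,
    dual statistical/biological (delta-beta) significance calling,
    estimation of female inactive-X methylation from the composite
    array signal with classification of per-gene X-chromosome
    inactivation status, random-intercept mixed models with likelihood
    ratio tests for crossover exposure designs, Welch-t sex-biased
    expression testing, and a synthetic methylation-array generator
    with known ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    lme4,
    multcomp,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: DNAMethylation, DifferentialMethylation, Epigenetics,
    MethylationArray, QualityControl, Software
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
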