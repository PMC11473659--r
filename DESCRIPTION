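Package: glacialsfs
Title: Site Frequency Spectrum Demographic Inference Across Glacial Cycles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative population-genomic inference of effective
    population size (Ne) histories from folded site frequency spectra (SFS).
    Provides coalescent simulators for piecewise-constant and two-deme
    demographies, genotype- and variant-level quality filters including
    HDplot-based paralog detection and windowed paralog-region exclusion,
    folded-SFS construction with hypergeometric downsampling and nucleotide
    diversity estimation, isolation-by-distance regression and scaled
    population differentiation, Poisson composite-likelihood fitting of
    epoch and divergence models with AIC comparison and parametric
    bootstrap, a stairway-style flexible Ne-trajectory estimator, and a
    randomization test for synchronous Ne decreases across species.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    geosphere,
    vcfR,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
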