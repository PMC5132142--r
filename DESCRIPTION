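Package: epiget
Title: Global Test for Gene-Gene Interactions via Random Matrix Theory
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the global epistasis test (GET), a single parametric
    test for the presence of gene-gene interactions relative to a binary
    phenotype. The test compares the case and control SNP correlation
    matrices through the largest eigenvalue of a two-matrix function, with
    the null distribution calibrated against the Tracy-Widom law of order 1
    after Johnstone's logit transformation, centering and scaling. Also
    provides the two-stage benchmark test (case-only trend tests combined by
    Fisher's method), Gaussian-copula genotype and logistic phenotype
    simulators, a marginal-association screening filter, and an experiment
    harness for type-I-error, power and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    deSolve
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
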