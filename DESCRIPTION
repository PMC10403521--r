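Package: gxescreen
Title: Genome-Wide Gene-Environment Interaction Scans for Case-Control Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for genome-wide gene-environment (GxE) interaction analysis
    in case-control studies: a logistic-regression scan engine producing the
    standard 1-d.f. GxE test alongside joint 2-d.f. and 3-d.f. tests, a
    two-step weighted-testing screen driven by the EDGE statistic with
    LD-aware error control, genotype- and exposure-stratified odds ratios,
    Hartung-Knapp random-effects meta-analysis with Cochran's Q and I-squared,
    genomic-inflation diagnostics (lambda and lambda-1000), variant quality
    control (Hardy-Weinberg exact test, call rate, imputation quality), and a
    mixed-effects score test for rare-variant set x exposure interactions
    combining a fixed burden-by-exposure component with a variance-component
    heterogeneity test via Fisher's method. A synthetic multi-study
    case-control generator with configurable allele frequencies, LD blocks,
    exposure prevalence and interaction effects makes every stage testable
    end to end with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    metafor,
    jsonlite
Config/testthat/edition: 3
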