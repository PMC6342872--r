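Package: mrmediate
Title: Two-Step, Two-Sample Mendelian Randomisation with Mediation Analysis
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomisation from GWAS summary
    statistics: reading and harmonising per-SNP association tables to a common
    effect allele, causal-effect estimation by the inverse-variance-weighted,
    weighted-median and MR-Egger estimators, instrument-strength diagnostics,
    bidirectional causal screening among traits, and quantification of
    mediation of an exposure-outcome effect through multivariable IVW
    regression. Includes a summary-statistics simulator with configurable
    horizontal pleiotropy and mediation structure so that every stage of the
    analysis can be validated against known ground truth, and a command-line
    interface for running full studies from flat files.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
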