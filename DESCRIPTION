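Package: ctrlgwas
Title: Control-Selection Strategies for Biobank Case-Control GWAS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to evaluate how control-selection strategies affect
    biobank-scale genome-wide association studies. Simulates confounded
    cohorts with linkage-disequilibrium blocks and subpopulation structure,
    applies sample- and variant-level quality control, assembles
    case-control designs by exhaustive inclusion, seeded random 1:k
    subsetting, or propensity-score nearest-neighbour matching, runs
    covariate-adjusted logistic association scans, clumps significant
    variants into distance-based loci with lead-SNP extraction, and
    quantifies cross-strategy concordance, analytic power, selection
    stability, and compute-cost trade-offs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
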