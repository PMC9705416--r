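Package: epiphase
Title: Phase-Aware SNP-SNP Epistasis Scanning for Case-Control Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Scans phased case-control genotype data for SNP-by-SNP
    interactions with a lead variant under four interaction models
    (phase-independent, cis, trans, and cis-and-trans), using logistic
    regression with likelihood-ratio inference, an eigenvalue-based
    effective-number-of-tests Bonferroni correction, linkage-disequilibrium
    clustering and proxy selection, and a synthetic phased-cohort generator
    for calibration and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    vcfR,
    GenomicRanges,
    IRanges
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
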