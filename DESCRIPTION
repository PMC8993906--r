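Package: svscape
Title: Structural-Variant Landscape Analysis for Cancer Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Cohort-scale analysis of somatic structural variants (SVs):
    breakend-level input/output (BEDPE, minimal Manta-style VCF, BED gene
    models), panel-of-normals filtering and callset matching, footprint
    clustering of per-tumour SVs into simple and complex rearrangements with
    LINE-1 mobile-element annotation, rearrangement-signature extraction by
    non-negative matrix factorisation with consensus patient grouping,
    binned breakpoint hotspot detection under a negative-binomial background
    model with genomic covariates and a three-method focal consensus, and
    driver-gene recurrence counting from SV spans. A synthetic cohort
    generator with known ground truth (covariate-driven negative-binomial
    breakpoint rates, implanted hotspots, driver deletions and mobile-element
    insertions) makes every stage testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    IRanges,
    S4Vectors,
    GenomicRanges
Suggests:
    withr,
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
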