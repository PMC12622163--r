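Package: pgiport
Title: Cross-Ancestry Portability of Polygenic Indexes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify how well polygenic indexes (PGIs) trained in
    one genetic ancestry transfer to another. Implements observed relative
    accuracy (the ratio of incremental R-squared between a target and a
    reference ancestry), a theoretical expected relative accuracy built from
    cross-population linkage-disequilibrium and allele-frequency summaries of
    candidate causal SNPs, and the decomposition of the observed accuracy
    loss into the share explained by LD/MAF and by heritability differences.
    Includes PCA-based ancestry assignment, phenotype residualization,
    dosage-based PGI scoring, LD clumping and pruning, bootstrap, jackknife
    and delta-method inference, and a two-population Balding-Nichols
    genotype simulator with tunable local LD, cross-population effect
    correlation and stratification confounding, so the whole pipeline is
    testable without restricted biobank data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
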