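Package: pleioconj
Title: Cross-Trait Pleiotropy Analysis with Conditional and Conjunction FDR
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies shared genetic signal between two traits from GWAS
    summary statistics. Implements stratified fold-enrichment curves of
    primary-trait association conditioned on secondary-trait significance,
    empirical conditional and conjunction false discovery rates with binned
    two-dimensional lookup tables, greedy LD-rank clumping, named-region
    (e.g. extended MHC) exclusion with LD propagation, and a functional
    follow-up layer (cis-eQTL additive-model tests, pooled-region
    differential expression, brain cell-type assignment). Includes a
    block-structured simulator of paired summary statistics with a
    four-component null/trait-specific/pleiotropic causal mixture for
    calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
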