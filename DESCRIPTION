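Package: pleioscan
Title: Multi-Trait GWAS Meta-Analysis, Resampling Significance, and
    Colocalization for Pleiotropic Locus Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for N-weighted multivariate meta-analysis (N-GWAMA) of
    correlated GWAS summary statistics, an empirical experiment-wide
    significance threshold obtained by max-|Z| resampling from a correlated
    multivariate normal null, sentinel/locus definition with pleiotropy and
    novelty filters, and Bayesian colocalization of trait-trait and
    trait-molecular-QTL signals via Wakefield approximate Bayes factors,
    including approximate conditional analysis for allelic heterogeneity.
    Ships a synthetic summary-statistics generator (LD blocks, sample-overlap
    correlation, planted causal variants) so the whole cascade is testable
    without access-controlled data, plus a published reference table of
    atherosclerosis multi-trait sentinel SNPs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
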