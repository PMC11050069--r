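Package: ploidysig
Title: Consensus Transcriptomic Signatures of Polyploidy Across Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers consensus transcriptomic signatures of polyploidy from
    multiple independent diploid-versus-polyploid cohorts. Provides quantile
    normalization and empirical-Bayes moderated t-testing per cohort,
    sign-consistent consensus calling across cohorts through an ortholog map,
    master-regulator detection by protein-interaction enrichment analysis
    (PIEA) on one-step interactome neighborhoods, hypergeometric gene-signature
    over-representation with observed/expected ratios and Benjamini-Hochberg
    false discovery rates, MCODE molecular-complex extraction, and external
    signature overlap validation. A synthetic multi-cohort generator with
    planted ground truth supports end-to-end recovery and calibration testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    limma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
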