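Package: pfasmeta
Title: Cross-Species Meta-Analysis of Transcriptional Responses to PFAS
Version: 0.1.0
Authors@R:
    person("pfasmeta", "developers", email = "pfasmeta@example.org",
           role = c("aut", "cre"))
Description: Tools for integrating differential-expression results from
    PFAS (per- and polyfluoroalkyl substances) exposure experiments across
    species. Per-contrast signed significance signatures
    (-log10(p) x sign(log FC)) are mapped to a common human-ortholog gene
    space (mapping tables or reciprocal best hits), compared by Pearson
    correlation, and combined by species-balanced weighted Stouffer
    integration with Benjamini-Hochberg correction and conserved-gene
    classification. Includes permutation-based gene set enrichment with
    cross-contrast NES integration, correlation-based metabolite response
    prediction from a paired transcriptome/metabolome reference, a
    negative-binomial multi-species simulator with planted ground truth,
    and a config-driven pipeline driver.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
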