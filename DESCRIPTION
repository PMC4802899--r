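Package: drynet
Title: Drought-Responsive Multi-Omics Correlation Networks and Promoter
    Motif Enrichment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds condition-specific metabolite correlation networks with a
    permutation null, stage-wise treatment response tables (log2 fold change
    and one-way ANOVA), merged metabolite-transcript association networks
    with top-k gene correlators, and cis-regulatory motif / GO-slim
    enrichment by the hypergeometric test. Includes a synthetic multi-omics
    generator that plants correlation modules, treatment-dependent module
    coupling, gene-metabolite links and promoter motif instances with full
    ground truth, so every stage of the pipeline can be exercised and
    validated without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
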