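Package: seednet
Title: Seed-Gene Co-Expression Network Discovery and Regulator Prioritization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers the conserved co-expression network of a seed gene
    across many expression datasets and prioritizes its upstream regulators.
    Provides a per-condition double-filter screen (differential expression
    after median stratification by the seed gene, plus a Spearman correlation
    screen), cross-condition intersection filtering, independent-dataset
    validation, annotation enrichment summaries, multi-database consensus
    voting for transcription factors and miRNAs, coherent net-effect scoring
    of regulator perturbation (knockdown/knockout) datasets, cross-species
    expression conservation statistics, single-cell dot-plot summaries, and
    immunoblot densitometry normalization. A seeded synthetic-data generator
    with planted ground truth stands in for public downloads and powers
    recovery benchmarks.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Matrix,
    methods,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
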