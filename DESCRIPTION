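Package: diffscreen
Title: Differential Analysis of Isogenic High-Throughput Drug Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for multi-plate cell-viability compound
    screens run under two isogenic conditions (for example an oncogene-high
    versus oncogene-knockdown cell line pair). Implements LOESS-log spatial
    plate normalization, robust hit calling by the median - 3*MAD rule,
    classification of condition-selective compounds by a two-fold viability
    criterion, evidence filtering and merging of drug-target affinity and
    chemical-protein interaction tables, detection of exclusive and
    overrepresented target genes (Fisher's exact test with
    Benjamini-Hochberg correction), functional term enrichment, annotated
    compound-target network construction with SIF/GraphML export, and
    four-parameter logistic dose-response fitting. A synthetic-screen
    generator with a full ground-truth manifest makes every stage testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    igraph,
    minpack.lm,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
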