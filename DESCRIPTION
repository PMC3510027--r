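Package: screensift
Title: Hit Calling, GO Enrichment, and Network Analysis for Arrayed RNAi
    Toxicity Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for arrayed siRNA suppressor screens read
    out by kinetic caspase 3/7 fluorescence. Computes per-well enzymatic
    activity (change in RFU per minute per milligram protein) from kinetic
    plate reads, removes plate position effects by per-position batch
    averaging, scales wells to on-plate negative controls, aggregates
    replicates, and calls suppressor hits by a mean-plus-standard-error
    criterion against a screen-wide standard-deviation cutoff. Downstream,
    it performs Parent-Child-Union Gene Ontology enrichment with
    Benjamini-Hochberg correction, term-level filtering, and a
    two-proportion z-test quality-control filter against the screened
    library, and builds hit networks (direct-connection and
    shortest-path-augmented) over a user-supplied interactome. A
    synthetic-data generator produces screens, ontologies, and
    interactomes with known ground truth for calibration and testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
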