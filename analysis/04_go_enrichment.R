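#!/usr/bin/env Rscript
# Parent-Child-Union GO enrichment of the synthetic study set against the
# genome-scale population, BH-corrected, level-filtered, and QC-filtered
# against the screened library with the two-proportion z-test.

source("analysis/00_common.R")

d <- file.path(DATA_DIR, "ontology")
dag <- parse_obo(file.path(d, "ontology.obo"))
print(dag)
annots <- propagate(dag, parse_gaf(file.path(d, "annotations.gaf")))

res <- enrich(dag, annots,
              study = readLines(file.path(d, "study_genes.txt")),
              population = readLines(file.path(d, "population_genes.txt")),
              library_genes = readLines(file.path(d, "library_genes.txt")))
fwrite(res, file.path(RESULTS_DIR, "enrichment.tsv"), sep = "\t")
export_dag_graph(res, dag, file.path(RESULTS_DIR, "enriched_terms.dot"))

kept <- res[res$kept == TRUE, ]
cat(nrow(res), "terms tested;", nrow(kept),
    "survive BH <= 0.05, level > 2, and the QC proportions filter\n")
print(kept[, c("term", "level", "study_count", "pop_count", "p_adj",
               "qc_z", "qc_p")])

truth <- jsonlite::read_json(file.path(d, "ontology_truth.json"))
planted <- unlist(truth$planted)
cat("planted terms recovered:", sum(planted %in% kept$term), "of",
    length(planted), "\n")
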