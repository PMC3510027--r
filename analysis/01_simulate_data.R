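#!/usr/bin/env Rscript
# Generate the synthetic study data: a 2,000-pool siRNA screen with 100
# spiked suppressors (effect 0.4, replicate noise SD 0.05, triplicate,
# 30-plate days), an ontology with two planted 10x-enriched deep terms,
# and an interactome with a planted seed clique and bridged seed pairs.

source("analysis/00_common.R")

scr <- generate_screen(file.path(DATA_DIR, "screen"), n_sirna = 2000L,
                       n_spiked = 100L, effect_range = c(0.4, 0.4),
                       noise_sd = 0.05, seed = SEED)
cat("screen: 2000 siRNA pools,", length(scr$truth$spiked),
    "spiked suppressors,", length(scr$truth$plate_scales), "plates\n")

ont <- generate_ontology(file.path(DATA_DIR, "ontology"), n_planted = 2L,
                         fold = 10, seed = SEED)
cat("ontology: planted enriched terms:",
    paste(ont$truth$planted, collapse = ", "), "\n")

net <- generate_interactome(file.path(DATA_DIR, "interactome"),
                            seed = SEED)
cat("interactome: clique", paste(unlist(net$truth$clique), collapse = " "),
    "| connectors", paste(net$truth$bridges$connector, collapse = " "), "\n")
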