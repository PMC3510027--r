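#!/usr/bin/env Rscript
# Reduce kinetic fluorescence reads to per-well caspase 3/7 activities
# (OLS slope in RFU/min divided by well protein mass in mg).

source("analysis/00_common.R")

d <- file.path(DATA_DIR, "screen")
act <- compute_plate_activities(file.path(d, "kinetics.csv"),
                                file.path(d, "protein.csv"),
                                file.path(d, "layout.csv"))
write_activity_tsv(act, file.path(RESULTS_DIR, "activities.tsv"))

cat(nrow(act), "wells on", length(unique(act$plate_id)), "plates\n")
neg <- act$activity[act$role == "neg_control"]
pos <- act$activity[act$role == "pos_control"]
cat(sprintf("negative-control activity median %.0f RFU/min/mg; positive
control (CASP3 siRNA) median %.0f (%.0f%% of negative)\n",
            median(neg), median(pos), 100 * median(pos) / median(neg)))
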