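# Shared settings for the analysis drivers. Run the scripts in order from
# the repository root:
#   Rscript analysis/01_simulate_data.R
#   Rscript analysis/02_plate_activity.R
#   ...
# All computation lives in the screensift package; these scripts only wire
# stages together and report what they find under results/.

library(screensift)
library(data.table)

SEED <- 20260928L
DATA_DIR <- "results/data"
RESULTS_DIR <- "results"
dir.create(DATA_DIR, recursive = TRUE, showWarnings = FALSE)
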