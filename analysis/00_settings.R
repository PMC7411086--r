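# Shared settings for the analysis workflow. Every script can be re-run on
# its own; stages communicate through the CSVs under results/.
library(phaeotox)

SEED <- 1L
DATA_DIR <- "results/data"
OUT_DIR <- "results/tables"
dir.create(DATA_DIR, recursive = TRUE, showWarnings = FALSE)
dir.create(OUT_DIR, recursive = TRUE, showWarnings = FALSE)

CONFIG <- experiment_config(seed = SEED)   # study design, 6 doses x 3 reps
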