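#!/usr/bin/env Rscript
# Generate the synthetic experiment: all instrument-level input tables for
# the 6-treatment x 3-replicate fluoxetine exposure, with known ground truth.
source("analysis/00_settings.R")

bundle <- generate_bundle(CONFIG)

write_table(bundle$growth, file.path(DATA_DIR, "growth_series.csv"), SEED)
write_table(bundle$transients, file.path(DATA_DIR, "ojip_transients.csv"), SEED)
write_table(bundle$spectra, file.path(DATA_DIR, "absorbance_spectra.csv"), SEED)
write_table(bundle$fa, file.path(DATA_DIR, "fame_peaks.csv"), SEED)
write_table(bundle$assays$endpoint, file.path(DATA_DIR, "assay_endpoints.csv"), SEED)
write_table(bundle$assays$kinetic, file.path(DATA_DIR, "assay_kinetics.csv"), SEED)
write_table(bundle$biochem, file.path(DATA_DIR, "biochem_masses.csv"), SEED)

truth <- bundle$ground_truth
message(sprintf("simulated %d doses x %d replicates (seed %d)",
                length(CONFIG$doses), CONFIG$n_replicates, SEED))
message(sprintf("ground-truth IC50 %.1f ug/L; top-dose inhibition %.1f%%",
                CONFIG$true_ic50,
                truth[[as.character(max(CONFIG$doses))]]$inhibition_pct))
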