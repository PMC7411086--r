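#!/usr/bin/env Rscript
# Oxidative-stress conversions (MDA, CAT, APX, SOD) and the cellular energy
# allocation model (Ea, Ec, CEA).
source("analysis/00_settings.R")

endpoint <- read_table(file.path(DATA_DIR, "assay_endpoints.csv"),
                       c(a532 = "numeric", a600 = "numeric",
                         sod_sample_rate = "numeric",
                         sod_control_rate = "numeric", protein_mg = "numeric",
                         dose_ug_per_l = "numeric", replicate = "numeric"))
kinetic <- read_table(file.path(DATA_DIR, "assay_kinetics.csv"),
                      c(time_s = "numeric", absorbance = "numeric",
                        assay = "character", dose_ug_per_l = "numeric",
                        replicate = "numeric"))
biochem <- read_table(file.path(DATA_DIR, "biochem_masses.csv"),
                      c(carb_mg = "numeric", protein_mg = "numeric",
                        lipid_mg = "numeric", cells = "numeric",
                        dose_ug_per_l = "numeric", replicate = "numeric"))

stress <- assay_analysis(endpoint, kinetic)
write_table(stress, file.path(OUT_DIR, "oxidative_stress.csv"), SEED)

ets_keys <- unique(kinetic[kinetic$assay == "ets",
                           c("dose_ug_per_l", "replicate")])
ets <- do.call(rbind, lapply(seq_len(nrow(ets_keys)), function(k) {
  trace <- kinetic[kinetic$assay == "ets" &
                     kinetic$dose_ug_per_l == ets_keys$dose_ug_per_l[k] &
                     kinetic$replicate == ets_keys$replicate[k], ]
  data.frame(dose_ug_per_l = ets_keys$dose_ug_per_l[k],
             replicate = ets_keys$replicate[k],
             da490_per_min = kinetic_rate(trace))
}))
budget <- energy_analysis(biochem, ets)
write_table(budget, file.path(OUT_DIR, "energy_budget.csv"), SEED)

top <- max(budget$dose_ug_per_l)
message(sprintf("MDA control %.2f uM vs top dose %.2f uM",
                mean(stress$mda_um[stress$dose_ug_per_l == 0]),
                mean(stress$mda_um[stress$dose_ug_per_l == top])))
message(sprintf("CEA control %.3g vs top dose %.3g (per-mM formazan reading)",
                mean(budget$cea[budget$dose_ug_per_l == 0]),
                mean(budget$cea[budget$dose_ug_per_l == top])))
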