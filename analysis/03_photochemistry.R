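#!/usr/bin/env Rscript
# JIP-test parameters from the OJIP transients, with dose statistics.
source("analysis/00_settings.R")

tr <- read_table(file.path(DATA_DIR, "ojip_transients.csv"),
                 c(time_s = "numeric", fluorescence = "numeric",
                   dose_ug_per_l = "numeric", replicate = "numeric"))
jip <- jip_analysis(tr)
write_table(jip, file.path(OUT_DIR, "jip_parameters.csv"), SEED)

for (endpoint in c("phi_p0", "abs_cs", "tr_cs", "aoec")) {
  kw <- kruskal_wallis_letters(jip[[endpoint]], jip$dose_ug_per_l)
  sp <- spearman_dose(jip[[endpoint]], jip$dose_ug_per_l)
  message(sprintf("%-8s KW H=%5.2f p=%.3f | signed rho^2 = %+.2f",
                  endpoint, kw$h, kw$p_value, sp$signed_rho_sq))
}
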