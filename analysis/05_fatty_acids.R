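#!/usr/bin/env Rscript
# FAME quantification, saturation classes and the double bond index.
source("analysis/00_settings.R")

fa_tab <- read_table(file.path(DATA_DIR, "fame_peaks.csv"),
                     c(fa_id = "character", peak_area = "numeric",
                       dose_ug_per_l = "numeric", replicate = "numeric"))
fa_tab$is_standard <- fa_tab$is_standard == "TRUE"
res <- fa_analysis(fa_tab, is_mass = 25)
write_table(res$profiles, file.path(OUT_DIR, "fatty_acid_profiles.csv"), SEED)
write_table(res$summaries, file.path(OUT_DIR, "fatty_acid_summaries.csv"), SEED)

s <- res$summaries
message(sprintf("control DBI %.2f; top-dose DBI %.2f",
                mean(s$dbi[s$dose_ug_per_l == 0]),
                mean(s$dbi[s$dose_ug_per_l == max(s$dose_ug_per_l)])))
for (endpoint in c("sfa_pct", "pufa_pct", "dbi")) {
  sp_t <- spearman_dose(s[[endpoint]], s$dose_ug_per_l)
  message(sprintf("%-8s signed rho^2 = %+.2f", endpoint, sp_t$signed_rho_sq))
}
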