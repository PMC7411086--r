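#!/usr/bin/env Rscript
# Specific growth rates, relative growth inhibition and the IC50 fit.
source("analysis/00_settings.R")

growth <- read_table(file.path(DATA_DIR, "growth_series.csv"),
                     c(time_h = "numeric", density_cells_per_ml = "numeric",
                       dose_ug_per_l = "numeric", replicate = "numeric"))
res <- growth_analysis(growth)
write_table(res$rates, file.path(OUT_DIR, "growth_rates.csv"), SEED)
write_table(res$inhibition, file.path(OUT_DIR, "growth_inhibition.csv"), SEED)

message(sprintf("control growth rate %.2f /day",
                mean(res$rates$mu_per_day[res$rates$dose_ug_per_l == 0])))
print(res$fit)

# the study's desk-reproducible anchor points, for comparison
anchor <- fit_ic50(c(0, 40, 80), c(0, 39, 83))
message(sprintf(
  "IC50 from the published anchor inhibitions (39%%/83%%): %.1f ug/L",
  anchor$ic50))
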