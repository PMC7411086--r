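#!/usr/bin/env Rscript
# GPS deconvolution of the whole-cell absorbance spectra.
source("analysis/00_settings.R")

sp <- read_table(file.path(DATA_DIR, "absorbance_spectra.csv"),
                 c(wavelength_nm = "numeric", absorbance = "numeric",
                   dose_ug_per_l = "numeric", replicate = "numeric"))
pig <- pigment_analysis(sp)
write_table(pig, file.path(OUT_DIR, "pigments.csv"), SEED)

lib <- gps_library()
message(sprintf("template Gram condition number: %.0f",
        fit_pigments(model_spectrum(setNames(rep(1, 7), lib$pigments), lib),
                     lib)$gram_condition))
for (p in c("chl_a", "pheophytin_a", "beta_carotene", "diadinoxanthin")) {
  sp_t <- spearman_dose(pig[[p]], pig$dose_ug_per_l)
  message(sprintf("%-15s signed rho^2 = %+.2f (p = %.3f)",
                  p, sp_t$signed_rho_sq, sp_t$p_value))
}
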