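#!/usr/bin/env Rscript
# CAP classification of exposure groups from the bio-optical (raw Kautsky
# curve) and fatty-acid feature sets.
source("analysis/00_settings.R")

tr <- read_table(file.path(DATA_DIR, "ojip_transients.csv"),
                 c(time_s = "numeric", fluorescence = "numeric",
                   dose_ug_per_l = "numeric", replicate = "numeric"))
profiles <- read_table(file.path(OUT_DIR, "fatty_acid_profiles.csv"),
                       c(fa_id = "character", relative_pct = "numeric",
                         dose_ug_per_l = "numeric", replicate = "numeric"))

optical <- transient_feature_matrix(tr)
cap_opt <- cap(optical$features, optical$groups, n_perm = 9999, seed = SEED)
message("bio-optical CAP:")
print(cap_opt)

fa_wide <- fa_feature_matrix(profiles)
cap_fa <- cap(fa_wide$features, fa_wide$groups, n_perm = 9999, seed = SEED)
message("fatty-acid CAP:")
print(cap_fa)

write_table(as.data.frame(cap_opt$confusion),
            file.path(OUT_DIR, "cap_optical_confusion.csv"), SEED)
write_table(as.data.frame(cap_fa$confusion),
            file.path(OUT_DIR, "cap_fa_confusion.csv"), SEED)
write_table(data.frame(feature_set = c("optical", "fatty_acids"),
                       m = c(cap_opt$m, cap_fa$m),
                       accuracy_pct = c(cap_opt$accuracy_pct,
                                        cap_fa$accuracy_pct),
                       p_permutation = c(cap_opt$p_permutation,
                                         cap_fa$p_permutation)),
            file.path(OUT_DIR, "cap_summary.csv"), SEED)
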