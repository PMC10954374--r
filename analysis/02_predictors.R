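#!/usr/bin/env Rscript
# Stage 2 — build the derived predictors on the simulated tables:
# number of limiting resources (NLR) from Ca/TP/SiO2/EC terciles, the
# glaciation-exposure index Glac = 1 - t_last/35 and the LGM indicator
# Fglac from the ice-history table, and the latitudinal bands.

suppressPackageStartupMessages(library(diatomLDG))

sites <- load_sites("results/data/sites.csv")
ice <- load_ice("results/data/ice.csv")
ice <- ice[match(sites$site_id, ice$site_id), ]

sites$Glac <- compute_glac(ice)
sites$Fglac <- compute_fglac(ice)           # 20 ka layer
nlr <- compute_nlr(sites)
sites$NLR <- nlr

message(sprintf("Glac range %.3f-%.3f; %d sites ever glaciated; %d with Fglac = 1",
                min(sites$Glac), max(sites$Glac), sum(sites$Glac > 0),
                sum(sites$Fglac)))
message(sprintf("NLR scored for %d sites (chemistry subset); range %d-%d",
                sum(!is.na(sites$NLR)), min(sites$NLR, na.rm = TRUE),
                max(sites$NLR, na.rm = TRUE)))

bands <- build_latitudinal_bands(sites, target_size = 12, isolation_gap = 1)
print(bands)

# band membership is deterministic from the sites table, so later stages
# recompute it rather than serializing it
write.csv(sites, "results/sites_predictors.csv", row.names = FALSE)
write.csv(bands$bands, "results/bands_raw.csv", row.names = FALSE)
message("written: results/sites_predictors.csv, results/bands_raw.csv")
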