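#!/usr/bin/env Rscript
# Stage 3 — latitudinal richness patterns: observed and effort-standardized
# band richness (incidence rarefaction/extrapolation to the largest band
# size, percentile bootstrap CI), and latitude additive models at site,
# band and estimated-band level.

suppressPackageStartupMessages(library(diatomLDG))

sites <- load_sites("results/sites_predictors.csv")
community <- load_community("results/data/community.csv", sites)

bands <- build_latitudinal_bands(sites, target_size = 12, isolation_gap = 1)
band_est <- estimate_band_richness(bands, community, n_boot = 200, seed = 2024)
message(sprintf("bands: %d | common sample size: %d sites",
                nrow(band_est), attr(band_est, "common_size")))

for (level in c("site", "band", "band_estimated")) {
  fit <- latitude_richness_gam(if (level == "site") sites else band_est,
                               level, k = if (level == "site") 10 else
                                 min(10, nrow(band_est) - 1))
  message(sprintf("latitude GAM [%s]: edf = %.2f, F = %.2f, p = %.3g%s",
                  level, fit$edf, fit$F, fit$p,
                  if (fit$p < 0.05) " (significant)" else ""))
}

write.csv(band_est, "results/bands_richness.csv", row.names = FALSE)
curve <- rarefaction_curve(community, bands$membership[[which.max(
  bands$bands$n_sites)]])
write.csv(curve, "results/rarefaction_largest_band.csv", row.names = FALSE)
message("written: results/bands_richness.csv, results/rarefaction_largest_band.csv")
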