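#!/usr/bin/env Rscript
# Stage 4 — the additive-model comparison suite (both dataset variants) and
# the pairwise predictor correlation matrix.

suppressPackageStartupMessages(library(diatomLDG))

sites <- load_sites("results/sites_predictors.csv")
sites$chem_subset <- sites$chem_subset %in% c(TRUE, "TRUE")

cor_vars <- c("richness", "Lat", "Lon", "Elev", "T_mean", "T_max", "T_min",
              "T_sd", "T_insitu", "pH", "EC", "Osat", "Ca", "TP", "SiO2",
              "Vel", "NLR", "Glac")
cors <- correlation_matrix(sites, cor_vars)
if (nrow(cors$high_collinearity)) {
  message("collinear pairs (r^2 > .90): ",
          paste(cors$high_collinearity$var1, cors$high_collinearity$var2,
                sep = "~", collapse = ", "))
} else message("no predictor pair exceeds r^2 = .90")
write.csv(as.data.frame(cors$r), "results/correlation_r.csv")
write.csv(as.data.frame(cors$p), "results/correlation_p.csv")

all_rows <- NULL
for (variant in c("complete", "chemical")) {
  suite <- run_model_suite(sites, variant)
  n_used <- suite$n[!is.na(suite$n)][1]
  message(sprintf("\n%s dataset (n = %d):", variant, n_used))
  for (i in seq_len(nrow(suite))) {
    message(sprintf("  %-40s %-28s dev %5.2f%%  AIC %8.2f%s%s",
                    suite$model[i], suite$significant[i],
                    suite$dev_expl[i], suite$aic[i],
                    if (isTRUE(suite$best[i])) "  <- best set" else "",
                    if (isFALSE(suite$aic_comparable[i]))
                      " (AIC non-comparable)" else ""))
  }
  all_rows <- rbind(all_rows,
                    cbind(dataset = if (variant == "complete") "All" else
                      "Chem", as.data.frame(suite)))
}
write.csv(all_rows, "results/model_suite.csv", row.names = FALSE)
message("\nwritten: results/model_suite.csv, results/correlation_{r,p}.csv")
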