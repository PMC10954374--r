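test_that("the metabolic-theory energy predictor follows Boltzmann arithmetic", {
  expect_equal(round(mte_predictor(10), 2), 40.99)
  expect_equal(mte_predictor(10), 1 / (8.617e-5 * 283.15))
  temps <- seq(-5, 30, by = 5)
  expect_true(all(diff(mte_predictor(temps)) < 0))
  expect_error(mte_predictor(-273.15), "absolute zero")
  expect_error(mte_predictor(NA_real_))
})

test_that("a constant response yields zero deviance explained and no significant terms", {
  d <- data.frame(richness = rep(7, 60), x = rnorm(60))
  fit <- fit_richness_gam(d, "x")
  expect_equal(fit$dev_expl, 0)
  expect_length(fit$significant, 0)
})

test_that("a smoothed term on linear data recovers the slope with edf near 1", {
  set.seed(2)
  d <- data.frame(x = runif(200, 0, 10))
  d$richness <- 3 * d$x + rnorm(200, 0, 0.15)
  fit <- fit_richness_gam(d, "x")
  expect_lt(fit$terms$edf[1], 1.8)
  grid <- data.frame(x = seq(1, 9, length.out = 50))
  slope <- coef(lm(predict(fit$model, grid) ~ grid$x))[2]
  expect_lt(abs(slope - 3) / 3, 0.05)
})

test_that("the null-space penalty shrinks pure-noise terms toward zero edf", {
  edf_pair <- vapply(1:20, function(seed) {
    set.seed(seed)
    d <- data.frame(x1 = runif(300), x2 = runif(300))
    d$richness <- sin(2 * pi * d$x1) * 3 + rnorm(300, 0, 0.5)
    with_pen <- fit_richness_gam(d, c("x1", "x2"))
    no_pen <- fit_richness_gam(d, c("x1", "x2"), select = FALSE)
    c(pen = with_pen$terms$edf[with_pen$terms$term == "x2"],
      free = no_pen$terms$edf[no_pen$terms$term == "x2"])
  }, numeric(2))
  # penalized noise terms collapse toward zero edf; unpenalized smooths
  # cannot drop below one degree of freedom
  expect_lt(median(edf_pair["pen", ]), 0.5)
  expect_lt(mean(edf_pair["pen", ]), mean(edf_pair["free", ]))
  expect_gte(mean(edf_pair["pen", ] < 1), 0.7)
})

test_that("deviance explained is monotone for nested unpenalized term sets", {
  set.seed(6)
  d <- data.frame(x1 = runif(150), x2 = runif(150), x3 = runif(150))
  d$richness <- 2 * d$x1 + sin(4 * d$x2) + rnorm(150, 0, 0.4)
  small <- fit_richness_gam(d, c("x1", "x2"), fx = TRUE)
  big <- fit_richness_gam(d, c("x1", "x2", "x3"), fx = TRUE)
  expect_gte(big$dev_expl, small$dev_expl - 1e-8)
})

test_that("the suite fits the variant-appropriate equations and applies the AIC rule", {
  d <- simulate_dataset(sim_config(n_sites = 200, n_species = 60,
                                   structure = "gleasonian", seed = 14))
  suite <- run_model_suite(d$sites |> transform(
    Glac = compute_glac(generate_ice_history(d$sites)),
    Fglac = compute_fglac(generate_ice_history(d$sites)),
    NLR = compute_nlr(d$sites)), "complete")
  expect_false(any(suite$model %in% c("Chemical effect",
                                      "Niche dimensionality")))
  expect_equal(nrow(suite), 10)
  ok <- !is.na(suite$aic) & suite$aic_comparable
  expect_true(any(suite$best))
  best_aic <- min(suite$aic[ok])
  expect_true(all(suite$aic[suite$best] < best_aic + 2))
  # MTE never enters the comparable set
  expect_false(suite$best[suite$model == "Metabolic theory"])
  expect_false(suite$aic_comparable[suite$model == "Metabolic theory"])
  # two fits 1.5 AIC apart are both flagged best (the <2 rule)
  expect_true(all(suite$best[ok & suite$aic < best_aic + 1.5 &
                               suite$aic >= best_aic]))
  # deviance explained within range
  expect_true(all(suite$dev_expl >= 0 & suite$dev_expl <= 100, na.rm = TRUE))
})

test_that("the chemical variant adds the chemistry equations and responds to chemical drivers", {
  cfg <- sim_config(n_sites = 250, n_species = 60, structure = "random",
                    seed = 19, chem_subset_fraction = 1,
                    richness_effects = c(SiO2 = 1.2, Vel = -12),
                    richness_noise_sd = 4, richness_intercept = 15)
  s <- generate_richness_response(generate_sites(cfg), cfg)
  s$richness <- pmax(round(s$richness), 0)
  ice <- generate_ice_history(s)
  s$Glac <- compute_glac(ice); s$Fglac <- compute_fglac(ice)
  s$NLR <- compute_nlr(s)
  s$Cel_den <- round(exp(8 + 0.05 * s$richness))
  suite <- run_model_suite(s, "chemical")
  expect_true(all(c("Chemical effect", "Niche dimensionality") %in%
                    suite$model))
  expect_equal(nrow(suite), 12)
  chem_dev <- suite$dev_expl[suite$model == "Chemical effect"]
  clim_dev <- suite$dev_expl[suite$model == "Climatical effect"]
  expect_gt(chem_dev, clim_dev)
  sig <- suite$significant[suite$model == "Chemical effect"]
  expect_match(sig, "SiO2")
  expect_match(sig, "Vel")
})

test_that("per-model failures are reported without stopping the suite", {
  d <- simulate_dataset(sim_config(n_sites = 120, n_species = 40,
                                   structure = "random", seed = 3))
  s <- d$sites
  s$Glac <- 0; s$Fglac <- 0L   # constant historical predictors
  s$NLR <- compute_nlr(s)
  suite <- run_model_suite(s, "complete")
  hist_row <- suite[suite$model == "Historical effect", ]
  expect_true(!is.na(hist_row$error) || hist_row$dev_expl >= 0)
  expect_gt(sum(is.na(suite$error)), 5)  # the rest of the suite still ran
})

test_that("correlation matrices reproduce closed-form Pearson tests and stars", {
  set.seed(10)
  d <- data.frame(a = rnorm(10))
  d$b <- d$a * 2                      # r = 1
  d$c <- rnorm(10)
  cm <- correlation_matrix(d, c("a", "b", "c"))
  expect_equal(cm$r["a", "b"], 1)
  expect_equal(cm$r["a", "a"], 1)
  ct <- cor.test(d$a, d$c)
  expect_equal(cm$r["a", "c"], unname(ct$estimate))
  expect_equal(cm$p["a", "c"], ct$p.value)
  expect_equal(cm$stars["a", "b"], "***")
  expect_equal(nrow(cm$high_collinearity), 1)   # only the a~b pair
  # orthogonal contrasts -> r = 0
  d2 <- data.frame(x = c(-1, -1, 1, 1), y = c(-1, 1, -1, 1))
  cm2 <- correlation_matrix(d2, c("x", "y"))
  expect_equal(cm2$r["x", "y"], 0)
  expect_error(correlation_matrix(data.frame(x = rep(1, 5), y = rnorm(5)),
                                  c("x", "y")), "zero-variance")
})

test_that("latitude GAMs detect strong gradients and stay quiet on flat ones", {
  set.seed(8)
  d <- data.frame(Lat = runif(373, -52, -35))
  d$richness <- round(20 + 0.8 * (d$Lat + 52) + rnorm(373, 0, 4))
  fit <- latitude_richness_gam(d, "site")
  expect_lt(fit$p, 0.001)
  flat <- data.frame(Lat = runif(100, -52, -35),
                     richness = round(rnorm(100, 20, 4)))
  fit_flat <- latitude_richness_gam(flat, "site")
  expect_gt(fit_flat$p, 0.01)
  expect_error(latitude_richness_gam(head(flat, 3), "site"), ">= 5")
})
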