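test_that("observed richness is the union of the subset's species sets", {
  m <- fixture_community_5x7()
  expect_equal(observed_richness(m, "s1"), 3L)
  # two disjoint 3-species sites
  d <- rbind(c(1, 1, 1, 0, 0, 0), c(0, 0, 0, 1, 1, 1))
  rownames(d) <- c("a", "b")
  expect_equal(observed_richness(d), 6L)
  # exhaustive set-union oracle on the fixture
  for (sub in list("s1", c("s1", "s3"), c("s2", "s4", "s5"))) {
    union_count <- length(Reduce(union, lapply(sub, function(s)
      which(m[s, ] > 0))))
    expect_equal(observed_richness(m, sub), union_count)
  }
  expect_error(observed_richness(m, "nope"), "unknown site")
})

test_that("incidence summaries count uniques and duplicates on incidence, not counts", {
  m <- fixture_community_5x7() * 3   # counts, not 0/1
  s <- incidence_summary(m)
  expect_equal(s$T, 5L)
  expect_equal(s$S_obs, 7L)
  expect_equal(unname(s$Y), c(3, 3, 3, 2, 2, 2, 2))
  expect_equal(s$Q1, 0L)
  expect_equal(s$Q2, 4L)
  # all-singleton matrix
  ident <- diag(4); rownames(ident) <- paste0("s", 1:4)
  s2 <- incidence_summary(ident)
  expect_equal(s2$Q1, s2$S_obs)
  expect_equal(s2$Q2, 0L)
  # ubiquitous species contributes to neither Q1 nor Q2
  ubiq <- cbind(rep(1, 5), c(1, 0, 0, 0, 1))
  s3 <- incidence_summary(ubiq)
  expect_equal(s3$Q1, 0L)
  expect_equal(s3$Q2, 1L)
})

test_that("analytic rarefaction equals exhaustive subset enumeration", {
  m <- fixture_community_5x7()
  s <- incidence_summary(m)
  expect_equal(rarefy_richness(s, s$T), s$S_obs)        # m = T
  expect_equal(rarefy_richness(s, 1), mean(rowSums(m > 0)))  # m = 1
  for (k in 2:4)
    expect_equal(rarefy_richness(s, k), brute_rarefaction(m > 0, k),
                 tolerance = 1e-9)
  # larger random fixtures, exhaustive for T <= 12
  set.seed(8)
  for (rep in 1:3) {
    T <- sample(8:12, 1)
    inc <- matrix(rbinom(T * 15, 1, 0.35), T, 15)
    inc <- inc[, colSums(inc) > 0, drop = FALSE]
    rownames(inc) <- paste0("s", seq_len(T))
    s2 <- incidence_summary(inc)
    for (k in c(2, T %/% 2, T - 1))
      expect_equal(rarefy_richness(s2, k), brute_rarefaction(inc, k),
                   tolerance = 1e-9)
  }
  expect_error(rarefy_richness(s, 0), "m must be")
})

test_that("rarefaction curves are non-decreasing and concave", {
  set.seed(4)
  inc <- matrix(rbinom(10 * 20, 1, 0.3), 10, 20)
  inc <- inc[, colSums(inc) > 0, drop = FALSE]
  rownames(inc) <- paste0("s", 1:10)
  curve <- rarefaction_curve(inc)$S
  expect_true(all(diff(curve) >= -1e-12))
  expect_true(all(diff(diff(curve)) <= 1e-12))
  expect_equal(curve[10], observed_richness(inc))
})

test_that("extrapolation follows the uniques/duplicates arithmetic and its asymptote", {
  s <- structure(list(T = 10L, S_obs = 20L, Y = NULL, Q1 = 6L, Q2 = 3L),
                 class = "incidence_summary")
  q0 <- (9 / 10) * 36 / 6
  expect_equal(q0, 5.4)
  expect_equal(extrapolate_richness(s, 0), 20)
  big <- extrapolate_richness(s, 10000)
  expect_equal(big, 20 + q0, tolerance = 1e-6)
  ms <- c(0, 1, 2, 5, 10, 50)
  vals <- vapply(ms, function(m) extrapolate_richness(s, m), numeric(1))
  expect_true(all(diff(vals) >= 0))
  expect_true(all(vals <= 20 + q0 + 1e-12))
  # Q1 = 0 -> no undetected species signal
  s0 <- structure(list(T = 10L, S_obs = 20L, Y = NULL, Q1 = 0L, Q2 = 3L),
                  class = "incidence_summary")
  expect_equal(extrapolate_richness(s0, 50), 20)
  # Q2 = 0 fallback
  s1 <- structure(list(T = 10L, S_obs = 20L, Y = NULL, Q1 = 3L, Q2 = 0L),
                  class = "incidence_summary")
  expect_equal(extrapolate_richness(s1, 1e6), 20 + 0.9 * 3 * 2 / 2,
               tolerance = 1e-6)
  expect_error(extrapolate_richness(s, -1), "m_star")
})

test_that("extrapolation is continuous with rarefaction at the observed effort", {
  set.seed(12)
  inc <- matrix(rbinom(8 * 25, 1, 0.3), 8, 25)
  inc <- inc[, colSums(inc) > 0, drop = FALSE]
  rownames(inc) <- paste0("s", 1:8)
  s <- incidence_summary(inc)
  expect_equal(standardize_richness(s, s$T), as.numeric(s$S_obs))
  expect_equal(extrapolate_richness(s, 0), as.numeric(s$S_obs))
})

test_that("band richness estimation is seeded-deterministic and standardizes effort", {
  d <- simulate_dataset(sim_config(n_sites = 80, n_species = 50,
                                   structure = "gleasonian", seed = 21))
  bands <- build_latitudinal_bands(d$sites)
  est1 <- estimate_band_richness(bands, d$community, n_boot = 50, seed = 7)
  est2 <- estimate_band_richness(bands, d$community, n_boot = 50, seed = 7)
  expect_identical(est1, est2)
  expect_true(all(est1$S_est_lo <= est1$S_est_hi))
  # extrapolation beyond observed effort never shrinks below S_obs
  small <- est1[est1$n_sites < attr(est1, "common_size"), ]
  expect_true(all(small$S_est >= small$S_obs - 1e-9))
  # a band already at the common size keeps its observed richness
  common <- attr(est1, "common_size")
  at_common <- est1[est1$n_sites == common, ]
  if (nrow(at_common))
    expect_equal(at_common$S_est, as.numeric(at_common$S_obs))
})

test_that("standardized richness varies less across bands than observed richness", {
  # unequal band sizes sampled from one homogeneous community process
  disp_ratio <- vapply(1:20, function(seed) {
    set.seed(seed)
    n <- 60
    inc <- matrix(rbinom(n * 80, 1, 0.15), n, 80)
    rownames(inc) <- sprintf("s%03d", 1:n)
    sizes <- c(6, 10, 14, 30)
    idx <- split(seq_len(n), rep(seq_along(sizes), sizes))
    sobs <- vapply(idx, function(i)
      observed_richness(inc, rownames(inc)[i]), numeric(1))
    sest <- vapply(idx, function(i)
      standardize_richness(incidence_summary(inc, rownames(inc)[i]), 30),
      numeric(1))
    sd(sest) / sd(sobs)
  }, numeric(1))
  expect_lt(mean(disp_ratio), 1)
})
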