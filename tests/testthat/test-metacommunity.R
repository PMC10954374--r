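test_that("matrix preparation removes singletons then empty sites", {
  m <- rbind(c(2, 0, 1, 0, 0, 1, 0, 3),
             c(1, 0, 1, 0, 0, 2, 0, 0),
             c(0, 1, 0, 0, 0, 1, 0, 0),
             c(0, 0, 1, 1, 0, 1, 0, 2),
             c(3, 0, 0, 0, 0, 1, 0, 1),
             c(0, 0, 1, 0, 1, 1, 0, 0))
  dimnames(m) <- list(paste0("s", 1:6), paste0("sp", 1:8))
  # sp2, sp4, sp5 are singletons; sp7 never occurs
  prep <- prepare_matrix(m)
  expect_equal(colnames(prep), c("sp1", "sp3", "sp6", "sp8"))
  expect_true(all(prep %in% c(0, 1)))
  expect_setequal(attr(prep, "dropped_species"), c("sp2", "sp4", "sp5", "sp7"))
  expect_equal(nrow(prep), 6)
  # all entries >= 1 -> all-ones, nothing dropped
  ones <- matrix(1 + rpois(12, 2), 3, 4,
                 dimnames = list(letters[1:3], LETTERS[1:4]))
  expect_true(all(prepare_matrix(ones) == 1))
  expect_error(prepare_matrix(diag(3)), "singleton")
})

test_that("reciprocal averaging matches the eigen-decomposition oracle", {
  set.seed(31)
  for (rep in 1:5) {
    m <- matrix(rbinom(8 * 10, 1, 0.45), 8, 10)
    m <- m[rowSums(m) > 0, colSums(m) > 0, drop = FALSE]
    if (nrow(m) < 3 || ncol(m) < 3) next
    rownames(m) <- sprintf("r%02d", seq_len(nrow(m)))
    colnames(m) <- sprintf("c%02d", seq_len(ncol(m)))
    om <- reciprocal_averaging(m)
    oracle <- eigen_ca_row_scores(m)
    err_same <- max(abs(om$row_scores - oracle))
    err_flip <- max(abs(om$row_scores + oracle))
    expect_lt(min(err_same, err_flip), 1e-8)
  }
})

test_that("ordination recovers banded structure and is permutation invariant", {
  banded <- matrix(0, 8, 10, dimnames = list(paste0("s", 1:8),
                                             paste0("p", 1:10)))
  for (i in 1:8) banded[i, i:min(i + 2, 10)] <- 1
  om <- reciprocal_averaging(banded)
  expect_equal(count_embedded_absences(om, "columns"), 0)
  expect_equal(count_embedded_absences(om, "both"), 0)
  # shuffle rows and columns: same ordering up to global reversal
  set.seed(5)
  perm <- banded[sample(8), sample(10)]
  om2 <- reciprocal_averaging(perm)
  ids1 <- rownames(om$matrix)
  ids2 <- rownames(om2$matrix)
  expect_true(identical(ids1, ids2) || identical(ids1, rev(ids2)))
})

test_that("embedded absences match brute force in both modes and under reversal", {
  col <- matrix(c(1, 0, 1), 3, 1, dimnames = list(1:3, "a"))
  expect_equal(count_embedded_absences(col, "columns"), 1)
  set.seed(17)
  for (rep in 1:8) {
    m <- matrix(rbinom(25, 1, 0.5), 5, 5)
    for (mode in c("columns", "rows", "both")) {
      expect_equal(count_embedded_absences(m, mode),
                   brute_embedded_absences(m, mode))
    }
    rev_m <- m[5:1, 5:1]
    expect_equal(count_embedded_absences(m, "both"),
                 count_embedded_absences(rev_m, "both"))
  }
  # larger random fixtures
  set.seed(18)
  m8 <- matrix(rbinom(64, 1, 0.4), 8, 8)
  for (mode in c("columns", "rows", "both"))
    expect_equal(count_embedded_absences(m8, mode),
                 brute_embedded_absences(m8, mode))
})

test_that("the swap null preserves margins exactly and mixes uniformly", {
  # 2x2 identity: the only reachable other state is its swap
  id2 <- diag(2L)
  dimnames(id2) <- list(c("a", "b"), c("x", "y"))
  nulls <- swap_null(id2, n_sim = 20, seed = 1, burn_in = 10, thin = 3)
  for (nm in nulls) {
    expect_equal(unname(rowSums(nm)), c(1, 1))
    expect_equal(unname(colSums(nm)), c(1, 1))
  }
  states <- unique(lapply(nulls, function(x) paste(x, collapse = "")))
  expect_lte(length(states), 2)

  m <- fixture_4x4_five_configs()
  nulls <- swap_null(m, n_sim = 400, seed = 3, burn_in = 500, thin = 20)
  for (nm in nulls) {
    expect_equal(unname(rowSums(nm)), unname(rowSums(m)))
    expect_equal(unname(colSums(nm)), unname(colSums(m)))
  }
  # degenerate (perfectly nested) matrix has no swappable submatrix
  nested <- rbind(c(1, 0, 0), c(1, 1, 0), c(1, 1, 1))
  expect_error(swap_null(nested, 5), "degenerate")
})

test_that("turnover contributions match the pairwise replacement definition", {
  # identical filled ranges -> zero contribution
  same <- cbind(c(0, 1, 1, 0), c(0, 1, 1, 0))
  expect_equal(turnover_stat(same), 0)
  # disjoint ranges of sizes a and b contribute a * b
  disj <- cbind(c(1, 1, 0, 0, 0), c(0, 0, 0, 1, 1))
  expect_equal(turnover_stat(disj), 2 * 2)
  set.seed(23)
  for (rep in 1:6) {
    m <- matrix(rbinom(36, 1, 0.5), 6, 6)
    expect_equal(turnover_stat(m), brute_turnover(m))
  }
})

test_that("Morisita boundary clumping follows its closed form", {
  # fixture: boundary counts (3,3,0,0,2) over T=5 sites, N=8 -> I = 1.25
  m <- cbind(c(1, 1, 0, 0, 0),   # boundaries at sites 1, 2
             c(1, 1, 0, 0, 0),
             c(1, 1, 0, 0, 0),
             c(1, 1, 1, 1, 1))   # boundaries at sites 1, 5
  b <- boundary_clumping(list(matrix = m) |> structure(class = "ems_ordination"))
  expect_equal(b$boundaries, c(4, 3, 0, 0, 1))
  # construct the spec-style count vector directly instead
  m2 <- cbind(c(1, 1, 0, 0, 0), c(1, 1, 0, 0, 0), c(0, 1, 0, 0, 1),
              c(0, 1, 0, 0, 1))
  b2 <- boundary_clumping(structure(list(matrix = m2),
                                    class = "ems_ordination"))
  expect_equal(b2$boundaries, c(2, 4, 0, 0, 2))
  expect_equal(b2$morisita, 5 * (2 + 12 + 0 + 0 + 2) / (8 * 7))
  # all boundaries at one site -> I = T
  one_site <- cbind(c(0, 0, 1, 0), c(0, 0, 1, 0), c(0, 0, 1, 0))
  b3 <- boundary_clumping(structure(list(matrix = one_site),
                                    class = "ems_ordination"))
  expect_equal(b3$morisita, 4)
  # one boundary per site -> minimal clumping (I = 0)
  spread <- cbind(c(1, 1, 0, 0), c(0, 0, 1, 1))
  b4 <- boundary_clumping(structure(list(matrix = spread),
                                    class = "ems_ordination"))
  expect_equal(b4$morisita, 0)
})

test_that("the classification tree routes the three test outcomes correctly", {
  coh <- function(z, p) list(z = z, p = p)
  clump <- function(I, p) list(morisita = I, p = p)
  turn <- function(z, p) list(z = z, p = p)
  expect_equal(classify_structure(coh(-3, 0.003), turn(7.3, 1e-5),
                                  clump(2.54, 1e-5)), "Clementsian")
  expect_equal(classify_structure(coh(-1, 0.4), turn(7, 1e-5),
                                  clump(2.5, 1e-4)), "Random")
  expect_equal(classify_structure(coh(3, 0.001), turn(7, 1e-5),
                                  clump(2.5, 1e-4)), "Checkerboard")
  expect_equal(classify_structure(coh(-3, 0.001), turn(-4, 1e-4),
                                  clump(2.5, 1e-4)),
               "Nested (clumped species loss)")
  expect_equal(classify_structure(coh(-3, 0.001), turn(4, 1e-4),
                                  clump(1.1, 0.4)), "Gleasonian")
  expect_equal(classify_structure(coh(-3, 0.001), turn(4, 1e-4),
                                  clump(0.4, 0.01)), "EvenlySpaced")
  expect_equal(classify_structure(coh(-3, 0.001), turn(1, 0.3),
                                  clump(2.5, 1e-4)), "Quasi-Clementsian")
  expect_equal(classify_structure(coh(-3, 0.001), turn(-1, 0.3),
                                  clump(1.0, 0.7)),
               "Quasi-Nested (stochastic species loss)")
})

test_that("site-order correlations follow the closed-form t statistic", {
  set.seed(41)
  m <- matrix(rbinom(80, 1, 0.5), 10, 8,
              dimnames = list(sprintf("s%02d", 1:10), sprintf("p%d", 1:8)))
  m <- m[rowSums(m) > 0, colSums(m) > 1, drop = FALSE]
  om <- reciprocal_averaging(m)
  n <- nrow(m)
  cov <- rnorm(n)
  res <- site_order_correlation(om, cov)
  rank_pos <- integer(n); rank_pos[om$row_order] <- seq_len(n)
  ct <- cor.test(rank_pos, cov)
  expect_equal(res$r, unname(ct$estimate))
  expect_equal(res$t, unname(ct$statistic))
  expect_equal(res$df, n - 2)
  expect_equal(res$p, ct$p.value)
  # covariate equal to the rank itself
  res2 <- site_order_correlation(om, rank_pos + 0.0)
  expect_equal(res2$r, 1)
  # named covariate is aligned by site id
  named <- setNames(cov, rownames(m))
  res3 <- site_order_correlation(om, named)
  expect_equal(res3$r, res$r)
})

test_that("a coherent banded metacommunity tests as coherent against the swap null", {
  banded <- matrix(0, 10, 12)
  for (i in 1:10) banded[i, (i):(min(i + 3, 12))] <- 1
  rownames(banded) <- sprintf("s%02d", 1:10)
  colnames(banded) <- sprintf("p%02d", 1:12)
  om <- reciprocal_averaging(banded)
  nulls <- swap_null(banded, n_sim = 200, seed = 3, burn_in = 5000,
                     thin = 200)
  coh <- coherence_test(om, nulls)
  expect_lt(coh$z, -1.96)
  # z/p arithmetic sanity on synthetic null values
  fake_om <- om
  nv <- c(10, 12, 14, 16, 18)
  zt <- diatomLDG:::.z_test(14, nv)
  expect_equal(zt$z, 0)
  expect_equal(zt$p, 1)
  zt2 <- diatomLDG:::.z_test(mean(nv) - 2 * sd(nv), nv)
  expect_equal(zt2$z, -2)
  expect_equal(zt2$p, 2 * pnorm(-2), tolerance = 1e-12)
})
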