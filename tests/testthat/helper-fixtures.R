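# Small fixtures and independent brute-force oracles used across the suite.

# 4x4 matrix whose fixed-margin set has exactly 5 members (verified by the
# exhaustive enumeration below); used for swap-null uniformity checks.
fixture_4x4_five_configs <- function() {
  rbind(c(1L, 0L, 0L, 1L),
        c(0L, 1L, 0L, 0L),
        c(0L, 0L, 0L, 1L),
        c(1L, 1L, 1L, 1L))
}

# exhaustively enumerate all 4x4 binary matrices with the given margins
enumerate_fixed_margin_4x4 <- function(rs, cs) {
  res <- list()
  for (i in 0:(2^16 - 1)) {
    m <- matrix(as.integer(intToBits(i)[1:16]), 4, 4)
    if (all(rowSums(m) == rs) && all(colSums(m) == cs))
      res[[length(res) + 1]] <- m
  }
  res
}

# brute-force embedded-absence count (gap scan), independent of the package
brute_embedded_absences <- function(m, mode = "both") {
  gaps <- function(mm) {
    total <- 0L
    for (j in seq_len(ncol(mm))) {
      p <- which(mm[, j] == 1)
      if (length(p) >= 2)
        total <- total + sum(mm[min(p):max(p), j] == 0)
    }
    total
  }
  switch(mode, columns = gaps(m), rows = gaps(t(m)),
         both = gaps(m) + gaps(t(m)))
}

# brute-force turnover: fill ranges, then count replacements pair by pair
brute_turnover <- function(m_ordered) {
  f <- m_ordered
  for (j in seq_len(ncol(f))) {
    p <- which(f[, j] == 1)
    if (length(p)) f[min(p):max(p), j] <- 1
  }
  total <- 0
  for (i in seq_len(ncol(f) - 1)) {
    for (j in seq(i + 1, ncol(f))) {
      di <- sum(f[, i] == 1 & f[, j] == 0)
      dj <- sum(f[, j] == 1 & f[, i] == 0)
      total <- total + di * dj
    }
  }
  total
}

# mean richness over all C(T, m) site subsets — enumeration rarefaction oracle
brute_rarefaction <- function(inc, m) {
  subsets <- utils::combn(nrow(inc), m)
  mean(apply(subsets, 2, function(idx)
    sum(colSums(inc[idx, , drop = FALSE]) > 0)))
}

# direct eigen-decomposition oracle for the first CA axis (row scores,
# weighted mean 0 / weighted variance 1)
eigen_ca_row_scores <- function(m) {
  r <- rowSums(m); cs <- colSums(m); tot <- sum(m)
  S <- diag(1 / sqrt(r)) %*% m %*% diag(1 / cs) %*% t(m) %*% diag(1 / sqrt(r))
  e <- eigen(S, symmetric = TRUE)
  v <- e$vectors[, 2]            # first axis after the trivial one
  x <- v / sqrt(r)
  x <- x - sum(r * x) / tot
  x / sqrt(sum(r * x^2) / tot)
}

# deterministic small incidence fixture with overlapping occupancy
fixture_community_5x7 <- function() {
  m <- rbind(
    c(1, 1, 0, 0, 1, 0, 0),
    c(0, 1, 1, 0, 0, 1, 0),
    c(1, 0, 1, 1, 0, 0, 0),
    c(0, 0, 1, 1, 1, 0, 1),
    c(1, 1, 0, 0, 0, 1, 1))
  dimnames(m) <- list(paste0("s", 1:5), paste0("sp", 1:7))
  m
}
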