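# Observed and sample-size-corrected species richness per site subset and per
# latitudinal band: incidence-based analytic rarefaction and Chao-type
# extrapolation from incidence frequencies (uniques Q1, duplicates Q2).

.subset_matrix <- function(matrix, site_subset = NULL) {
  if (is.null(site_subset)) return(matrix)
  if (is.character(site_subset)) {
    unknown <- setdiff(site_subset, rownames(matrix))
    if (length(unknown))
      stop("unknown site id(s): ", paste(head(unknown, 5), collapse = ", "))
  }
  m <- matrix[site_subset, , drop = FALSE]
  if (nrow(m) == 0) stop("empty site subset")
  m
}

#' Observed species richness of a site subset
#'
#' Number of species with at least one occurrence across the subset (the
#' band-level richness is the total of taxa recorded in all member sites).
#'
#' @param matrix sites x species count (or incidence) matrix with site ids as
#'   rownames.
#' @param site_subset site ids or indices; `NULL` for all sites.
#' @return integer.
#' @export
observed_richness <- function(matrix, site_subset = NULL) {
  m <- .subset_matrix(matrix, site_subset)
  sum(colSums(m > 0) > 0)
}

#' Incidence frequency summary
#'
#' Per-species incidence frequencies over `T` sampling units (sites), and the
#' derived quantities feeding the rarefaction/extrapolation estimator:
#' observed richness `S_obs`, uniques `Q1` (species in exactly one unit) and
#' duplicates `Q2` (exactly two units).
#'
#' @inheritParams observed_richness
#' @return list of class `incidence_summary`: `T`, `S_obs`, `Y`, `Q1`, `Q2`.
#' @export
incidence_summary <- function(matrix, site_subset = NULL) {
  m <- .subset_matrix(matrix, site_subset)
  Y <- colSums(m > 0)
  structure(list(T = nrow(m), S_obs = sum(Y >= 1), Y = Y,
                 Q1 = sum(Y == 1), Q2 = sum(Y == 2)),
            class = "incidence_summary")
}

#' Analytic incidence-based rarefaction
#'
#' Expected species richness in a random subsample of `m` of the `T`
#' sampling units:
#' `E[S(m)] = sum_i (1 - choose(T - Y_i, m) / choose(T, m))`,
#' the exact mean over all `choose(T, m)` site subsets (species whose
#' `T - Y_i < m` contribute 1).
#'
#' @param summary an [incidence_summary()].
#' @param m number of sampling units, `1 <= m <= T`.
#' @return expected richness (numeric). Non-decreasing and concave in `m`;
#'   equals `S_obs` at `m = T`.
#' @export
rarefy_richness <- function(summary, m) {
  stopifnot(inherits(summary, "incidence_summary"))
  if (m < 1 || m > summary$T) stop("m must be in [1, T]")
  Y <- summary$Y[summary$Y >= 1]
  sum(1 - exp(lchoose(summary$T - Y, m) - lchoose(summary$T, m)))
}

#' Chao-type incidence extrapolation
#'
#' Estimated species richness when the number of sampling units is extended
#' from `T` to `T + m_star`:
#' `S(T + m*) = S_obs + Q0 * (1 - (1 - Q1 / (Q1 + T * Q0))^m*)`,
#' with the undetected-species estimate
#' `Q0 = ((T-1)/T) * Q1^2 / (2 * Q2)` when `Q2 > 0`, else
#' `((T-1)/T) * Q1 * (Q1 - 1) / 2`. Returns `S_obs` when `Q1 = 0` or
#' `m_star = 0`; monotone non-decreasing in `m_star` with asymptote
#' `S_obs + Q0`.
#'
#' @param summary an [incidence_summary()] (needs `T >= 2`).
#' @param m_star additional sampling units, `>= 0`.
#' @return estimated richness (numeric).
#' @export
extrapolate_richness <- function(summary, m_star) {
  stopifnot(inherits(summary, "incidence_summary"))
  if (m_star < 0) stop("m_star must be >= 0")
  if (summary$T < 2) stop("extrapolation needs T >= 2")
  Tn <- summary$T; Q1 <- summary$Q1; Q2 <- summary$Q2
  if (Q1 == 0 || m_star == 0) return(as.numeric(summary$S_obs))
  Q0 <- if (Q2 > 0) (Tn - 1) / Tn * Q1^2 / (2 * Q2) else
    (Tn - 1) / Tn * Q1 * (Q1 - 1) / 2
  if (Q0 == 0) return(as.numeric(summary$S_obs))
  summary$S_obs + Q0 * (1 - (1 - Q1 / (Q1 + Tn * Q0))^m_star)
}

#' Richness standardized to a common number of sampling units
#'
#' Rarefies (`size < T`) or extrapolates (`size > T`) as needed; `size = T`
#' returns observed richness.
#'
#' @param summary an [incidence_summary()].
#' @param size target number of sampling units (`>= 1`).
#' @return estimated richness at `size` units.
#' @export
standardize_richness <- function(summary, size) {
  stopifnot(inherits(summary, "incidence_summary"))
  if (size <= summary$T) return(rarefy_richness(summary, size))
  # a single sampling unit carries no incidence-frequency information, so
  # the undetected-species estimate is zero and the estimate stays at S_obs
  if (summary$T < 2) return(as.numeric(summary$S_obs))
  extrapolate_richness(summary, size - summary$T)
}

#' Estimated band richness at a common sample size
#'
#' For every latitudinal band, standardizes richness to a common number of
#' sites (default the largest band size, so smaller bands are purely
#' extrapolated) and attaches a percentile bootstrap confidence interval
#' obtained by resampling the band's sites with replacement.
#'
#' @param bands a `lat_bands` object from [build_latitudinal_bands()].
#' @param matrix community matrix with site ids as rownames.
#' @param common_size common number of sampling units; default
#'   `max(bands$bands$n_sites)`.
#' @param n_boot bootstrap replicates (default 200).
#' @param seed RNG seed for the bootstrap (recorded in the output).
#' @param conf confidence level of the percentile interval.
#' @return the bands data.frame with `S_obs`, `S_est`, `S_est_lo`, `S_est_hi`
#'   columns; attributes `common_size`, `n_boot`, `seed`.
#' @export
estimate_band_richness <- function(bands, matrix, common_size = NULL,
                                   n_boot = 200, seed = 1, conf = 0.95) {
  stopifnot(inherits(bands, "lat_bands"))
  df <- bands$bands
  if (is.null(common_size)) common_size <- max(df$n_sites)
  if (common_size < 1) stop("common_size must be >= 1")
  set.seed(seed)
  a <- (1 - conf) / 2
  est <- t(vapply(bands$membership, function(ids) {
    if (!length(ids)) stop("band with no sites")
    summ <- incidence_summary(matrix, ids)
    s_est <- standardize_richness(summ, common_size)
    boot <- vapply(seq_len(n_boot), function(b) {
      res <- sample(ids, length(ids), replace = TRUE)
      standardize_richness(incidence_summary(matrix, res), common_size)
    }, numeric(1))
    c(S_obs = summ$S_obs, S_est = s_est,
      lo = unname(quantile(boot, a)), hi = unname(quantile(boot, 1 - a)))
  }, numeric(4)))
  df$S_obs <- as.integer(est[, "S_obs"])
  df$S_est <- est[, "S_est"]
  df$S_est_lo <- est[, "lo"]
  df$S_est_hi <- est[, "hi"]
  attr(df, "common_size") <- common_size
  attr(df, "n_boot") <- n_boot
  attr(df, "seed") <- seed
  df
}

#' Rarefaction curve of a site subset
#'
#' @inheritParams observed_richness
#' @param sizes sampling-unit counts; defaults to `1:T`.
#' @return data.frame with columns `m` and `S` (expected richness).
#' @export
rarefaction_curve <- function(matrix, site_subset = NULL, sizes = NULL) {
  summ <- incidence_summary(matrix, site_subset)
  if (is.null(sizes)) sizes <- seq_len(summ$T)
  data.frame(m = sizes,
             S = vapply(sizes, function(m) standardize_richness(summ, m),
                        numeric(1)))
}
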