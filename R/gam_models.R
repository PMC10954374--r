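# Additive-model comparison suite: penalized-spline fits with REML smoothing
# and null-space (shrinkage) penalization so uninformative terms drop toward
# zero effective degrees of freedom; deviance explained, AIC and the
# delta-AIC < 2 best-set rule; pairwise predictor correlations.

#' Metabolic-theory energy predictor
#'
#' `1 / (k * T_K)` with `T_K = T_mean + 273.15` and `k` the Boltzmann
#' constant in eV/K (8.617e-5). Paired with a natural-log richness response
#' (sites with zero richness must be excluded); strictly decreasing in
#' temperature.
#'
#' @param T_mean mean temperature in degrees Celsius (> -273.15).
#' @return inverse thermal energy, 1/eV.
#' @export
mte_predictor <- function(T_mean) {
  if (any(!is.finite(T_mean)) || any(T_mean <= -273.15))
    stop("T_mean must be finite and > -273.15 (absolute zero)")
  1 / (8.617e-5 * (T_mean + 273.15))
}

#' Fit a penalized additive richness model
#'
#' Builds and fits a generalized additive model: each smoothed term gets a
#' cubic-regression-spline basis (default 10 basis functions) with its
#' curvature penalty plus a null-space shrinkage penalty
#' (`select = TRUE`), and smoothing parameters are chosen by REML. Terms
#' with too few unique values for a spline basis (e.g. the glaciation index
#' or the limiting-resources rank, whose low numerical variability breaks
#' spline fitting) enter linearly. Rows with missing values in the used
#' columns are dropped (count reported in the result).
#'
#' @param data site table (data.frame).
#' @param predictors character vector of predictor columns.
#' @param smooth predictors to smooth; default all except `Glac`, `NLR` and
#'   `Fglac`.
#' @param response response column (default `"richness"`).
#' @param family model family (default [stats::gaussian()]).
#' @param k spline basis dimension per smooth (default 10).
#' @param select apply the null-space penalty (default `TRUE`).
#' @param fx fixed (unpenalized) regression splines, for nested-model
#'   deviance comparisons (default `FALSE`).
#' @param name optional model name carried into the result.
#' @param aic_comparable whether the AIC is comparable with other models of a
#'   suite (`FALSE` when the response is transformed).
#' @return object of class `drgam`: `model` (the mgcv fit), `terms`
#'   (data.frame: term, type, edf, statistic, p), `significant` (p < .05),
#'   `dev_expl` (%), `aic`, `aic_comparable`, `n`, `name`.
#' @export
fit_richness_gam <- function(data, predictors,
                             smooth = NULL,
                             response = "richness",
                             family = gaussian(),
                             k = 10, select = TRUE, fx = FALSE,
                             name = NULL, aic_comparable = TRUE) {
  missing_cols <- setdiff(c(predictors, response), names(data))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  if (is.null(smooth)) smooth <- setdiff(predictors, c("Glac", "NLR", "Fglac"))
  use <- data[, c(response, predictors), drop = FALSE]
  keep <- stats::complete.cases(use)
  use <- use[keep, , drop = FALSE]
  n <- nrow(use)
  if (n < length(predictors) + 2) stop("too few complete observations")
  rhs <- vapply(predictors, function(p) {
    if (p %in% smooth) {
      kp <- min(k, length(unique(use[[p]])) - 1)
      if (kp >= 3)
        sprintf("s(%s, k = %d, bs = \"cr\"%s)", p, kp,
                if (fx) ", fx = TRUE" else "")
      else p
    } else p
  }, character(1))
  form <- as.formula(paste(response, "~", paste(rhs, collapse = " + ")))
  if (sd(use[[response]]) == 0) {
    # a constant response has nothing to explain; REML cannot even start
    fit0 <- mgcv::gam(as.formula(paste(response, "~ 1")), data = use,
                      family = family)
    terms_tab <- data.frame(term = predictors, type = "dropped",
                            edf = 0, statistic = NA_real_, p = NA_real_,
                            stringsAsFactors = FALSE)
    return(structure(list(model = fit0, name = name, terms = terms_tab,
                          significant = character(0), dev_expl = 0,
                          aic = AIC(fit0), aic_comparable = aic_comparable,
                          n = n, response = response,
                          n_dropped = sum(!keep)), class = "drgam"))
  }
  fit <- mgcv::gam(form, data = use, family = family, method = "REML",
                   select = select && !fx)
  sm <- summary(fit)
  terms_tab <- data.frame(term = character(0), type = character(0),
                          edf = numeric(0), statistic = numeric(0),
                          p = numeric(0), stringsAsFactors = FALSE)
  if (length(sm$s.table)) {
    st <- sm$s.table
    terms_tab <- rbind(terms_tab, data.frame(
      term = gsub("^s\\(|\\)$", "", rownames(st)),
      type = "smooth", edf = st[, "edf"],
      statistic = st[, ncol(st) - 1], p = st[, ncol(st)],
      stringsAsFactors = FALSE))
  }
  pt <- sm$p.table
  if (nrow(pt) > 1) {
    pt <- pt[rownames(pt) != "(Intercept)", , drop = FALSE]
    if (nrow(pt))
      terms_tab <- rbind(terms_tab, data.frame(
        term = rownames(pt), type = "linear", edf = 1,
        statistic = pt[, 3], p = pt[, 4], stringsAsFactors = FALSE))
  }
  rownames(terms_tab) <- NULL
  null_dev <- fit$null.deviance
  dev_expl <- if (is.finite(null_dev) && null_dev > 0)
    100 * (1 - fit$deviance / null_dev) else 0
  sig <- terms_tab$term[!is.na(terms_tab$p) & terms_tab$p < 0.05]
  structure(list(model = fit, name = name, terms = terms_tab,
                 significant = sig, dev_expl = dev_expl, aic = AIC(fit),
                 aic_comparable = aic_comparable, n = n,
                 response = response, n_dropped = sum(!keep)),
            class = "drgam")
}

#' @export
print.drgam <- function(x, ...) {
  cat("Penalized additive model", if (!is.null(x$name)) paste0("(", x$name, ")"),
      "\n")
  cat(sprintf("  n = %d | deviance explained = %.2f%% | AIC = %.2f%s\n",
              x$n, x$dev_expl, x$aic,
              if (!x$aic_comparable) " (non-comparable)" else ""))
  print(x$terms, row.names = FALSE, digits = 3)
  cat("  significant (p < .05):",
      if (length(x$significant)) paste(x$significant, collapse = " + ")
      else "none", "\n")
  invisible(x)
}

.suite_specs <- function(variant) {
  climate <- c("T_min", "T_max", "T_sd", "T_mean")
  chem <- c("T_insitu", "pH", "EC", "Osat", "Ca", "TP", "SiO2", "Vel")
  hist <- c("Glac", "Fglac")
  specs <- list(
    list(name = "Latitudinal effect", group = "Exploratory model",
         predictors = "Lat"),
    list(name = "Spatial effect", group = "Exploratory model",
         predictors = c("Lat", "Lon", "Elev")),
    list(name = "Climatical effect", group = "Exploratory model",
         predictors = climate),
    list(name = "Chemical effect", group = "Exploratory model",
         predictors = chem, chemical_only = TRUE),
    list(name = "Total effect", group = "Exploratory model",
         predictors = if (variant == "chemical") c(chem, climate, hist)
         else c(climate, hist)),
    list(name = "Species-energy theory via temperature",
         group = "Formal hypothesis", predictors = "T_mean"),
    list(name = "Species-energy theory via cell density",
         group = "Formal hypothesis", predictors = "ln_celden"),
    list(name = "Energy variability hypothesis", group = "Formal hypothesis",
         predictors = "T_sd"),
    list(name = "Climatical tolerance hypothesis",
         group = "Formal hypothesis", predictors = c("T_min", "T_max")),
    list(name = "Metabolic theory", group = "Formal hypothesis",
         predictors = "inv_kT", mte = TRUE),
    list(name = "Historical effect", group = "Formal hypothesis",
         predictors = hist),
    list(name = "Niche dimensionality", group = "Formal hypothesis",
         predictors = "NLR", chemical_only = TRUE)
  )
  if (variant == "complete")
    specs <- Filter(function(s) !isTRUE(s$chemical_only), specs)
  specs
}

#' Fit the full model-comparison suite
#'
#' Fits every applicable equation of the twelve-model comparison (latitude,
#' spatial, climatic, chemical, total, two species-energy forms, energy
#' variability, climatic tolerance, metabolic theory, historical effect,
#' niche dimensionality). The `"complete"` variant skips the
#' chemistry-dependent equations; the `"chemical"` variant restricts to sites
#' with full chemistry and fits all twelve. The metabolic-theory model
#' regresses log richness on the unsmoothed inverse thermal energy and its
#' AIC is flagged non-comparable. The best set holds every comparable model
#' whose AIC lies within 2 units of the minimum. Per-model failures are
#' caught and reported; the suite continues.
#'
#' @param data site table with `richness`, spatial/climate columns, and (for
#'   the chemical variant) chemistry, `NLR`, `Glac`, `Fglac`, `Cel_den`.
#' @param variant `"complete"` or `"chemical"`.
#' @param family model family (default gaussian on untransformed richness).
#' @param k spline basis dimension.
#' @param alpha significance level for reporting significant terms.
#' @return data.frame of class `model_suite` (one row per model: name, group,
#'   equation, significant terms, `dev_expl`, `aic`, `aic_comparable`,
#'   `best`, `n`, `error`), with the fitted `drgam` objects in the `fits`
#'   attribute.
#' @export
run_model_suite <- function(data, variant = c("complete", "chemical"),
                            family = gaussian(), k = 10, alpha = 0.05) {
  variant <- match.arg(variant)
  data <- as.data.frame(data)
  if (variant == "chemical") {
    if ("chem_subset" %in% names(data)) data <- data[data$chem_subset, ]
    chem_cols <- c("T_insitu", "pH", "EC", "Osat", "Ca", "TP", "SiO2", "Vel")
    have <- chem_cols %in% names(data)
    if (!all(have))
      stop("chemical variant needs columns: ",
           paste(chem_cols[!have], collapse = ", "))
    data <- data[stats::complete.cases(data[, chem_cols]), ]
  }
  if ("Cel_den" %in% names(data)) data$ln_celden <- log(data$Cel_den + 1)
  if ("T_mean" %in% names(data)) data$inv_kT <- mte_predictor(data$T_mean)
  specs <- .suite_specs(variant)
  fits <- vector("list", length(specs))
  rows <- lapply(seq_along(specs), function(i) {
    sp <- specs[[i]]
    res <- tryCatch({
      if (isTRUE(sp$mte)) {
        mte_data <- data[data$richness >= 1, , drop = FALSE]
        mte_data$ln_richness <- log(mte_data$richness)
        fit <- fit_richness_gam(mte_data, sp$predictors, smooth = character(0),
                                response = "ln_richness", family = gaussian(),
                                k = k, name = sp$name, aic_comparable = FALSE)
      } else {
        fit <- fit_richness_gam(data, sp$predictors, family = family, k = k,
                                name = sp$name)
      }
      fits[[i]] <<- fit
      data.frame(model = sp$name, group = sp$group,
                 equation = paste("~", paste(sp$predictors, collapse = " + ")),
                 significant = if (length(fit$significant))
                   paste(fit$significant, collapse = " + ") else "N.S.",
                 dev_expl = fit$dev_expl, aic = fit$aic,
                 aic_comparable = fit$aic_comparable, n = fit$n,
                 error = NA_character_, stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(model = sp$name, group = sp$group,
                 equation = paste("~", paste(sp$predictors, collapse = " + ")),
                 significant = NA_character_, dev_expl = NA_real_,
                 aic = NA_real_, aic_comparable = NA, n = NA_integer_,
                 error = conditionMessage(e), stringsAsFactors = FALSE)
    })
    res
  })
  out <- do.call(rbind, rows)
  comparable <- !is.na(out$aic) & out$aic_comparable
  out$best <- FALSE
  if (any(comparable)) {
    best_aic <- min(out$aic[comparable])
    out$best <- comparable & out$aic < best_aic + 2
  }
  attr(out, "fits") <- fits
  attr(out, "variant") <- variant
  class(out) <- c("model_suite", "data.frame")
  out
}

#' Pairwise Pearson correlation matrix with significance stars
#'
#' Pairwise-complete Pearson correlations between predictors and responses,
#' with two-tailed p-values, the usual star coding (*** p < .001, ** p < .01,
#' * p < .05) and a flag for collinear pairs with r^2 > 0.90.
#'
#' @param data site table.
#' @param variables columns to correlate (>= 3 complete pairs per cell
#'   required).
#' @return object of class `cor_matrix`: `r`, `p`, `stars` matrices and
#'   `high_collinearity` (data.frame of flagged pairs).
#' @export
correlation_matrix <- function(data, variables) {
  missing_cols <- setdiff(variables, names(data))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  v <- length(variables)
  r <- p <- matrix(NA_real_, v, v, dimnames = list(variables, variables))
  stars <- matrix("", v, v, dimnames = list(variables, variables))
  diag(r) <- 1
  for (i in seq_len(v)) {
    for (j in seq_len(v)) {
      if (i >= j) next
      x <- data[[variables[i]]]; y <- data[[variables[j]]]
      ok <- is.finite(x) & is.finite(y)
      if (sum(ok) < 3) stop("fewer than 3 complete pairs for ",
                            variables[i], " / ", variables[j])
      if (sd(x[ok]) == 0 || sd(y[ok]) == 0)
        stop("zero-variance column: ", variables[if (sd(x[ok]) == 0) i else j])
      ct <- cor.test(x[ok], y[ok])
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
      s <- if (ct$p.value < 0.001) "***" else if (ct$p.value < 0.01) "**"
      else if (ct$p.value < 0.05) "*" else ""
      stars[i, j] <- stars[j, i] <- s
    }
  }
  pairs <- which(upper.tri(r) & r^2 > 0.90, arr.ind = TRUE)
  high <- data.frame(var1 = variables[pairs[, 1]],
                     var2 = variables[pairs[, 2]],
                     r = r[pairs], stringsAsFactors = FALSE)
  structure(list(r = r, p = p, stars = stars, high_collinearity = high),
            class = "cor_matrix")
}

#' @export
print.cor_matrix <- function(x, ...) {
  disp <- matrix(paste0(formatC(x$r, digits = 2, format = "f"), x$stars),
                 nrow(x$r), dimnames = dimnames(x$r))
  diag(disp) <- "1"
  print(disp, quote = FALSE)
  if (nrow(x$high_collinearity))
    cat("collinear pairs (r^2 > .90):",
        paste(x$high_collinearity$var1, x$high_collinearity$var2,
              sep = "~", collapse = ", "), "\n")
  invisible(x)
}

#' Latitude-richness additive model
#'
#' One smoothed latitude term against per-site richness, band observed
#' richness, or band estimated richness; reports the smooth's effective
#' degrees of freedom, F statistic and p-value.
#'
#' @param data site table (level `"site"`) or band table from
#'   [estimate_band_richness()] (levels `"band"`, `"band_estimated"`).
#' @param level which response/latitude pairing to fit.
#' @param k spline basis dimension (clipped to the data).
#' @return a `drgam`; convenience fields `edf`, `F`, `p` for the latitude
#'   smooth.
#' @export
latitude_richness_gam <- function(data,
                                  level = c("site", "band", "band_estimated"),
                                  k = 10) {
  level <- match.arg(level)
  df <- as.data.frame(data)
  if (level == "site") {
    use <- data.frame(richness = df$richness, Lat = df$Lat)
  } else {
    resp <- if (level == "band") df$S_obs else df$S_est
    use <- data.frame(richness = resp, Lat = df$mean_lat)
  }
  if (nrow(use) < 5) stop("need >= 5 observations")
  fit <- fit_richness_gam(use, "Lat", k = k,
                          name = paste0("richness ~ s(Lat) [", level, "]"))
  smooth_row <- fit$terms[fit$terms$term == "Lat", ]
  fit$edf <- smooth_row$edf[1]
  fit$F <- smooth_row$statistic[1]
  fit$p <- smooth_row$p[1]
  fit
}
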