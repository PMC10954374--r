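# Paper-defined predictor variables: number of limiting resources (NLR),
# glaciation exposure (Glac, Fglac), detection-limit substitution, and
# latitudinal bands.

#' Number of limiting resources (NLR)
#'
#' Scores each of four resource variables (Ca, TP, SiO2 and electrical
#' conductivity as a proxy of basic cations) against its own 0.33 and 0.66
#' sample quantiles across the scored sites: 2 below the 0.33 quantile,
#' 1 between the quantiles (closed interval), 0 above the 0.66 quantile.
#' NLR is the sum of the four scores, a rank between 8 (strong resource
#' limitation) and 0 (no limitation). Rank-based, so invariant under any
#' strictly monotone transform of a resource variable.
#'
#' Sites with missing chemistry are excluded from the quantile computation
#' and returned as `NA`, with their ids recorded in the `excluded` attribute.
#'
#' @param chem data.frame with the resource variables (and optionally
#'   `site_id`).
#' @param vars the four resource columns.
#' @param probs the two quantile levels.
#' @param type sample-quantile estimator passed to [stats::quantile()]
#'   (default 7, linear interpolation).
#' @return integer vector of NLR ranks aligned to `chem` rows, attribute
#'   `excluded` (character ids or row numbers of unscored sites) and
#'   `scores` (the per-variable score matrix).
#' @export
compute_nlr <- function(chem, vars = c("Ca", "TP", "SiO2", "EC"),
                        probs = c(0.33, 0.66), type = 7) {
  missing_cols <- setdiff(vars, names(chem))
  if (length(missing_cols))
    stop("missing resource variable(s): ", paste(missing_cols, collapse = ", "))
  x <- as.matrix(chem[, vars])
  complete <- stats::complete.cases(x)
  if (sum(complete) < 3) stop("need >= 3 sites with complete chemistry")
  scores <- matrix(NA_integer_, nrow(x), length(vars),
                   dimnames = list(NULL, vars))
  for (j in seq_along(vars)) {
    v <- x[complete, j]
    q <- quantile(v, probs = probs, type = type, names = FALSE)
    scores[complete, j] <- ifelse(v < q[1], 2L, ifelse(v > q[2], 0L, 1L))
  }
  nlr <- as.integer(rowSums(scores))
  ids <- if ("site_id" %in% names(chem)) chem$site_id else
    as.character(seq_len(nrow(chem)))
  attr(nlr, "excluded") <- ids[!complete]
  attr(nlr, "scores") <- scores
  nlr
}

.ice_presence <- function(ice) {
  cols <- grep("^ice_", names(ice), value = TRUE)
  if (length(cols) != 9)
    stop("ice history must have exactly nine ice_* timestamp columns")
  ts <- as.numeric(sub("^ice_", "", cols))
  pres <- as.matrix(ice[, cols[order(-ts)]])
  if (!all(pres %in% c(0, 1))) stop("ice presence must be binary")
  list(pres = pres, ts = sort(ts, decreasing = TRUE))
}

#' Glaciation exposure index (Glac)
#'
#' Proportion of the last 35 ka a site spent under the ice sheet:
#' `Glac = 1 - t_last / 35`, where `t_last` (ka) is the most recent
#' reconstruction timestamp at which ice was present. Sites never iced get 0.
#' With the nine reconstruction timestamps the maximum attainable value when
#' no ice persists past 10 ka is 1 - 10/35 = 0.714.
#'
#' @param ice ice-history data.frame (`site_id` + nine binary `ice_*`
#'   columns named by timestamp in ka, e.g. `ice_20`).
#' @return numeric vector in `[0, 1)` aligned to `ice` rows.
#' @export
compute_glac <- function(ice) {
  ih <- .ice_presence(ice)
  t_last <- apply(ih$pres, 1, function(p) {
    iced <- which(p == 1)
    if (!length(iced)) NA_real_ else min(ih$ts[iced])
  })
  ifelse(is.na(t_last), 0, 1 - t_last / 35)
}

#' Ice presence at the Last Glacial Maximum (Fglac)
#'
#' Binary indicator: 1 if ice was present at any of the configured LGM
#' timestamps (default the 20 ka reconstruction layer, the closest to the
#' Last Glacial Maximum), else 0.
#'
#' @param ice ice-history data.frame as in [compute_glac()].
#' @param lgm_timestamps timestamps (ka) defining the LGM layer.
#' @return integer 0/1 vector aligned to `ice` rows.
#' @export
compute_fglac <- function(ice, lgm_timestamps = 20) {
  if (!length(lgm_timestamps)) stop("lgm_timestamps must be nonempty")
  ih <- .ice_presence(ice)
  use <- ih$ts %in% lgm_timestamps
  if (!any(use)) stop("no ice-history column matches lgm_timestamps")
  as.integer(rowSums(ih$pres[, use, drop = FALSE]) > 0)
}

#' Substitute values below the detection limit
#'
#' Replaces flagged below-detection measurements by a value strictly inside
#' (0, DL): either DL/2 (deterministic default) or a uniform draw on (0, DL).
#'
#' @param values numeric vector of measurements (must be nonnegative).
#' @param detection_limit detection limit(s), scalar or per-value, > 0.
#' @param method `"half_dl"` or `"uniform"`.
#' @param flags logical vector marking below-detection entries; default
#'   `values < detection_limit`.
#' @param seed optional seed for the uniform method.
#' @return numeric vector; attributes `method`, `seed`, `n_substituted`.
#' @export
substitute_below_detection <- function(values, detection_limit,
                                       method = c("half_dl", "uniform"),
                                       flags = NULL, seed = NULL) {
  method <- match.arg(method)
  if (any(detection_limit <= 0, na.rm = TRUE))
    stop("detection_limit must be > 0")
  if (any(values < 0, na.rm = TRUE)) stop("negative measured values")
  dl <- rep_len(detection_limit, length(values))
  if (is.null(flags)) flags <- !is.na(values) & values < dl
  out <- values
  if (any(flags)) {
    if (method == "half_dl") {
      out[flags] <- dl[flags] / 2
    } else {
      if (!is.null(seed)) set.seed(seed)
      out[flags] <- runif(sum(flags), 0, dl[flags])
    }
  }
  attr(out, "method") <- method
  attr(out, "seed") <- seed
  attr(out, "n_substituted") <- sum(flags)
  out
}

#' Latitudinal bands
#'
#' Partitions sites into consecutive latitudinal bands of about
#' `target_size` sites. Sites are sorted by latitude; any run of sites
#' separated from the rest by more than `isolation_gap` degrees forms its own
#' band regardless of size (so a handful of far-southern sites become a
#' single long band); within each contiguous segment the sites are split into
#' `round(n / target_size)` consecutive bands of near-equal size; bands
#' narrower than `min_extension` degrees are merged with their neighbor.
#' Every site falls in exactly one band and concatenating bands in latitude
#' order recovers the sorted site list.
#'
#' @param sites site table with `site_id` and `Lat`.
#' @param target_size nominal number of sites per band (default 12).
#' @param isolation_gap gap (degrees) beyond which a run of sites is isolated
#'   into its own band (default 1).
#' @param min_extension minimum band extension in degrees (default 0, no
#'   merging).
#' @return object of class `lat_bands`: list with `bands` (data.frame:
#'   `band_id`, `n_sites`, `mean_lat`, `lat_min`, `lat_max`, `extension`) and
#'   `membership` (named list band_id -> site ids, south to north).
#' @export
build_latitudinal_bands <- function(sites, target_size = 12,
                                    isolation_gap = 1, min_extension = 0) {
  stopifnot(nrow(sites) >= 1, target_size >= 1)
  ord <- order(sites$Lat, seq_len(nrow(sites)))
  lat <- sites$Lat[ord]
  ids <- sites$site_id[ord]
  n <- length(lat)
  seg <- cumsum(c(1, diff(lat) > isolation_gap))
  groups <- list()
  for (s in unique(seg)) {
    idx <- which(seg == s)
    nb <- max(1L, round(length(idx) / target_size))
    cuts <- rep(seq_len(nb), diff(round(seq(0, length(idx), length.out = nb + 1))))
    groups <- c(groups, split(idx, cuts))
  }
  # merge bands narrower than min_extension with their (next) neighbor,
  # never across an isolation gap
  if (min_extension > 0 && length(groups) > 1) {
    i <- 1
    while (i <= length(groups) && length(groups) > 1) {
      ext <- diff(range(lat[groups[[i]]]))
      if (ext < min_extension) {
        j <- if (i < length(groups)) i + 1 else i - 1
        # adjacent bands inside one segment are contiguous, so merging never
        # crosses an isolation gap
        same_seg <- seg[groups[[i]][1]] == seg[groups[[j]][1]]
        if (same_seg) {
          groups[[j]] <- sort(c(groups[[i]], groups[[j]]))
          groups[[i]] <- NULL
          next
        }
      }
      i <- i + 1
    }
  }
  groups <- groups[order(vapply(groups, function(g) min(lat[g]), numeric(1)))]
  band_id <- sprintf("B%02d", seq_along(groups))
  bands <- data.frame(
    band_id = band_id,
    n_sites = vapply(groups, length, integer(1)),
    mean_lat = vapply(groups, function(g) mean(lat[g]), numeric(1)),
    lat_min = vapply(groups, function(g) min(lat[g]), numeric(1)),
    lat_max = vapply(groups, function(g) max(lat[g]), numeric(1)),
    stringsAsFactors = FALSE
  )
  bands$extension <- bands$lat_max - bands$lat_min
  membership <- lapply(groups, function(g) ids[g])
  names(membership) <- band_id
  structure(list(bands = bands, membership = membership), class = "lat_bands")
}

#' @export
print.lat_bands <- function(x, ...) {
  cat("Latitudinal bands:", nrow(x$bands), "bands,",
      sum(x$bands$n_sites), "sites\n")
  print(x$bands, row.names = FALSE)
  invisible(x)
}
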