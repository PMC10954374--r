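# Synthetic site tables, ice histories and community matrices with the
# statistical structure the downstream analyses assume: climate and several
# chemistry variables trend linearly with latitude (increasing northward),
# flow velocity and oxygen saturation are spatially unstructured, a chemical
# subset carries the laboratory variables, and the community matrix follows a
# configurable idealized metacommunity structure.

.phys_chem_vars <- c("T_insitu", "pH", "EC", "Osat", "Ca", "TP", "SiO2",
                     "Vel", "depth")

.default_lat_slopes <- c(
  T_mean = 0.45, T_max = 0.60, T_min = 0.35, T_sd = 0.08,
  T_insitu = 0.40, pH = 0.05, EC = 6, SiO2 = 0.6, Ca = 0.4, TP = 0.002,
  Vel = 0, Osat = 0, depth = 0, Elev = 35, Lon = 0.12
)

.default_base <- c(
  T_mean = 9, T_max = 20, T_min = 2, T_sd = 3.2,
  T_insitu = 11, pH = 7.6, EC = 150, SiO2 = 9, Ca = 8, TP = 0.05,
  Vel = 0.6, Osat = 95, depth = 0.35, Elev = 450, Lon = -72.5
)

.default_noise_sd <- c(
  T_mean = 0.8, T_max = 1.2, T_min = 1.0, T_sd = 0.35,
  T_insitu = 2.2, pH = 0.35, EC = 60, SiO2 = 3, Ca = 4, TP = 0.03,
  Vel = 0.3, Osat = 6, depth = 0.15, Elev = 280, Lon = 0.8
)

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. Defaults mirror the
#' study design the generator emulates: 373 sites between 52 and 35 degrees
#' south (latitude signed, south negative, so "increases with latitude" means
#' increases northward), climate and SiO2/pH trending northward, Vel and Osat
#' latitude-independent, and a chemical subset of roughly half the sites
#' (182/373) carrying the laboratory chemistry.
#'
#' @param n_sites number of sites.
#' @param lat_range latitude interval, signed decimal degrees, south negative.
#' @param n_species number of species in the community matrix.
#' @param structure idealized metacommunity structure of the community
#'   generator: `"gleasonian"`, `"clementsian"`, `"nested"`, `"random"` or
#'   `"checkerboard"`.
#' @param n_compartments number of species compartments (clementsian only).
#' @param climate_lat_slopes named numeric vector of per-degree latitude
#'   slopes; entries override the built-in defaults.
#' @param noise_sd named numeric vector of residual standard deviations;
#'   entries override the built-in defaults. All values must be >= 0.
#' @param chem_subset_fraction fraction of sites carrying full chemistry.
#' @param richness_effects named vector of linear effects for
#'   [generate_richness_response()]; default a negative number-of-limiting-
#'   resources effect.
#' @param richness_intercept,richness_noise_sd intercept and residual sd of
#'   the simulated richness response.
#' @param occupancy_prob Bernoulli occupancy probability of the `"random"`
#'   structure.
#' @param seed integer seed; all generator randomness derives from it.
#' @return an object of class `sim_config` (a list).
#' @export
sim_config <- function(n_sites = 373L,
                       lat_range = c(-52, -35),
                       n_species = 120L,
                       structure = c("gleasonian", "clementsian", "nested",
                                     "random", "checkerboard"),
                       n_compartments = 3L,
                       climate_lat_slopes = NULL,
                       noise_sd = NULL,
                       chem_subset_fraction = 182 / 373,
                       richness_effects = c(NLR = -2),
                       richness_intercept = 25,
                       richness_noise_sd = 5,
                       occupancy_prob = 0.25,
                       seed = 1L) {
  structure <- match.arg(structure)
  stopifnot(n_sites >= 2, n_species >= 2,
            length(lat_range) == 2, lat_range[1] < lat_range[2],
            chem_subset_fraction > 0, chem_subset_fraction <= 1,
            n_compartments >= 1, n_compartments <= n_species)
  slopes <- .default_lat_slopes
  if (!is.null(climate_lat_slopes)) {
    if (!all(is.finite(climate_lat_slopes)))
      stop("climate_lat_slopes must be finite")
    slopes[names(climate_lat_slopes)] <- climate_lat_slopes
  }
  nsd <- .default_noise_sd
  if (!is.null(noise_sd)) {
    if (any(noise_sd < 0)) stop("noise_sd must be >= 0")
    nsd[names(noise_sd)] <- noise_sd
  }
  structure(list(
    n_sites = as.integer(n_sites), lat_range = lat_range,
    n_species = as.integer(n_species), structure = structure,
    n_compartments = as.integer(n_compartments),
    climate_lat_slopes = slopes, noise_sd = nsd,
    chem_subset_fraction = chem_subset_fraction,
    richness_effects = richness_effects,
    richness_intercept = richness_intercept,
    richness_noise_sd = richness_noise_sd,
    occupancy_prob = occupancy_prob,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Generate a synthetic site table
#'
#' Latitudes are uniform over `lat_range`; every covariate with a configured
#' slope is linear in latitude plus independent Gaussian noise, so covariates
#' with positive slopes increase northward (toward -35 degrees). Vel, Osat and
#' depth have zero slope by default and are therefore latitude-independent.
#' Laboratory chemistry columns (`T_insitu`, `pH`, `EC`, `Osat`, `Ca`, `TP`,
#' `SiO2`, `Vel`, `depth`) are set to `NA` outside the chemical subset.
#'
#' @param config a [sim_config()].
#' @return a `data.frame` with one row per site (`site_id`, `Lat`, `Lon`,
#'   `Elev`, climate, chemistry, `chem_subset` flag). Deterministic for a
#'   fixed config.
#' @export
generate_sites <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_sites
  lat <- sort(runif(n, config$lat_range[1], config$lat_range[2]))
  lat_c <- lat - mean(config$lat_range)
  sl <- config$climate_lat_slopes
  nsd <- config$noise_sd
  gen <- function(v) {
    .default_base[[v]] + sl[[v]] * lat_c + rnorm(n, 0, nsd[[v]])
  }
  sites <- data.frame(
    site_id = sprintf("S%04d", seq_len(n)),
    Lat = lat,
    Lon = gen("Lon"),
    Elev = pmax(gen("Elev"), 0),
    T_mean = gen("T_mean"), T_max = gen("T_max"), T_min = gen("T_min"),
    T_sd = pmax(gen("T_sd"), 0.1),
    T_insitu = gen("T_insitu"),
    pH = gen("pH"),
    EC = pmax(gen("EC"), 5),
    Osat = pmin(pmax(gen("Osat"), 40), 130),
    Ca = pmax(gen("Ca"), 0.2),
    TP = pmax(gen("TP"), 0.001),
    SiO2 = pmax(gen("SiO2"), 0.5),
    Vel = pmax(gen("Vel"), 0.02),
    depth = pmax(gen("depth"), 0.05),
    stringsAsFactors = FALSE
  )
  n_chem <- max(1L, round(config$chem_subset_fraction * n))
  chem_sites <- sort(sample.int(n, n_chem))
  sites$chem_subset <- seq_len(n) %in% chem_sites
  sites[!sites$chem_subset, .phys_chem_vars] <- NA_real_
  sites
}

#' Generate an ice-sheet history table
#'
#' Sites south of `southern_threshold` receive ice records at the nine
#' reconstruction timestamps (35, 30, 25, 20, 15, 13, 10, 5, 0.2 ka); ice
#' presence is monotone in time (once gone it never returns) and the last-ice
#' timestamp gets older northward across the glaciated zone, so the most
#' recently deglaciated sites are the southernmost. Sites north of the
#' threshold were never iced. Deterministic given the site table.
#'
#' @param sites a site table with `site_id` and `Lat`.
#' @param southern_threshold latitude (signed) north of which no site was
#'   ever glaciated; default -38.
#' @param config optional [sim_config()] (unused; accepted for interface
#'   symmetry with the other generators).
#' @return a `data.frame`: `site_id` plus binary columns `ice_35` ... `ice_0.2`.
#' @export
generate_ice_history <- function(sites, southern_threshold = -38,
                                 config = NULL) {
  ts <- ice_timestamps()
  lat <- sites$Lat
  out <- matrix(0L, nrow = nrow(sites), ncol = length(ts),
                dimnames = list(NULL, paste0("ice_", ts)))
  south <- lat < southern_threshold
  if (any(south)) {
    lat_min <- min(lat[south])
    span <- southern_threshold - lat_min
    # fraction 0 at the threshold edge -> deglaciated earliest (t_last = 35);
    # fraction 1 at the deep south -> deglaciated latest (t_last = 10).
    frac <- if (span > 0) (southern_threshold - lat[south]) / span else
      rep(1, sum(south))
    target <- 35 - 25 * frac
    usable <- ts[ts >= 10]
    t_last <- vapply(target, function(a) usable[which.min(abs(usable - a))],
                     numeric(1))
    for (i in seq_along(t_last)) {
      out[which(south)[i], ts >= t_last[i]] <- 1L
    }
  }
  data.frame(site_id = sites$site_id, out, check.names = FALSE,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic community matrix
#'
#' Builds a sites-by-species count matrix realizing one of five idealized
#' metacommunity structures along the latent latitude gradient:
#' \describe{
#'   \item{gleasonian}{each species occupies the sites whose gradient position
#'     falls inside its own response window, with optima drawn independently.}
#'   \item{clementsian}{optima are drawn in `n_compartments` tight clusters so
#'     species ranges coincide in blocks.}
#'   \item{nested}{sites are ordered by a richness gradient and every site's
#'     species set is a prefix of one fixed species ranking, so the poorer
#'     community is always a subset of the richer.}
#'   \item{random}{independent Bernoulli occupancy.}
#'   \item{checkerboard}{species come in mutually exclusive pairs that never
#'     co-occur at a site.}
#' }
#' Counts for occupied cells are 1 + Poisson; the `truth` attribute records
#' the generating parameters (optima, widths, compartments, ranking).
#'
#' @param sites site table from [generate_sites()].
#' @param config a [sim_config()].
#' @return integer matrix (sites x species) with dimnames, attribute `truth`.
#' @export
generate_community <- function(sites, config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_species < 2) stop("n_species must be >= 2")
  set.seed(config$seed + 2L)
  n <- nrow(sites)
  s <- config$n_species
  g <- (sites$Lat - min(sites$Lat)) / diff(range(sites$Lat))
  occ <- matrix(0L, n, s)
  truth <- list(structure = config$structure)

  if (config$structure %in% c("gleasonian", "clementsian")) {
    if (config$structure == "gleasonian") {
      opt <- runif(s, 0, 1)
      wid <- runif(s, 0.08, 0.20)
      truth$compartment <- rep(NA_integer_, s)
    } else {
      k <- config$n_compartments
      centers <- (seq_len(k) - 0.5) / k
      comp <- sort(rep_len(seq_len(k), s))
      opt <- centers[comp] + rnorm(s, 0, 0.01)
      wid <- rep(0.5 / k * 0.95, s) + runif(s, -0.01, 0.01)
      truth$compartment <- comp
    }
    occ <- outer(g, opt, function(x, o) abs(x - o)) <=
      matrix(wid, n, s, byrow = TRUE)
    occ <- occ * 1L
    truth$optima <- opt
    truth$widths <- wid
  } else if (config$structure == "nested") {
    # site order by richness gradient: northern (larger g) sites are richer
    n_i <- pmax(1L, round(s * (0.15 + 0.8 * g)^1.3))
    ranking <- sample.int(s)
    for (i in seq_len(n)) occ[i, ranking[seq_len(n_i[i])]] <- 1L
    truth$ranking <- ranking
    truth$site_richness <- n_i
  } else if (config$structure == "random") {
    occ <- matrix(rbinom(n * s, 1, config$occupancy_prob), n, s)
  } else { # checkerboard
    if (s %% 2 == 1) s_pairs <- (s - 1) / 2 else s_pairs <- s / 2
    pair_of <- rep(seq_len(s_pairs), each = 2, length.out = s)
    for (p in seq_len(s_pairs)) {
      members <- which(pair_of == p)
      pick <- sample(c(members, 0L), n, replace = TRUE,
                     prob = c(0.4, 0.4, 0.2)[seq_len(length(members) + 1)])
      for (i in seq_len(n)) if (pick[i] > 0) occ[i, pick[i]] <- 1L
    }
    if (s %% 2 == 1) occ[, s] <- rbinom(n, 1, 0.3)
    truth$pair_of <- pair_of
  }

  counts <- occ
  counts[occ == 1L] <- 1L + rpois(sum(occ), 20)
  dimnames(counts) <- list(sites$site_id, sprintf("sp%03d", seq_len(s)))
  attr(counts, "truth") <- truth
  counts
}

#' Simulate a richness response from site covariates
#'
#' Adds a `richness` column generated as a linear predictor in the chosen
#' covariates plus Gaussian noise (rounded, floored at zero), for recovery
#' tests of the additive-model suite. The generating parameters are recorded
#' in the `truth` attribute.
#'
#' @param sites site table (must contain every predictor named in
#'   `config$richness_effects`).
#' @param config a [sim_config()].
#' @param round_response round to integer counts (default `TRUE`).
#' @return `sites` with a `richness` column and a `truth` attribute.
#' @export
generate_richness_response <- function(sites, config, round_response = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  eff <- config$richness_effects
  missing_vars <- setdiff(names(eff), names(sites))
  if (length(missing_vars))
    stop("unknown predictor(s) in richness_effects: ",
         paste(missing_vars, collapse = ", "))
  set.seed(config$seed + 3L)
  lp <- rep(config$richness_intercept, nrow(sites))
  for (v in names(eff)) lp <- lp + eff[[v]] * sites[[v]]
  y <- lp + rnorm(nrow(sites), 0, config$richness_noise_sd)
  if (round_response) y <- round(y)
  sites$richness <- pmax(y, 0)
  attr(sites, "truth") <- list(effects = eff,
                               intercept = config$richness_intercept,
                               noise_sd = config$richness_noise_sd,
                               link = "identity", family = "gaussian")
  sites
}

#' Simulate a full study-like dataset
#'
#' Runs the three generators and ties them together: per-site richness is the
#' realized species count of the community matrix, and total cell density is
#' log-normal with mean increasing in realized richness (so density and
#' richness are positively associated without asserting causality).
#'
#' @param config a [sim_config()].
#' @param southern_threshold passed to [generate_ice_history()].
#' @return a list of class `diatom_simulation`: `sites`, `community`, `ice`,
#'   `truth`, `config`.
#' @export
simulate_dataset <- function(config = sim_config(),
                             southern_threshold = -38) {
  sites <- generate_sites(config)
  ice <- generate_ice_history(sites, southern_threshold, config)
  community <- generate_community(sites, config)
  rich <- as.integer(rowSums(community > 0))
  set.seed(config$seed + 4L)
  sites$richness <- rich
  sites$Cel_den <- round(rlnorm(nrow(sites),
                                meanlog = 8 + 0.06 * rich, sdlog = 0.5))
  structure(list(sites = sites, community = community, ice = ice,
                 truth = attr(community, "truth"), config = config),
            class = "diatom_simulation")
}

#' @export
print.diatom_simulation <- function(x, ...) {
  cat("Synthetic diatom dataset:", nrow(x$sites), "sites,",
      ncol(x$community), "species\n")
  cat("  structure:", x$truth$structure,
      "| latitude:", sprintf("%.1f to %.1f", min(x$sites$Lat),
                             max(x$sites$Lat)),
      "| chemical subset:", sum(x$sites$chem_subset), "sites\n")
  invisible(x)
}

#' Reconstruction timestamps of the ice-history tables (ka before present)
#' @return numeric vector of the nine timestamps.
#' @export
ice_timestamps <- function() c(35, 30, 25, 20, 15, 13, 10, 5, 0.2)
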