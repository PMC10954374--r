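# CSV I/O for the three tabular schemas (sites, community, ice history).
# "CE" is accepted as an alias of "EC" (electrical conductivity), and
# below-detection values written as "<DL" are parsed into the detection
# limit plus a companion logical flag column.

.numeric_site_cols <- c("Lat", "Lon", "Elev", "T_mean", "T_max", "T_min",
                        "T_sd", "T_insitu", "pH", "EC", "Osat", "Ca", "TP",
                        "SiO2", "Vel", "depth", "Cel_den", "richness",
                        "Glac", "Fglac", "NLR")

#' Load a site table
#'
#' Reads the sites CSV, maps the `CE` header alias to `EC`, and parses
#' below-detection notation: a cell `"<0.1"` becomes the value 0.1 with a
#' companion logical column `<var>_bdl` set to `TRUE` (feed these to
#' [substitute_below_detection()]). Unparseable cells become `NA` and are
#' reported with their row numbers in a warning.
#'
#' @param path CSV file with a header and a unique `site_id` column.
#' @return data.frame.
#' @export
load_sites <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"site_id" %in% names(df)) stop("sites CSV needs a site_id column")
  if (anyDuplicated(df$site_id)) stop("duplicate site ids")
  names(df)[names(df) == "CE"] <- "EC"
  for (v in intersect(.numeric_site_cols, names(df))) {
    x <- df[[v]]
    if (is.numeric(x)) next
    x <- trimws(as.character(x))
    bdl <- grepl("^<", x)
    clean <- sub("^<", "", x)
    num <- suppressWarnings(as.numeric(clean))
    bad <- which(!is.na(clean) & clean != "" & is.na(num))
    if (length(bad))
      warning(sprintf("column %s: unparseable value(s) at row(s) %s", v,
                      paste(head(bad, 10), collapse = ", ")))
    df[[v]] <- num
    if (any(bdl)) df[[paste0(v, "_bdl")]] <- bdl
  }
  df
}

#' Load a community matrix
#'
#' Sites x species CSV, first column the site id; cells must be nonnegative
#' integers. Species (column) order is preserved.
#'
#' @param path CSV file.
#' @param sites optional site table; ids must match.
#' @return integer matrix with site ids as rownames.
#' @export
load_community <- function(path, sites = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) stop("duplicate site ids in community matrix")
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("community matrix cells must be numeric")
  if (any(m < 0)) stop("negative counts in community matrix")
  storage.mode(m) <- "integer"
  rownames(m) <- ids
  if (!is.null(sites)) {
    missing_ids <- setdiff(ids, sites$site_id)
    if (length(missing_ids))
      stop("community sites absent from sites table: ",
           paste(head(missing_ids, 5), collapse = ", "))
  }
  m
}

#' Load an ice-history table
#'
#' @param path CSV with `site_id` and nine binary `ice_<ka>` columns.
#' @return data.frame validated for the nine-timestamp binary schema.
#' @export
load_ice <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"site_id" %in% names(df)) stop("ice CSV needs a site_id column")
  .ice_presence(df) # validates
  df
}

#' Write a community matrix as CSV
#' @param matrix community matrix with site rownames.
#' @param path output path.
#' @export
write_community <- function(matrix, path) {
  df <- data.frame(site_id = rownames(matrix), matrix, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE)
}

#' Write the synthetic dataset's three CSV files
#'
#' @param dataset a `diatom_simulation` from [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return invisibly, the three file paths.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "diatom_simulation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("sites.csv", "community.csv", "ice.csv"))
  write.csv(dataset$sites, paths[1], row.names = FALSE)
  write_community(dataset$community, paths[2])
  write.csv(dataset$ice, paths[3], row.names = FALSE)
  invisible(paths)
}
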