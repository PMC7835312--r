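#' @useDynLib funbeta, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats aggregate aov as.dist coef cophenetic cor dist hclust
#'   lm median pf predict rmultinom rnorm runif sd setNames TukeyHSD var
#' @importFrom utils read.csv write.csv
NULL

## Closed trait vocabularies. `peduncle_type` refines `attachment` and is
## "not-applicable" exactly when a species is not pedunculate.
TRAIT_LEVELS <- list(
  size          = c("large", "small"),
  mobility      = c("mobile", "non-mobile"),
  attachment    = c("adnate", "pedunculate", "non-attached"),
  peduncle_type = c("pad", "stalk", "not-applicable"),
  colonization  = c("colonial", "non-colonial"),
  growth_form   = c("low-profile", "high-profile", "motile", "planktonic"),
  nitrogen_fixation = c("fixer", "non-fixer")
)

#' Validate a site-by-species abundance matrix
#'
#' Communities are held as a plain numeric matrix with sites as rows (row
#' order encodes the sampling gradient; site 1 is the reference for
#' distance-decay analyses) and species as columns. Entries are counts of
#' identified valves.
#'
#' @param x matrix or data.frame of non-negative counts, sites x species.
#' @param drop_empty_species drop species columns with no occurrences
#'   (default TRUE, with a message).
#' @return validated numeric matrix with dimnames.
#' @export
as_community_matrix <- function(x, drop_empty_species = TRUE) {
  m <- as.matrix(x)
  storage.mode(m) <- "double"
  if (is.null(rownames(m))) rownames(m) <- paste0("site", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("sp", seq_len(ncol(m)))
  rownames(m) <- trimws(rownames(m))
  colnames(m) <- trimws(colnames(m))
  if (anyDuplicated(rownames(m))) stop("duplicate site identifiers")
  if (anyDuplicated(colnames(m))) stop("duplicate species identifiers")
  if (anyNA(m)) stop("missing values in community matrix")
  if (any(m < 0)) stop("negative counts in community matrix")
  empty <- colSums(m) == 0
  if (any(empty)) {
    if (!drop_empty_species)
      stop("species with no occurrences: ", paste(colnames(m)[empty], collapse = ", "))
    message("dropping ", sum(empty), " species with no occurrences")
    m <- m[, !empty, drop = FALSE]
  }
  m
}

#' Validate a species-by-trait table
#'
#' Seven categorical trait variables describe each species: cell size
#' (biovolume class), mobility, attachment mode, peduncle type (pad/stalk,
#' applicable only to pedunculate species), coloniality, growth form and
#' nitrogen fixation. Category labels must come from the closed vocabularies
#' in `TRAIT_LEVELS`.
#'
#' @param x data.frame with species as rows (rownames or a `species` column)
#'   and the seven trait variables as columns.
#' @return data.frame of factors with species rownames.
#' @export
as_trait_table <- function(x) {
  x <- as.data.frame(x)
  if ("species" %in% names(x)) {
    rownames(x) <- trimws(as.character(x$species))
    x$species <- NULL
  }
  rownames(x) <- trimws(rownames(x))
  if (anyDuplicated(rownames(x))) stop("duplicate species identifiers in trait table")
  missing_vars <- setdiff(names(TRAIT_LEVELS), names(x))
  if (length(missing_vars))
    stop("trait table lacks variables: ", paste(missing_vars, collapse = ", "))
  x <- x[names(TRAIT_LEVELS)]
  for (v in names(TRAIT_LEVELS)) {
    vals <- trimws(as.character(x[[v]]))
    bad <- !vals %in% TRAIT_LEVELS[[v]]
    if (any(bad))
      stop("invalid '", v, "' categories: ",
           paste(unique(vals[bad]), collapse = ", "))
    x[[v]] <- factor(vals, levels = TRAIT_LEVELS[[v]])
  }
  if (anyNA(x)) stop("missing trait values")
  ped <- x$attachment == "pedunculate"
  if (any(ped & x$peduncle_type == "not-applicable"))
    stop("pedunculate species must have peduncle_type pad or stalk: ",
         paste(rownames(x)[ped & x$peduncle_type == "not-applicable"], collapse = ", "))
  if (any(!ped & x$peduncle_type != "not-applicable"))
    stop("non-pedunculate species must have peduncle_type not-applicable: ",
         paste(rownames(x)[!ped & x$peduncle_type != "not-applicable"], collapse = ", "))
  x
}

#' Validate a site-by-environment table
#'
#' @param x data.frame, sites as rows; numeric environmental variables as
#'   columns. A `distance_from_site1` column (km) or `lon`/`lat` coordinate
#'   columns carry the geography.
#' @return data.frame with a `log10_vars` attribute (initially empty) that
#'   records which variables have been log10-transformed.
#' @export
as_environment_table <- function(x) {
  x <- as.data.frame(x)
  if ("site" %in% names(x)) {
    rownames(x) <- trimws(as.character(x$site))
    x$site <- NULL
  }
  rownames(x) <- trimws(rownames(x))
  if (anyDuplicated(rownames(x))) stop("duplicate site identifiers in environment table")
  num <- vapply(x, is.numeric, logical(1))
  if (!all(num)) stop("non-numeric environment columns: ",
                      paste(names(x)[!num], collapse = ", "))
  if (anyNA(x)) stop("missing values in environment table")
  if (is.null(attr(x, "log10_vars"))) attr(x, "log10_vars") <- character(0)
  x
}

read_table_any <- function(path, format = NULL, sheet = 1) {
  if (is.null(format))
    format <- switch(tolower(tools::file_ext(path)),
                     csv = "csv", tsv = "tsv", txt = "tsv", xlsx = "xlsx",
                     stop("cannot infer format of ", path))
  switch(format,
    csv  = read.csv(path, check.names = FALSE, row.names = 1),
    tsv  = read.csv(path, sep = "\t", check.names = FALSE, row.names = 1),
    xlsx = {
      if (!requireNamespace("readxl", quietly = TRUE))
        stop("reading xlsx requires the readxl package")
      d <- as.data.frame(readxl::read_excel(path, sheet = sheet))
      rownames(d) <- as.character(d[[1]])
      d[-1]
    },
    stop("unknown format: ", format))
}

#' Read and cross-validate the three input tables
#'
#' Reads the community, trait and environment tables, validates each,
#' intersects their identifier sets (sites between community and environment,
#' species between community and traits) and reports anything dropped.
#' Identifier matching is exact after whitespace trimming. A community table
#' supplied species-by-sites is auto-detected through identifier overlap with
#' the trait table and transposed with a warning.
#'
#' @param community,traits,environment file paths (csv, tsv or xlsx; format
#'   inferred from the extension).
#' @return list with elements `community` (matrix), `traits` (data.frame),
#'   `environment` (data.frame) and `report` (dropped/unmatched identifiers).
#' @export
read_tables <- function(community, traits, environment) {
  cm_raw <- read_table_any(community)
  tt <- as_trait_table(read_table_any(traits))
  env <- as_environment_table(read_table_any(environment))

  sp_in_cols <- mean(trimws(colnames(cm_raw)) %in% rownames(tt))
  sp_in_rows <- mean(trimws(rownames(cm_raw)) %in% rownames(tt))
  if (sp_in_rows > sp_in_cols) {
    warning("community table appears transposed (species as rows); transposing")
    cm_raw <- as.data.frame(t(as.matrix(cm_raw)))
  }
  cm <- as_community_matrix(cm_raw)

  missing_traits <- setdiff(colnames(cm), rownames(tt))
  if (length(missing_traits))
    stop("species present in community but absent from traits: ",
         paste(missing_traits, collapse = ", "))
  extra_traits <- setdiff(rownames(tt), colnames(cm))

  sites <- intersect(rownames(cm), rownames(env))
  dropped_cm_sites  <- setdiff(rownames(cm), sites)
  dropped_env_sites <- setdiff(rownames(env), sites)
  if (length(sites) < 2) stop("fewer than 2 sites shared by community and environment")
  ## keep the community's site order: it encodes the gradient
  sites <- rownames(cm)[rownames(cm) %in% sites]

  cm <- cm[sites, , drop = FALSE]
  lv <- attr(env, "log10_vars")
  env <- env[sites, , drop = FALSE]
  attr(env, "log10_vars") <- lv
  tt <- tt[colnames(cm), , drop = FALSE]

  list(community = cm, traits = tt, environment = env,
       report = list(unused_trait_species = extra_traits,
                     dropped_community_sites = dropped_cm_sites,
                     dropped_environment_sites = dropped_env_sites))
}

#' Expand species traits into site-level trait-category abundances
#'
#' For every category of every trait variable, sums the valve counts of the
#' species carrying that category at each site. Column order is fixed:
#' variables in the canonical order of `TRAIT_LEVELS`, categories in their
#' declared level order, named `"variable:category"`. For trait variables
#' without a not-applicable level, the category columns at a site sum to the
#' site's total count.
#'
#' @param cm community matrix (sites x species counts).
#' @param tt trait table for the same species.
#' @param drop_na drop `"peduncle_type:not-applicable"`-style columns
#'   (default TRUE): not-applicable is the absence of a trait state, not a
#'   functional category.
#' @return sites x trait-category abundance matrix.
#' @export
expand_traits <- function(cm, tt, drop_na = TRUE) {
  tt <- as_trait_table(tt)
  if (!all(colnames(cm) %in% rownames(tt)))
    stop("species missing from trait table: ",
         paste(setdiff(colnames(cm), rownames(tt)), collapse = ", "))
  tt <- tt[colnames(cm), , drop = FALSE]
  cols <- list()
  for (v in names(TRAIT_LEVELS)) {
    for (lev in TRAIT_LEVELS[[v]]) {
      if (drop_na && lev == "not-applicable") next
      carriers <- tt[[v]] == lev
      cols[[paste0(v, ":", lev)]] <- as.vector(cm %*% as.numeric(carriers))
    }
  }
  out <- do.call(cbind, cols)
  rownames(out) <- rownames(cm)
  out
}

#' Write analysis outputs with a reproducibility manifest
#'
#' Writes each element of `tables` as a CSV into `dir` and a `manifest.json`
#' recording the seed, parameters and package version.
#'
#' @param tables named list of data.frames/matrices.
#' @param dir output directory (created if needed).
#' @param seed,params recorded in the manifest.
#' @return invisibly, the manifest list.
#' @export
write_outputs <- function(tables, dir, seed = NULL, params = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(tables))
    write.csv(as.data.frame(tables[[nm]]), file.path(dir, paste0(nm, ".csv")),
              row.names = TRUE)
  manifest <- list(
    package = "funbeta",
    version = as.character(utils::packageVersion("funbeta")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    seed = seed, params = params, files = paste0(names(tables), ".csv"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
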