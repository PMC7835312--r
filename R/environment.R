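#' Log10-transform skewed environmental variables
#'
#' Replaces the listed columns by their log10 values and records them in the
#' table's `log10_vars` attribute. Zero or negative values are an error
#' unless an explicit offset is opted into, in which case log10(x + offset)
#' is used and a message is logged.
#'
#' @param env environment table.
#' @param variables character vector of column names to transform.
#' @param offset optional positive constant added before the log (opt-in for
#'   variables containing zeros, e.g. salinity 0 at a river site).
#' @return transformed environment table with updated metadata.
#' @export
log10_transform <- function(env, variables, offset = NULL) {
  env <- as_environment_table(env)
  bad <- setdiff(variables, names(env))
  if (length(bad)) stop("unknown variables: ", paste(bad, collapse = ", "))
  for (v in variables) {
    x <- env[[v]]
    if (any(x <= 0)) {
      if (is.null(offset))
        stop("variable '", v, "' has zero or negative values; ",
             "supply a positive `offset` to use log10(x + offset)")
      if (offset <= 0) stop("offset must be positive")
      message("log10_transform: applying offset ", offset, " to '", v, "'")
      x <- x + offset
    }
    env[[v]] <- log10(x)
  }
  attr(env, "log10_vars") <- union(attr(env, "log10_vars"), variables)
  env
}

#' Screen environmental predictors for collinearity
#'
#' Pairwise Pearson correlations between all variables; the screen passes
#' when every off-diagonal |r| is at or below the threshold, the criterion
#' under which all predictors are retained for dissimilarity modelling.
#'
#' @param env environment table (numeric columns only are used).
#' @param threshold maximum tolerated absolute pairwise correlation
#'   (default 0.7).
#' @param exclude columns ignored by the screen (default
#'   `distance_from_site1`, `lon`, `lat`: geography is not a predictor).
#' @return list with the correlation matrix `r`, `max_abs_r`, logical
#'   `pass`, and `message` describing any failure.
#' @export
pearson_screen <- function(env, threshold = 0.7,
                           exclude = c("distance_from_site1", "lon", "lat")) {
  env <- as_environment_table(env)
  x <- env[setdiff(names(env), exclude)]
  if (nrow(x) < 3) stop("pearson_screen needs at least 3 sites")
  constant <- vapply(x, function(col) sd(col) == 0, logical(1))
  r <- suppressWarnings(cor(x, method = "pearson"))
  off <- abs(r[upper.tri(r)])
  max_r <- if (all(is.na(off))) NA_real_ else max(off, na.rm = TRUE)
  msg <- NULL
  pass <- !anyNA(off) && max_r <= threshold
  if (any(constant))
    msg <- paste0("constant columns (correlation undefined): ",
                  paste(names(x)[constant], collapse = ", "))
  else if (!pass)
    msg <- paste0("max |r| = ", format(max_r), " exceeds ", threshold)
  list(r = r, max_abs_r = max_r, pass = pass, threshold = threshold,
       message = msg)
}

#' Standardize variables to the unit interval
#'
#' (x - min) / (max - min) per column, used to overlay variables with
#' different units in gradient plots.
#'
#' @param env environment table.
#' @param exclude columns left untouched.
#' @return environment table with listed columns rescaled to span 0..1.
#' @export
standardize_01 <- function(env, exclude = c("distance_from_site1", "lon", "lat")) {
  env <- as_environment_table(env)
  for (v in setdiff(names(env), exclude)) {
    rng <- range(env[[v]])
    if (diff(rng) == 0) stop("constant column: ", v)
    env[[v]] <- (env[[v]] - rng[1]) / diff(rng)
  }
  env
}

#' Environmental heterogeneity between site pairs
#'
#' Each variable is z-scored (mean 0, sample sd with n - 1 denominator) and
#' heterogeneity is the Euclidean distance between the scaled site vectors.
#'
#' @param env environment table, already transformed as desired.
#' @param exclude columns not entering the distance (default geography).
#' @return symmetric site x site distance matrix with zero diagonal.
#' @export
env_heterogeneity <- function(env, exclude = c("distance_from_site1", "lon", "lat")) {
  env <- as_environment_table(env)
  x <- as.matrix(env[setdiff(names(env), exclude)])
  if (nrow(x) < 2) stop("need at least 2 sites")
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) stop("constant column(s): ",
                          paste(colnames(x)[sds == 0], collapse = ", "))
  z <- scale(x)
  d <- as.matrix(dist(z, method = "euclidean"))
  dimnames(d) <- list(rownames(x), rownames(x))
  d
}

#' Geographic distance from the reference site
#'
#' Uses the `distance_from_site1` column when present; otherwise great-circle
#' (haversine, Earth radius 6371 km) distances computed from `lon`/`lat`.
#'
#' @param env environment table.
#' @return list with `from_site1` (km vector, named by site) and `pairwise`
#'   (full km matrix; from coordinates only, or differences of the linear
#'   distance column otherwise).
#' @export
geo_distance <- function(env) {
  env <- as_environment_table(env)
  if ("distance_from_site1" %in% names(env)) {
    d1 <- setNames(env$distance_from_site1, rownames(env))
    pw <- abs(outer(d1, d1, "-"))
    return(list(from_site1 = d1, pairwise = pw))
  }
  if (all(c("lon", "lat") %in% names(env))) {
    coords <- as.matrix(env[c("lon", "lat")])
    n <- nrow(coords)
    pw <- matrix(0, n, n, dimnames = list(rownames(env), rownames(env)))
    for (i in seq_len(n))
      pw[i, ] <- geosphere::distHaversine(coords[i, ], coords, r = 6371) # km
    return(list(from_site1 = pw[1, ], pairwise = pw))
  }
  stop("environment table has neither distance_from_site1 nor lon/lat")
}
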