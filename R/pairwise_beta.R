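#' Shared and unique abundance components of two profiles
#'
#' The abundance components A = sum(min(x, y)) (shared), B = sum(x - min)
#' (unique to the first profile) and C = sum(y - min) (unique to the second),
#' together with their presence-absence analogues a, b, c (shared and unique
#' species counts). All abundance-based pairwise indices in the package are
#' ratios of these.
#'
#' @param x,y non-negative abundance profiles of equal length.
#' @return named list A, B, C, a, b, c.
#' @export
pairwise_components <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (any(x < 0) || any(y < 0)) stop("negative abundances")
  m <- pmin(x, y)
  px <- x > 0; py <- y > 0
  list(A = sum(m), B = sum(x - m), C = sum(y - m),
       a = sum(px & py), b = sum(px & !py), c = sum(!px & py))
}

#' Bray-Curtis similarity
#'
#' 2A / (sum(x) + sum(y)): the abundance generalization of Sorensen
#' similarity, 1 for identical profiles and 0 for profiles with no shared
#' species.
#'
#' @param x,y non-negative abundance profiles of equal length, not both
#'   all-zero.
#' @return similarity in \[0, 1\].
#' @export
bray_curtis_similarity <- function(x, y) {
  tot <- sum(x) + sum(y)
  if (tot == 0) stop("both profiles are all-zero; similarity undefined")
  if (any(x < 0) || any(y < 0)) stop("negative abundances")
  2 * sum(pmin(x, y)) / tot
}

#' Simpson similarity
#'
#' 1 - min(b, c) / (a + min(b, c)) on presence-absence data: insensitive to
#' richness differences, so a community nested in another scores 1.
#' Abundance profiles are binarized at > 0.
#'
#' @param x,y profiles (binarized internally), each with at least one
#'   presence.
#' @return similarity in \[0, 1\].
#' @export
simpson_similarity <- function(x, y) {
  pc <- pairwise_components(as.numeric(x > 0), as.numeric(y > 0))
  if (pc$a + pc$b == 0 || pc$a + pc$c == 0)
    stop("a profile with zero presences; similarity undefined")
  1 - min(pc$b, pc$c) / (pc$a + min(pc$b, pc$c))
}

#' Sorensen-family abundance partition of pairwise beta diversity
#'
#' Total dissimilarity (B + C) / (2A + B + C) split exactly into a
#' replacement component 2 min(B, C) / (2A + B + C) (balanced abundance
#' exchange) and a richness-difference component |B - C| / (2A + B + C)
#' (abundance-gradient surplus). The complement of the total is the
#' Bray-Curtis similarity.
#'
#' @param x,y non-negative abundance profiles, not both all-zero. Components
#'   A, B, C may also be supplied directly via `components`.
#' @param components optional list with elements A, B, C overriding x, y
#'   (used by the tree-based functional variant).
#' @return named list beta_total, beta_repl, beta_rich, similarity.
#' @export
sorensen_abundance_partition <- function(x, y, components = NULL) {
  pc <- if (is.null(components)) pairwise_components(x, y) else components
  denom <- 2 * pc$A + pc$B + pc$C
  if (denom == 0) stop("both profiles are all-zero; partition undefined")
  beta_total <- (pc$B + pc$C) / denom
  beta_repl  <- 2 * min(pc$B, pc$C) / denom
  beta_rich  <- abs(pc$B - pc$C) / denom
  list(beta_total = beta_total, beta_repl = beta_repl,
       beta_rich = beta_rich, similarity = 1 - beta_total)
}

#' Species present at more than half of the sites
#'
#' The "widely distributed" (dominant) species: occupancy strictly greater
#' than n/2 sites.
#'
#' @param cm community matrix.
#' @return character vector of species names.
#' @export
dominant_species <- function(cm) {
  occ <- colSums(cm > 0)
  colnames(cm)[occ > nrow(cm) / 2]
}

apply_species_filter <- function(cm, species_filter = "all", k = 8, seed = NULL) {
  if (is.character(species_filter) && length(species_filter) == 1 &&
      species_filter %in% c("all", "dominant", "random_subset")) {
    keep <- switch(species_filter,
      all      = colnames(cm),
      dominant = dominant_species(cm),
      random_subset = {
        if (!is.null(seed)) {
          old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
          on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
          set.seed(seed)
        }
        sample(colnames(cm), k)
      })
  } else keep <- intersect(species_filter, colnames(cm))
  if (length(keep) < 1) stop("species filter retained no species")
  cm[, keep, drop = FALSE]
}

#' Similarity of every site to the reference site
#'
#' Similarity between site 1 (the head of the gradient) and each site in
#' turn, optionally after restricting to dominant species (occupancy > 50%
#' of sites) or a random subset of k species.
#'
#' @param x sites x species (or sites x trait-category) abundance matrix.
#' @param index `"bray_curtis"` or `"simpson"`.
#' @param species_filter `"all"`, `"dominant"`, `"random_subset"`, or an
#'   explicit character vector of column names.
#' @param k,seed size and seed of the random subset.
#' @param reference row index or name of the reference site (default 1).
#' @return named numeric vector of similarities (NA, with a warning, where a
#'   filtered profile is empty).
#' @export
similarity_to_site1 <- function(x, index = c("bray_curtis", "simpson"),
                                species_filter = "all", k = 8, seed = NULL,
                                reference = 1) {
  index <- match.arg(index)
  f <- switch(index, bray_curtis = bray_curtis_similarity,
              simpson = simpson_similarity)
  m <- apply_species_filter(x, species_filter, k = k, seed = seed)
  ref <- m[reference, ]
  out <- rep(NA_real_, nrow(m))
  names(out) <- rownames(m)
  for (j in seq_len(nrow(m))) {
    out[j] <- tryCatch(f(ref, m[j, ]), error = function(e) NA_real_)
  }
  if (anyNA(out))
    warning("similarity undefined for site(s): ",
            paste(names(out)[is.na(out)], collapse = ", "))
  out
}

#' Pairwise similarity matrix over all site pairs
#'
#' @param x sites x species (or trait-category) abundance matrix.
#' @param index `"bray_curtis"`, `"simpson"`, or `"sorensen_abundance"`
#'   (the partition's similarity, identical to Bray-Curtis).
#' @return symmetric similarity matrix with unit diagonal.
#' @export
pairwise_matrix <- function(x, index = c("bray_curtis", "simpson",
                                         "sorensen_abundance")) {
  index <- match.arg(index)
  x <- as.matrix(x)
  n <- nrow(x)
  if (index %in% c("bray_curtis", "sorensen_abundance")) {
    s <- pair_bray_matrix(x)  # Rcpp kernel
  } else {
    s <- diag(1, n)
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      s[i, j] <- s[j, i] <- simpson_similarity(x[i, ], x[j, ])
  }
  dimnames(s) <- list(rownames(x), rownames(x))
  s
}

#' Mean, minimum and maximum off-diagonal similarity
#'
#' @param s similarity matrix from [pairwise_matrix()].
#' @return named vector mean, min, max over the n(n-1)/2 site pairs.
#' @export
similarity_summary <- function(s) {
  v <- s[upper.tri(s)]
  c(mean = mean(v), min = min(v), max = max(v))
}
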