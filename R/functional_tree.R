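#' Gower distance between species trait profiles
#'
#' For categorical traits the Gower distance between two species is the
#' fraction of applicable trait variables on which they differ. A variable
#' is inapplicable to a pair when either species carries its
#' `"not-applicable"` level (e.g. peduncle type for species that are not
#' pedunculate); such variables are excluded from numerator and denominator
#' for that pair.
#'
#' @param tt trait table (validated by [as_trait_table()]).
#' @return symmetric species x species distance matrix in \[0, 1\].
#' @export
gower_distance <- function(tt) {
  tt <- as_trait_table(tt)
  n <- nrow(tt)
  mism <- matrix(0, n, n)
  appl <- matrix(0, n, n)
  for (v in names(tt)) {
    codes <- as.integer(tt[[v]])
    ok <- as.numeric(tt[[v]] != "not-applicable")
    pair_ok <- outer(ok, ok)               # 1 iff applicable to both
    diff <- outer(codes, codes, "!=") * pair_ok
    mism <- mism + diff
    appl <- appl + pair_ok
  }
  if (any(appl == 0 & upper.tri(appl)))
    stop("species pair(s) with no applicable trait variables")
  d <- mism / appl
  diag(d) <- 0
  dimnames(d) <- list(rownames(tt), rownames(tt))
  d
}

#' Build an ultrametric functional dendrogram
#'
#' UPGMA (average-linkage) clustering of the species distance matrix. Node
#' heights are half the cophenetic distance, so the path length between two
#' leaves equals their distance. Leaves are pre-sorted lexicographically so
#' tie-breaking is deterministic.
#'
#' @param d species x species distance matrix (e.g. [gower_distance()]).
#' @param linkage only `"upgma"` is supported.
#' @return object of class `functional_tree` with elements `hclust`,
#'   `labels`, `heights` (per internal node), `branch_lengths` (2n - 2
#'   edges), and `incidence` (species x branch 0/1 membership matrix: which
#'   leaves descend through each branch).
#' @export
build_tree <- function(d, linkage = "upgma") {
  linkage <- match.arg(linkage, "upgma")
  d <- as.matrix(d)
  if (anyNA(d)) stop("NaN/NA distances")
  n <- nrow(d)
  if (n < 2) stop("need at least 2 species")
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("sp", seq_len(n))
  ord <- order(rownames(d))
  d <- d[ord, ord]
  hc <- hclust(as.dist(d), method = "average")
  labels <- hc$labels
  heights <- hc$height / 2              # merge height = half cophenetic distance

  ## nodes: 1..n leaves (height 0), n+k internal node for merge row k
  n_br <- 2 * n - 2
  lengths <- numeric(n_br)              # branch above each non-root node
  inc <- matrix(0, n, n_br, dimnames = list(labels, NULL))
  node_height <- c(rep(0, n), heights)
  members <- vector("list", n - 1)
  for (k in seq_len(n - 1)) {
    kids <- hc$merge[k, ]
    memb <- integer(0)
    for (child in kids) {
      node_id <- if (child < 0) -child else n + child
      memb <- c(memb, if (child < 0) -child else members[[child]])
      if (node_id <= n_br) {            # root (node 2n-1) carries no branch
        lengths[node_id] <- heights[k] - node_height[node_id]
      }
    }
    members[[k]] <- memb
    if (n + k <= n_br) inc[memb, n + k] <- 1
  }
  inc[cbind(seq_len(n), seq_len(n))] <- 1      # leaf branches
  structure(list(hclust = hc, labels = labels, heights = heights,
                 branch_lengths = lengths, incidence = inc),
            class = "functional_tree")
}

#' @export
print.functional_tree <- function(x, ...) {
  cat("Functional dendrogram (UPGMA): ", length(x$labels), " species, ",
      "total branch length ", format(sum(x$branch_lengths), digits = 4),
      ", root height ", format(max(c(0, x$heights)), digits = 4), "\n", sep = "")
  invisible(x)
}

#' Functional tree from a trait table
#'
#' Convenience wrapper: Gower distance then UPGMA.
#' @param tt trait table; `subset` optional species names to restrict to.
#' @return `functional_tree`.
#' @export
functional_tree <- function(tt, subset = NULL) {
  tt <- as_trait_table(tt)
  if (!is.null(subset)) {
    if (length(subset) < 2) stop("subset must contain at least 2 species")
    tt <- tt[subset, , drop = FALSE]
  }
  build_tree(gower_distance(tt))
}

#' Prune a functional tree to a species subset
#'
#' Rebuilds the dendrogram from the subset's cophenetic distances; for an
#' ultrametric tree this preserves all remaining pairwise cophenetic
#' distances exactly.
#'
#' @param tree `functional_tree`; `subset` species names (>= 2).
#' @return `functional_tree` over the subset.
#' @export
prune_tree <- function(tree, subset) {
  if (length(subset) < 2) stop("subset must contain at least 2 species")
  d <- as.matrix(cophenetic(tree$hclust))
  build_tree(d[subset, subset])
}

#' Export a functional tree as Newick
#'
#' @param tree `functional_tree`; `file` optional path (returns the string
#'   invisibly when writing).
#' @return Newick string.
#' @export
tree_newick <- function(tree, file = NULL) {
  phy <- ape::as.phylo(tree$hclust)
  if (is.null(file)) ape::write.tree(phy)
  else { ape::write.tree(phy, file = file); invisible(ape::write.tree(phy)) }
}

## Sites x branches abundance matrix, columns scaled by branch length, so
## that Bray-Curtis components on it are the length-weighted tree components.
branch_abundance <- function(x, tree, weight = TRUE) {
  x <- as.matrix(x)
  missing <- setdiff(colnames(x), tree$labels)
  if (length(missing))
    stop("species missing from tree: ", paste(missing, collapse = ", "))
  m <- x[, tree$labels, drop = FALSE] %*% tree$incidence
  if (weight) m <- sweep(m, 2, tree$branch_lengths, "*")
  m
}

#' Tree-based functional beta diversity between two communities
#'
#' Every branch of the functional dendrogram carries, per community, the
#' summed abundance of the leaves descending through it. The shared
#' component A is the length-weighted sum of branch-wise minima, B and C the
#' length-weighted abundances unique to each community, and the
#' Sorensen-family partition of [sorensen_abundance_partition()] is applied
#' to (A, B, C). On a star tree with equal branch lengths this reduces
#' exactly to the taxonomic partition. If the tree has zero total branch
#' length (all species functionally identical) the communities form a single
#' functional unit and the partition falls back to total abundances.
#'
#' @param x,y abundance profiles named by (or ordered as) the tree's leaves.
#' @param tree `functional_tree`.
#' @return named list beta_total, beta_repl, beta_rich, similarity.
#' @export
tree_beta <- function(x, y, tree) {
  if (is.null(names(x))) names(x) <- tree$labels
  if (is.null(names(y))) names(y) <- tree$labels
  m <- branch_abundance(rbind(x, y), tree)
  if (sum(tree$branch_lengths) == 0)
    return(sorensen_abundance_partition(sum(x), sum(y)))
  pc <- list(A = sum(pmin(m[1, ], m[2, ])))
  pc$B <- sum(m[1, ]) - pc$A
  pc$C <- sum(m[2, ]) - pc$A
  sorensen_abundance_partition(components = pc)
}

#' Site-by-site functional similarity matrix
#'
#' Tree-based Sorensen-with-abundance similarity over all site pairs. The
#' dendrogram is rebuilt from the trait rows of the species subset in use
#' (set `rebuild = FALSE` to prune the full tree instead, for sensitivity
#' analysis).
#'
#' @param cm community matrix; `tt` trait table; `subset` optional species
#'   subset (>= 2).
#' @param rebuild rebuild the tree from subset traits (default) or prune.
#' @param tree optionally, a precomputed full `functional_tree` (used when
#'   `rebuild = FALSE` or `subset` is NULL, avoiding reclustering).
#' @return symmetric similarity matrix with unit diagonal.
#' @export
functional_similarity_matrix <- function(cm, tt, subset = NULL,
                                         rebuild = TRUE, tree = NULL) {
  if (!is.null(subset)) {
    if (length(subset) < 2) stop("subset must contain at least 2 species")
    cm <- cm[, subset, drop = FALSE]
    tr <- if (rebuild) functional_tree(tt, subset = subset)
          else prune_tree(if (is.null(tree)) functional_tree(tt) else tree, subset)
  } else {
    tr <- if (is.null(tree)) functional_tree(tt, subset = colnames(cm)) else tree
  }
  if (sum(tr$branch_lengths) == 0) {
    tot <- rowSums(cm)
    s <- pair_bray_matrix(matrix(tot, ncol = 1))
  } else {
    s <- pair_bray_matrix(branch_abundance(cm, tr))
  }
  dimnames(s) <- list(rownames(cm), rownames(cm))
  s
}
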