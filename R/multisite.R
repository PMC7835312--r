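#' Multiple-site Sorensen beta diversity partitioned into turnover and
#' nestedness
#'
#' Over all sites jointly, with S_i the richness of site i, S_T the pooled
#' richness and, for each ordered site pair, b_ij the number of units present
#' in i but not in j:
#'
#' * beta_SIM (turnover, multiple-site Simpson) =
#'   sum min(b_ij, b_ji) / (sum_i S_i - S_T + sum min(b_ij, b_ji))
#' * beta_SOR (overall Sorensen) = (sum min + sum max) /
#'   (2 (sum_i S_i - S_T) + sum min + sum max)
#' * beta_SNE (nestedness-resultant) = beta_SOR - beta_SIM
#'
#' with sums over unordered pairs i < j. The turnover fraction is
#' beta_SIM / beta_SOR and the nestedness fraction beta_SNE / beta_SOR;
#' they sum to one.
#'
#' @param x sites x units matrix; abundances are binarized at > 0. Units are
#'   species for the taxonomic partition or trait categories for the
#'   functional one.
#' @return object of class `multisite_partition`: beta_SOR, beta_SIM,
#'   beta_SNE, turnover_fraction, nestedness_fraction, n_sites, n_units.
#' @export
multisite_sorensen_partition <- function(x) {
  inc <- as.matrix(x) > 0
  storage.mode(inc) <- "double"
  n <- nrow(inc)
  if (n < 2) stop("need at least 2 sites")
  S_i <- rowSums(inc)
  if (any(S_i == 0))
    stop("site(s) with zero presences: ",
         paste(rownames(inc)[S_i == 0], collapse = ", "))
  S_T <- sum(colSums(inc) > 0)
  shared <- inc %*% t(inc)                 # a_ij
  b <- outer(S_i, rep(1, n)) - shared      # b_ij = S_i - a_ij
  ut <- upper.tri(b)
  bmin <- pmin(b, t(b))[ut]
  bmax <- pmax(b, t(b))[ut]
  core <- sum(S_i) - S_T
  beta_SIM <- sum(bmin) / (core + sum(bmin))
  beta_SOR <- (sum(bmin) + sum(bmax)) / (2 * core + sum(bmin) + sum(bmax))
  beta_SNE <- beta_SOR - beta_SIM
  if (beta_SOR == 0)
    message("all sites share an identical unit set (beta_SOR = 0); ",
            "turnover/nestedness fractions are undefined")
  structure(list(beta_SOR = beta_SOR, beta_SIM = beta_SIM,
                 beta_SNE = beta_SNE,
                 turnover_fraction = if (beta_SOR > 0) beta_SIM / beta_SOR else NA_real_,
                 nestedness_fraction = if (beta_SOR > 0) beta_SNE / beta_SOR else NA_real_,
                 n_sites = n, n_units = ncol(inc)),
            class = "multisite_partition")
}

#' @export
print.multisite_partition <- function(x, ...) {
  cat("Multiple-site Sorensen partition (", x$n_sites, " sites, ",
      x$n_units, " units)\n", sep = "")
  cat(sprintf("  beta_SOR = %.4f  (overall)\n", x$beta_SOR))
  cat(sprintf("  beta_SIM = %.4f  (turnover)\n", x$beta_SIM))
  cat(sprintf("  beta_SNE = %.4f  (nestedness-resultant)\n", x$beta_SNE))
  cat(sprintf("  turnover fraction   = %.1f%%\n", 100 * x$turnover_fraction))
  cat(sprintf("  nestedness fraction = %.1f%%\n", 100 * x$nestedness_fraction))
  invisible(x)
}
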