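#' Random species subset of a given percentage
#'
#' Uniform sample without replacement of round(percent/100 x S) species,
#' rounding half away from zero. Deterministic under `seed`.
#'
#' @param species_ids character vector of species names.
#' @param percent percentage in (0, 100].
#' @param seed optional integer seed (local to this draw).
#' @return character vector of sampled species names.
#' @export
subsample_species <- function(species_ids, percent, seed = NULL) {
  if (percent <= 0 || percent > 100) stop("percent must be in (0, 100]")
  S <- length(species_ids)
  size <- floor(percent / 100 * S + 0.5)   # round half away from zero
  if (size < 2) stop("subset size ", size, " is below 2")
  if (percent == 100) return(species_ids)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  sample(species_ids, size)
}

## slopes for one species subset: taxonomic (Sorensen-with-abundance, i.e.
## Bray-Curtis similarity on counts) and functional (tree-based, dendrogram
## rebuilt from the subset's traits), each regressed on heterogeneity.
## A site emptied by the subset has similarity 0 to any non-empty site;
## empty-vs-empty pairs are undefined (NA) and dropped by the regression.
subset_slopes <- function(cm, tt, E, subset, rebuild = TRUE, full_tree = NULL) {
  sub_cm <- cm[, subset, drop = FALSE]
  tax <- pairwise_matrix(sub_cm, index = "sorensen_abundance")
  fun <- functional_similarity_matrix(cm, tt, subset = subset,
                                      rebuild = rebuild, tree = full_tree)
  c(taxonomic = fit_similarity_vs_heterogeneity(tax, E)$slope,
    functional = fit_similarity_vs_heterogeneity(fun, E)$slope,
    empty_sites = sum(rowSums(sub_cm) == 0))
}

#' Species-loss resampling experiment
#'
#' Mimics species loss by randomly sampling 5-95% of the species pool,
#' `n_rep` times per level. For each replicate the community is restricted
#' to the subset (columns dropped; site totals shrink), the functional
#' dendrogram is rebuilt from the subset's traits, taxonomic
#' (Sorensen-with-abundance) and functional (tree-based) pairwise similarity
#' matrices are computed, each is regressed on environmental heterogeneity,
#' and both slopes are recorded. The 100% level is deterministic and
#' computed once. Replicate seeds derive from the master seed by the counter
#' scheme seed + 7919 * level_index + replicate, so any replicate can be
#' reproduced in isolation. A subset may leave some sites with no observed
#' individuals (common at small percentages): such a site is completely
#' dissimilar to any non-empty site, pairs of two empty sites are undefined
#' and dropped from the slope regression, and the number of affected
#' replicates is reported in `empty_site_replicates`.
#'
#' @param cm community matrix; `tt` trait table; `E` environmental
#'   heterogeneity matrix from [env_heterogeneity()].
#' @param percents subset percentages (default 5..95 by 5, plus 100).
#' @param n_rep replicates per resampled level (default 100).
#' @param seed master integer seed.
#' @param rebuild rebuild the dendrogram per subset (default) or prune the
#'   full tree.
#' @return object of class `slope_table`: `slopes` (long data.frame:
#'   percent, replicate, taxonomic, functional, empty_sites), `means`
#'   (per-percent mean slopes), `empty_site_replicates`.
#' @export
run_species_loss <- function(cm, tt, E, percents = c(seq(5, 95, by = 5), 100),
                             n_rep = 100, seed = 1, rebuild = TRUE) {
  species <- colnames(cm)
  full_tree <- if (!rebuild) functional_tree(tt, subset = species) else NULL
  rows <- list()
  for (li in seq_along(percents)) {
    pct <- percents[li]
    reps <- if (pct == 100) 1L else n_rep
    for (r in seq_len(reps)) {
      rep_seed <- seed + 7919L * li + r
      sub <- subsample_species(species, pct, seed = rep_seed)
      sl <- subset_slopes(cm, tt, E, sub, rebuild = rebuild,
                          full_tree = full_tree)
      rows[[length(rows) + 1L]] <-
        data.frame(percent = pct, replicate = r,
                   taxonomic = sl[["taxonomic"]],
                   functional = sl[["functional"]],
                   empty_sites = sl[["empty_sites"]])
    }
  }
  slopes <- do.call(rbind, rows)
  means <- aggregate(slopes[c("taxonomic", "functional")],
                     by = list(percent = slopes$percent), FUN = mean)
  means <- means[order(-means$percent), ]
  rownames(means) <- NULL
  structure(list(slopes = slopes, means = means,
                 empty_site_replicates = sum(slopes$empty_sites > 0),
                 n_rep = n_rep, seed = seed),
            class = "slope_table")
}

#' @export
print.slope_table <- function(x, ...) {
  cat("Species-loss slope table: ", nrow(x$slopes), " fits, ",
      x$n_rep, " replicates/level, ", x$empty_site_replicates,
      " replicates with emptied sites\n", sep = "")
  print(x$means, digits = 4)
  invisible(x)
}

#' Compare resampled slopes against the full community
#'
#' One-way ANOVA of the slopes across subset-percentage groups followed by
#' Tukey HSD pairwise comparisons; reports the "100 vs q" family for the
#' taxonomic and functional responses separately. The 100% model is
#' deterministic, so running it once per replicate yields identical slopes:
#' the single stored 100% slope enters the ANOVA as `n_rep` identical
#' observations, mirroring an equal-replication resampling design. Zero
#' variance everywhere gives p = 1 by convention.
#'
#' @param st `slope_table` from [run_species_loss()].
#' @return data.frame: percent, p_taxonomic, p_functional (each the Tukey
#'   adjusted p of the 100-vs-percent contrast), plus the ANOVA p values as
#'   attributes `anova_p_taxonomic`, `anova_p_functional`.
#' @export
compare_slopes <- function(st) {
  sl <- st$slopes
  if (length(unique(sl$percent)) < 2) stop("need at least 2 levels")
  full <- sl$percent == 100
  if (sum(full) == 1 && st$n_rep > 1)   # deterministic level, equal replication
    sl <- rbind(sl, sl[rep(which(full), st$n_rep - 1L), ])
  grp <- factor(sl$percent)
  one <- function(response) {
    y <- sl[[response]]
    if (all(tapply(y, grp, var, default = 0) %in% c(0, NA)) &&
        var(y) == 0) {
      message("zero variance in ", response, " slopes; p = 1 by convention")
      pcts <- setdiff(sort(unique(sl$percent), decreasing = TRUE), 100)
      return(list(p = setNames(rep(1, length(pcts)), pcts), anova_p = 1))
    }
    fit <- aov(y ~ grp)
    anova_p <- summary(fit)[[1]][["Pr(>F)"]][1]
    tk <- TukeyHSD(fit)$grp
    want <- grepl("^100-|-100$", rownames(tk))
    p <- tk[want, "p adj"]
    names(p) <- sub("-?100-?", "", rownames(tk)[want])
    list(p = p, anova_p = anova_p)
  }
  tax <- one("taxonomic"); fun <- one("functional")
  pcts <- sort(as.numeric(names(tax$p)), decreasing = TRUE)
  out <- data.frame(percent = pcts,
                    p_taxonomic = tax$p[as.character(pcts)],
                    p_functional = fun$p[as.character(pcts)])
  rownames(out) <- NULL
  attr(out, "anova_p_taxonomic") <- tax$anova_p
  attr(out, "anova_p_functional") <- fun$anova_p
  out
}

#' Onset of slope degradation under species loss
#'
#' The largest subset percentage whose slope differs significantly (Tukey
#' adjusted p below `alpha`) from the full community: the head of the
#' degradation band, e.g. a band of significant levels from 45% downwards
#' has onset 45.
#'
#' @param cmp output of [compare_slopes()].
#' @param response `"functional"` or `"taxonomic"`.
#' @param alpha significance level (default 0.05).
#' @return onset percentage, or NA if no level differs significantly.
#' @export
loss_onset_percent <- function(cmp, response = c("functional", "taxonomic"),
                               alpha = 0.05) {
  response <- match.arg(response)
  sig <- cmp$percent[cmp[[paste0("p_", response)]] < alpha]
  if (length(sig)) max(sig) else NA_real_
}
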