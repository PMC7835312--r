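---
title: "Methods: taxonomic and functional beta diversity along a gradient"
author: "funbeta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: taxonomic and functional beta diversity along a gradient}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(funbeta)
```

## Scope and data model

funbeta analyses communities of microscopic organisms (its motivating use
case is benthic diatoms) sampled at ordered sites along a strong
environmental gradient, e.g. a river-to-sea estuary transition. Three
tables drive everything:

* a **community matrix** of counts (sites x species) obtained under fixed
  counting effort (e.g. 500 identified valves per site); site order encodes
  the gradient and site 1 is the reference for distance-decay analyses;
* a **trait table** assigning each species one category of each of seven
  categorical trait variables (size class, mobility, attachment, peduncle
  type, coloniality, growth form, nitrogen fixation). Peduncle type refines
  attachment and is `not-applicable` for species that are not pedunculate —
  splitting the hierarchy into two variables avoids double-counting
  attachment in trait distances;
* an **environment table** of per-site variables (salinity, pH,
  temperature, fetch, stone volume and six nutrient measurements) plus the
  geographic distance from site 1 (or lon/lat coordinates, from which
  great-circle distances with Earth radius 6371 km are computed).

Trait abundances are obtained by `expand_traits()`: the abundance of a
trait category at a site is the summed count of the species carrying it,
so for every complete trait variable the category columns sum to the
site's counting effort.

## Environmental preprocessing

Right-skewed variables (nutrients, salinity, fetch) are log10-transformed;
zeros (e.g. salinity 0 at a river site) require an explicit offset
`log10(x + c)`, opted into via `log10_offset` and logged. Collinearity is
screened with pairwise Pearson correlations against a |r| <= 0.7 threshold;
the screen reports rather than drops, since the modelling stages tolerate
correlated predictors. **Environmental heterogeneity** between two sites is
the Euclidean distance between their z-scored (sample sd, n - 1) variable
vectors. 0-1 range standardization is provided for visual overlays only.

## Pairwise indices and their partition

All abundance-based indices are ratios of the shared component
A = sum min(x_i, y_i) and the unique components B, C. Bray-Curtis
similarity is 2A/(2A + B + C); the Sorensen-with-abundance dissimilarity
(B + C)/(2A + B + C) splits exactly into a **replacement** part
2 min(B, C)/(2A + B + C) and a **richness-difference** part
|B - C|/(2A + B + C). Simpson similarity, 1 - min(b, c)/(a + min(b, c)) on
presence-absence data, is blind to nestedness and so isolates turnover.
The reference-site series can be restricted to widely distributed
("dominant") species — occupancy strictly greater than half the sites — or
to random k-species subsets (default k = 8, seeded).

A site whose (possibly filtered) profile is empty is completely dissimilar
to any non-empty site; a pair of two empty profiles has no defined
similarity and is reported as missing rather than silently dropped.

## Multiple-site partition

Over all sites jointly, with S_i the site richnesses, S_T the pooled
richness and b_ij the number of units present in site i but not j, the
multiple-site Sorensen dissimilarity beta_SOR decomposes into the
multiple-site Simpson (turnover) component beta_SIM and the
nestedness-resultant remainder beta_SNE = beta_SOR - beta_SIM; the
turnover and nestedness fractions divide the components by beta_SOR.
Incidence is abundance binarized at > 0. The taxonomic partition uses the
species incidence matrix; the functional partition uses trait-category
incidence (categories as units), since categorical traits do not admit
hull-volume methods. When every unit occurs at every site beta_SOR is 0
and the fractions are undefined (reported as NA with a message) — this can
happen for trait categories in highly redundant communities.

## Functional dendrogram and tree-based beta diversity

Species trait distance is the categorical Gower distance: the fraction of
applicable variables on which two species differ, excluding a variable for
a pair when either species carries its not-applicable level. UPGMA
(average linkage) over this distance yields an ultrametric dendrogram;
node heights are half the cophenetic distance and leaves are pre-sorted
lexicographically so ties break deterministically.

Functional beta diversity generalizes the abundance partition to the tree:
each branch carries, per community, the summed abundance of the leaves
descending through it; A, B, C become length-weighted sums of branch-wise
minima and remainders, and the same Sorensen-family partition applies. On
a star tree (equal branch lengths, no internal structure) this reduces
exactly to the taxonomic partition, which is property-tested. When the
tree has zero total branch length (all species functionally identical)
the communities form a single functional unit and the partition falls
back to total abundances — equal-effort sites are then fully similar.

In the species-loss experiment the dendrogram is **rebuilt** from each
subset's trait rows rather than pruned from the full tree, matching the
per-community-set workflow of tree-based beta diversity; `prune_tree()`
(which preserves cophenetic distances exactly) is available for
sensitivity analysis.

## Generalized dissimilarity modelling

Pairwise compositional dissimilarity (Bray-Curtis for species counts,
range-normalized quantitative Gower for trait-category abundances) is
regressed on site-pair environmental differences through monotone
transforms: each predictor gets three order-2 I-splines with knots at its
minimum, median and maximum (the canonical default; the knot collapses to
the range midpoint under heavy ties), the linear predictor is
eta = a0 + sum a_pk |I_pk(x_i) - I_pk(x_j)| with all coefficients >= 0,
and the response curve is mu = 1 - exp(-eta). Coefficients minimize the
binomial-form deviance (0 log 0 = 0; mu clipped to (1e-9, 1 - 1e-9)) by
iteratively reweighted least squares whose inner step is non-negative
least squares, with step halving and convergence when the deviance changes
by less than 1e-8. The null model is the intercept-only fit (mu = mean
dissimilarity), and deviance explained = 100 (1 - D/D0). Geographic
distance is deliberately not a predictor: the models quantify
environmental control only.

Predictor importance permutes a predictor's **site-level** values (not
pair rows, which would break the metric structure of the pair table) 50
times, refits, and reports the mean percent drop in deviance explained;
p values are the fraction of permutations fitting at least as well as the
observed model, with the whole-model p permuting all predictors jointly.

## Distance decay and halving distance

Similarity series are fit by ordinary least squares against geographic
distance from site 1 (the identity self-pair at distance 0 is excluded by
default; a flag restores it for sensitivity) or against environmental
heterogeneity over all site pairs. Reported statistics are the slope,
adjusted R², and the two-sided F-test p value; a constant response is
reported as slope 0 with R² 0 by convention. The **halving distance** is
where the fitted similarity falls to half its 1-km value:
(S(1)/2 - intercept)/slope for the linear form. Because the original
halving-distance literature used log-linear decay, a log-linear option
(halving at 1 + ln 2/|slope|) is computed alongside; the linear form is
the default since the decay models themselves are linear.

## Species-loss resampling

To mimic species loss, p% of the species pool (p = 5, 10, ..., 95) is
sampled uniformly without replacement (size rounded half away from zero),
100 times per level by default; each replicate drops the other columns
(site totals shrink — counts are not rescaled), rebuilds the functional
dendrogram from the subset's traits, computes taxonomic and functional
pairwise similarity matrices, regresses each on environmental
heterogeneity and records both slopes. Replicate seeds derive from the
master seed by a fixed counter (seed + 7919 x level + replicate), so the
whole experiment is bit-for-bit reproducible and any single replicate can
be re-created in isolation.

Small subsets routinely leave some sites with no observed individuals: at
the 5% level this is near-certain for realistic richness, so redrawing
such replicates would discard essentially all of them and bias the level.
They are therefore retained: an empty site is completely dissimilar to any
non-empty site, empty-empty pairs are dropped from the regression, and the
count of affected replicates is reported.

Differences between levels are assessed by one-way ANOVA over the slope
groups followed by Tukey HSD, reporting the 100-vs-p family. The 100%
model is deterministic, so running it once per replicate (as the
resampling protocol prescribes) yields n_rep identical slopes; the stored
single slope accordingly enters the ANOVA as n_rep identical observations.
A singleton 100% group was tried first and rejected: its Tukey contrasts
have standard error bounded below by the pooled sd regardless of
replication, which makes the functional-degradation onsets undetectable by
construction. The **onset** of degradation for a response is the largest
subset percentage whose slope differs significantly (Tukey p < 0.05) from
the full community — the start of the degradation band.

## The community simulator

`gradient_spec()`/`simulate_dataset()` generate data with the structure
the analysis assumes, so every stage is testable without field data:

* 51 equally spaced sites along a 60-km gradient (defaults);
* 11 environmental variables with river-to-sea shapes — salinity
  (logistic, ~0 to ~6), pH, fetch and phosphate increasing; temperature,
  nitrate+nitrite, ammonium and total nitrogen decreasing; stone volume
  unimodal; silicate and total phosphorus non-monotone — plus Gaussian
  site noise of sd `env_noise_sd` (default 0.05) times each shape's range;
* a 408-species pool with Gaussian niches: optima uniform on the gradient
  extended 10 km beyond each end (avoiding edge-richness artifacts),
  widths uniform on 1-10 km, and log-normal species abundance multipliers
  (sdlog 2) creating realistic dominance structure; counts are multinomial
  with 500 valves per site, mirroring fixed counting effort. The width
  range and sdlog were calibrated once so that per-site richness falls in
  the empirically observed band (roughly 25-100 of the pool) while a few
  dozen widespread generalists remain — without the multipliers no
  parameterization achieves both, and the dominant-species filter would be
  empty;
* trait syndromes: `n_trait_syndromes` distinct trait rows (default 25,
  i.e. functional redundancy of ~16 species per syndrome); species are
  assigned round-robin in order of niche optimum so every syndrome
  persists along the whole gradient.

What the simulator does **not** emulate: phylogenetic or trait
autocorrelation between niche neighbours, biotic interactions, dispersal
limitation, temporal dynamics, and trait-environment coupling beyond what
the round-robin assignment induces incidentally. Tests passing on this
generator therefore demonstrate correctness of the computations and the
qualitative redundancy-buffering mechanism, not field realism. One
consequence worth knowing: with high redundancy every trait category tends
to occur at every site, making the functional multiple-site partition
degenerate (beta_SOR = 0) more often than in real data, where rare trait
states (e.g. planktonic forms) drop out of some sites.

## Numerical conventions

* Identifier matching is exact after whitespace trimming; a transposed
  community table is auto-detected via trait-table overlap and fixed with
  a warning.
* Degenerate fits: constant predictor columns are errors for scaling and
  splines; constant responses give slope 0/R² 0; non-negative decay slopes
  give an infinite halving distance with a warning.
* All stochastic stages take explicit integer seeds; the pipeline spawns
  per-stage seeds from one master seed by fixed offsets.

## Problem sizes used by the test-suite

The packaged checks run the full analysis on simulated data at the default
51 x 408 size for the species-loss grid and timing checks, and at reduced
sizes (20-30 sites, 80-120 species) for per-module tests; the multi-seed
qualitative checks use 20 seeds with 20 replicates per subset level. These
sizes are the package's own test design, chosen to keep the default suite
quick while exercising every code path at realistic dimensions.

## A worked example

```{r example, eval = FALSE}
sim <- simulate_dataset(gradient_spec(seed = 1))
res <- analyze_gradient(sim$community, sim$traits, sim$environment,
                        n_perm = 50, n_rep = 100, seed = 1)
print(res)
```

`print(res)` reports, in order: the dataset dimensions, the number of
dominant species, mean pairwise taxonomic and functional similarity, the
taxonomic and functional turnover fractions, halving distances, GDM
deviance explained for the species and trait responses, and the
species-loss degradation onsets. `run_pipeline()` wraps the same analysis
behind a single config list and writes tidy CSVs plus a JSON manifest.

## Known limitations

* The GDM optimizer is an IRLS/NNLS scheme with fixed 3-spline bases; it
  matches the canonical implementations in deviance terms but coefficient
  values are not comparable across optimizers, so permutation importances
  should be read as ranks.
* The functional multiple-site partition uses trait-category incidence;
  dendrogram-based multiple-site measures are out of scope, and the
  trait-incidence choice is the main source of sensitivity in the
  functional turnover fraction.
* ANOVA on slope tables inherits the usual homogeneity assumptions;
  with the deterministic 100% level entered at equal replication its
  variance contribution is zero, which is anti-conservative for the
  100-vs-p family when replicate variance differs strongly between levels.
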