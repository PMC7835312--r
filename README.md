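# funbeta

Taxonomic and functional beta diversity of microbial communities along
environmental gradients, with a species-loss resampling experiment that asks
how long functional similarity survives biodiversity loss.

## The problem

Communities sampled along a strong environmental gradient — the motivating
case is benthic diatom biofilms counted along a river-to-sea estuary
transition — typically show high **taxonomic** beta diversity: species are
replaced wholesale from one end of the gradient to the other. Whether the
**functions** those species perform turn over equally fast is a different
question: if many species share the same trait syndrome (functional
redundancy), communities can remain functionally similar while their species
lists change almost completely, and that redundancy buffers ecosystem
functioning against species loss. funbeta implements the full analysis chain
needed to quantify this, for anyone working with a site-by-species count
matrix, a species-by-trait table and per-site environmental measurements.

## What it computes

* **Pairwise indices** built from the shared/unique abundance components
  A = Σ min(xᵢ, yᵢ), B, C: Bray-Curtis similarity 2A/(2A+B+C), Simpson
  presence-absence similarity 1 − min(b,c)/(a + min(b,c)), and the
  Sørensen-with-abundance dissimilarity partitioned exactly into replacement
  2·min(B,C)/(2A+B+C) and richness-difference |B−C|/(2A+B+C).
* **Multiple-site partition**: Sørensen dissimilarity over all sites split
  into its Simpson (turnover) and nestedness-resultant components, with
  turnover/nestedness fractions β_SIM/β_SOR and β_SNE/β_SOR.
* **Functional dendrograms**: categorical Gower distance on traits
  (not-applicable levels excluded pairwise), UPGMA clustering, and
  tree-based functional beta diversity in which every branch carries the
  summed abundance of its descendant leaves and A, B, C become
  length-weighted branch sums.
* **Generalized dissimilarity models**: monotone order-2 I-spline transforms
  (knots at min/median/max), negative-exponential link
  μ = 1 − exp(−η), non-negative coefficients fitted by IRLS with an NNLS
  inner step on the binomial-form deviance, percent deviance explained, and
  permutation-based predictor importance (site-level permutation, 50
  permutations by default).
* **Distance decay**: OLS fits of similarity against km-from-site-1 or
  against environmental heterogeneity (Euclidean distance of z-scored
  variables), adjusted R², F-test p values, and the halving distance — the
  distance at which fitted similarity drops to half its 1-km value.
* **Species-loss experiment**: 5–95% random subsets of the species pool,
  100 replicates per level, taxonomic and functional
  similarity-vs-heterogeneity slopes per replicate, ANOVA + Tukey HSD
  against the full community, and the degradation onset (largest subset
  percentage whose slope differs significantly from 100%).
* **A community simulator** (Gaussian niches along the gradient, multinomial
  fixed counting effort, log-normal dominance structure, tunable functional
  redundancy via trait syndromes) so the whole pipeline is testable without
  field data.

## Worked example

```r
library(funbeta)

sim <- simulate_dataset(gradient_spec(seed = 1))   # 51 sites, 60 km, 408-species pool
res <- analyze_gradient(sim$community, sim$traits, sim$environment,
                        n_perm = 50, n_rep = 100, seed = 1)
print(res)
#> Beta-diversity analysis: 51 sites, 336 species, 17 trait categories
#>   dominant species (occupancy > 50% of sites): 25
#>   mean pairwise similarity: taxonomic 0.265, functional 0.676
#>   turnover fraction: taxonomic 99.4%, functional NA%
#>   halving distance: taxonomic 23 km, functional 210 km
#>   GDM deviance explained: species 94.52%, traits 85.63%
#>   species-loss onset: taxonomic 25%, functional 85%
```

Reading this: of the 408-species pool, 336 were observed; communities at
opposite ends of the gradient share almost no species (mean pairwise
taxonomic similarity 0.265, taxonomic beta diversity 99.4% turnover) yet
remain functionally alike (mean functional similarity 0.676) — taxonomic
similarity halves within 23 km while functional similarity would need
210 km. The functional turnover fraction is NA here because in this highly
redundant simulated community every trait category occurs at every site
(β_SOR = 0); real data, where rare trait states drop out of some sites,
gives a defined value. The onsets say random species removal significantly
steepens the functional similarity-heterogeneity slope already at 85%
retention, long before the taxonomic slope shifts (25%).

Individual stages are available as plain functions returning classed
objects with the usual methods:

```r
m <- fit_gdm(build_site_pair_table(1 - pairwise_matrix(sim$community, "bray_curtis"),
                                   log10_transform(sim$environment,
                                                   c("salinity", "fetch"), offset = 0.01)))
summary(m); plot(m); predict(m)
```

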