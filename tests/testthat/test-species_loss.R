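test_that("subsample_species rounds half away from zero and respects seeds", {
  ids <- paste0("sp", 1:408)
  expect_identical(subsample_species(ids, 100), ids)
  expect_length(subsample_species(ids, 45, seed = 1), 184)   # round(183.6)
  expect_length(subsample_species(ids, 5, seed = 1), 20)     # round(20.4)
  expect_identical(subsample_species(ids, 30, seed = 5),
                   subsample_species(ids, 30, seed = 5))
  expect_false(identical(subsample_species(ids, 30, seed = 5),
                         subsample_species(ids, 30, seed = 6)))
  expect_error(subsample_species(paste0("s", 1:10), 5), "below 2")
  expect_error(subsample_species(ids, 0), "percent")
})

test_that("species-loss experiment returns the expected structure and the 100% level is deterministic", {
  sim <- small_sim(1)
  E <- env_heterogeneity(sim$environment)
  st <- run_species_loss(sim$community, sim$traits, E,
                         percents = c(40, 70, 100), n_rep = 4, seed = 2)
  expect_s3_class(st, "slope_table")
  expect_equal(nrow(st$slopes), 4 * 2 + 1)
  expect_equal(sum(st$slopes$percent == 100), 1)

  # the 100% level equals the deterministic full-community slopes
  tax <- pairwise_matrix(sim$community, "sorensen_abundance")
  fun <- functional_similarity_matrix(sim$community, sim$traits)
  full_tax <- fit_similarity_vs_heterogeneity(tax, E)$slope
  full_fun <- fit_similarity_vs_heterogeneity(fun, E)$slope
  expect_equal(st$means$taxonomic[st$means$percent == 100], full_tax)
  expect_equal(st$means$functional[st$means$percent == 100], full_fun)

  # reproducible end to end under the same master seed
  st2 <- run_species_loss(sim$community, sim$traits, E,
                          percents = c(40, 70, 100), n_rep = 4, seed = 2)
  expect_identical(st$slopes, st2$slopes)
})

test_that("total functional redundancy flattens the functional response", {
  sim <- small_sim(3, n_trait_syndromes = 1)
  E <- env_heterogeneity(sim$environment)
  st <- run_species_loss(sim$community, sim$traits, E,
                         percents = c(30, 60, 100), n_rep = 3, seed = 4)
  # equal sampling depths: the full community is functionally identical
  # everywhere, so its slope is exactly zero
  expect_identical(st$slopes$functional[st$slopes$percent == 100], 0)
  # subsets retain unequal depths, but functional decay stays attenuated
  # relative to taxonomic decay in every replicate
  expect_true(all(abs(st$slopes$functional) <= abs(st$slopes$taxonomic)))
  expect_true(any(abs(st$slopes$taxonomic) > 1e-6))
})

test_that("compare_slopes runs ANOVA + Tukey and honours conventions", {
  # null case: slopes drawn from one distribution -> large p vs 100%
  set.seed(18)
  sl <- data.frame(percent = rep(c(100, 95, 90), c(1, 30, 30)),
                   replicate = c(1, 1:30, 1:30))
  # the 100% slope is the exact deterministic value; resampled levels
  # scatter around the same mean under the null
  sl$taxonomic <- c(-0.05, rnorm(60, -0.05, 0.001))
  sl$functional <- c(-0.02, rnorm(60, -0.02, 0.001))
  st <- structure(list(slopes = sl, n_rep = 30), class = "slope_table")
  cmp <- compare_slopes(st)
  expect_equal(cmp$percent, c(95, 90))
  expect_true(all(cmp$p_taxonomic > 0.05))
  expect_true(all(cmp$p_functional > 0.05))

  # a clearly shifted group is detected
  sl2 <- sl
  sl2$functional[sl2$percent == 90] <- rnorm(30, -0.04, 0.001)
  st2 <- structure(list(slopes = sl2, n_rep = 30), class = "slope_table")
  cmp2 <- compare_slopes(st2)
  expect_lt(cmp2$p_functional[cmp2$percent == 90], 0.001)
  expect_gt(cmp2$p_functional[cmp2$percent == 95], 0.05)

  # zero variance everywhere: p = 1 by convention
  sl3 <- sl
  sl3$taxonomic <- -0.05
  sl3$functional <- -0.02
  st3 <- structure(list(slopes = sl3, n_rep = 30), class = "slope_table")
  expect_message(cmp3 <- compare_slopes(st3), "convention")
  expect_true(all(cmp3$p_taxonomic == 1))
})

test_that("loss_onset_percent returns the head of the significant band", {
  cmp <- data.frame(percent = c(95, 90, 85, 80),
                    p_taxonomic = c(0.9, 0.8, 0.03, 0.01),
                    p_functional = c(0.9, 0.01, 0.2, 0.01))
  expect_equal(loss_onset_percent(cmp, "taxonomic"), 85)
  expect_equal(loss_onset_percent(cmp, "functional"), 90)
  cmp$p_functional <- rep(0.5, 4)
  expect_true(is.na(loss_onset_percent(cmp, "functional")))
})
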