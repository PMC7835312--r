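test_that("gower_distance is the mismatch fraction over applicable variables", {
  tt <- toy_traits()
  d <- gower_distance(tt)
  expect_equal(unname(diag(d)), rep(0, 4))
  expect_equal(d, t(d))
  expect_true(all(d >= 0 & d <= 1))

  # sp2 vs sp4: both pedunculate so all 7 variables applicable; they differ
  # in size, peduncle_type, colonization and growth_form
  expect_equal(d["sp2", "sp4"], 4 / 7)
  # sp1 vs sp3: peduncle_type not applicable to either -> 6 variables; only
  # mobility agrees
  expect_equal(d["sp1", "sp3"], 5 / 6)

  ident <- tt[c(1, 1), ]
  rownames(ident) <- c("a", "b")
  expect_equal(gower_distance(ident)["a", "b"], 0)

  # all applicable variables differ -> distance 1
  tt2 <- data.frame(size = c("large", "small"), mobility = c("mobile", "non-mobile"),
                    attachment = c("adnate", "non-attached"),
                    peduncle_type = c("not-applicable", "not-applicable"),
                    colonization = c("colonial", "non-colonial"),
                    growth_form = c("low-profile", "motile"),
                    nitrogen_fixation = c("fixer", "non-fixer"),
                    row.names = c("a", "b"))
  expect_equal(gower_distance(tt2)["a", "b"], 1)
})

test_that("gower_distance agrees with cluster::daisy on random trait tables", {
  set.seed(9)
  sim <- small_sim(2)
  tt <- sim$traits[sample(nrow(sim$traits), 25), ]
  d <- gower_distance(tt)
  # encode not-applicable as NA: daisy then excludes it pairwise, as we do
  tt_na <- tt
  tt_na$peduncle_type[tt_na$peduncle_type == "not-applicable"] <- NA
  tt_na$peduncle_type <- droplevels(tt_na$peduncle_type)
  dd <- as.matrix(cluster::daisy(tt_na, metric = "gower"))
  expect_equal(d, dd[rownames(d), colnames(d)], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("build_tree reproduces a hand-computed UPGMA merge", {
  d <- matrix(c(0, .2, .6,
                .2, 0, .6,
                .6, .6, 0), 3, dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  tr <- build_tree(d)
  expect_s3_class(tr, "functional_tree")
  expect_equal(sort(tr$heights), c(0.1, 0.3))
  # leaves A and B sit under the first merge (branch 0.1 each); C joins at 0.3
  cop <- as.matrix(cophenetic(tr$hclust))
  expect_equal(cop["A", "B"], 0.2)
  expect_equal(cop["A", "C"], 0.6)
  # branch lengths: two leaves at 0.1, leaf C at 0.3, internal node 0.2
  expect_setequal(round(tr$branch_lengths, 10), c(0.1, 0.1, 0.3, 0.2))
  expect_equal(sum(tr$branch_lengths), 0.1 + 0.1 + 0.3 + 0.2)

  # equal distances give a comb with a constant cophenetic matrix
  de <- matrix(0.4, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(de) <- 0
  tre <- build_tree(de)
  cope <- as.matrix(cophenetic(tre$hclust))
  expect_true(all(abs(cope[upper.tri(cope)] - 0.4) < 1e-12))

  expect_error(build_tree(matrix(c(0, NA, NA, 0), 2)), "NaN/NA")
})

test_that("UPGMA matches a brute-force average-linkage oracle", {
  set.seed(10)
  for (rep in 1:10) {
    n <- sample(4:6, 1)
    d <- matrix(0, n, n)
    d[upper.tri(d)] <- runif(n * (n - 1) / 2, 0.1, 1)
    d <- d + t(d)
    dimnames(d) <- list(letters[1:n], letters[1:n])
    tr <- build_tree(d)
    expect_equal(as.matrix(cophenetic(tr$hclust))[letters[1:n], letters[1:n]],
                 upgma_oracle(d), tolerance = 1e-12)
  }
})

test_that("tree incidence matrix encodes descendant leaves with correct lengths", {
  sim <- small_sim(1)
  tr <- functional_tree(sim$traits, subset = rownames(sim$traits)[1:15])
  n <- length(tr$labels)
  expect_identical(dim(tr$incidence), c(n, 2L * n - 2L))
  expect_true(all(tr$branch_lengths >= -1e-12))
  # total branch length below each leaf's path equals the root height
  root_h <- max(tr$heights)
  # each leaf's root-to-leaf path (branches it descends through) spans the root height
  for (i in seq_len(n))
    expect_equal(sum(tr$branch_lengths[tr$incidence[i, ] > 0]), root_h)
})

test_that("tree_beta reduces to the taxonomic partition on equal-height trees", {
  # all pairwise distances equal -> zero-length internals, equal leaf branches
  n <- 5
  de <- matrix(0.6, n, n); diag(de) <- 0
  dimnames(de) <- list(paste0("sp", 1:n), paste0("sp", 1:n))
  tr <- build_tree(de)
  set.seed(11)
  for (rep in 1:20) {
    x <- rpois(n, 3); y <- rpois(n, 3)
    if (sum(x) == 0 || sum(y) == 0) next
    names(x) <- names(y) <- paste0("sp", 1:n)
    tb <- tree_beta(x, y, tr)
    tax <- sorensen_abundance_partition(x, y)
    expect_equal(tb$beta_total, tax$beta_total, tolerance = 1e-12)
    expect_equal(tb$beta_repl, tax$beta_repl, tolerance = 1e-12)
    expect_equal(tb$beta_rich, tax$beta_rich, tolerance = 1e-12)
  }
})

test_that("tree_beta handles identity, disjoint leaves and partition identity", {
  sim <- small_sim(1)
  sub <- rownames(sim$traits)[1:12]
  tr <- functional_tree(sim$traits, subset = sub)
  x <- sim$community[1, sub]
  expect_equal(tree_beta(x, x, tr)$similarity, 1)

  d2 <- matrix(c(0, 0.8, 0.8, 0), 2, dimnames = list(c("u", "v"), c("u", "v")))
  tr2 <- build_tree(d2)
  expect_equal(tree_beta(c(u = 1, v = 0), c(u = 0, v = 1), tr2)$similarity, 0)

  set.seed(12)
  for (rep in 1:20) {
    a <- rpois(12, 2); b <- rpois(12, 2)
    names(a) <- names(b) <- sub
    if (sum(a) == 0 || sum(b) == 0) next
    tb <- tree_beta(a, b, tr)
    expect_equal(tb$beta_total, tb$beta_repl + tb$beta_rich, tolerance = 1e-12)
  }

  expect_error(tree_beta(c(w = 1), c(w = 2), tr2), "missing from tree")
})

test_that("pruning preserves the subset's cophenetic distances", {
  sim <- small_sim(2)
  tr <- functional_tree(sim$traits)
  sub <- sample(rownames(sim$traits), 10)
  pr <- prune_tree(tr, sub)
  full_cop <- as.matrix(cophenetic(tr$hclust))[sub, sub]
  sub_cop <- as.matrix(cophenetic(pr$hclust))[sub, sub]
  expect_equal(sub_cop, full_cop, tolerance = 1e-12)
})

test_that("functional similarity matrix behaves at the degenerate extremes", {
  cm <- toy_community()
  tt <- toy_traits()
  s <- functional_similarity_matrix(cm, tt)
  expect_equal(unname(diag(s)), rep(1, 3))
  expect_equal(s, t(s))
  expect_true(all(s >= 0 & s <= 1))

  # all species functionally identical: equal-depth sites are fully similar
  tt_one <- toy_traits()[c(1, 1, 1, 1), ]
  rownames(tt_one) <- paste0("sp", 1:4)
  cm_eq <- matrix(c(250, 250, 0, 0,
                    0, 0, 400, 100,
                    100, 100, 100, 200), 3, byrow = TRUE,
                  dimnames = dimnames(cm))
  s_one <- functional_similarity_matrix(cm_eq, tt_one)
  expect_true(all(abs(s_one - 1) < 1e-12))

  expect_error(functional_similarity_matrix(cm, tt, subset = "sp1"),
               "at least 2")
})

test_that("newick export round-trips through ape", {
  sim <- small_sim(1)
  tr <- functional_tree(sim$traits, subset = rownames(sim$traits)[1:8])
  nwk <- tree_newick(tr)
  phy <- ape::read.tree(text = nwk)
  expect_setequal(phy$tip.label, tr$labels)
  expect_true(ape::is.ultrametric(phy, tol = 1e-8))
})
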