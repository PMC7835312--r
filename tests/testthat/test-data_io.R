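test_that("read_tables round-trips the csv trio with the expected shapes", {
  dir <- withr::local_tempdir()
  write.csv(as.data.frame(toy_community()), file.path(dir, "community.csv"))
  write.csv(toy_traits(), file.path(dir, "traits.csv"))
  write.csv(toy_env(), file.path(dir, "environment.csv"))
  inp <- read_tables(file.path(dir, "community.csv"),
                     file.path(dir, "traits.csv"),
                     file.path(dir, "environment.csv"))
  expect_identical(dim(inp$community), c(3L, 4L))
  expect_identical(dim(inp$traits), c(4L, 7L))
  expect_identical(dim(inp$environment), c(3L, 12L))
  expect_identical(inp$community, toy_community())
  expect_length(inp$report$unused_trait_species, 0)
})

test_that("validation rejects broken inputs with informative errors", {
  dir <- withr::local_tempdir()
  cm <- as.data.frame(toy_community())
  names(cm)[4] <- "X"
  write.csv(cm, file.path(dir, "community.csv"))
  write.csv(toy_traits(), file.path(dir, "traits.csv"))
  write.csv(toy_env(), file.path(dir, "environment.csv"))
  expect_error(read_tables(file.path(dir, "community.csv"),
                           file.path(dir, "traits.csv"),
                           file.path(dir, "environment.csv")),
               "X")

  expect_error(as_community_matrix(matrix(c(-1, 2, 3, 4), 2)), "negative")
  bad <- toy_community(); rownames(bad) <- c("s", "s", "t")
  expect_error(as_community_matrix(bad), "duplicate")
  tt <- toy_traits(); tt$peduncle_type[1] <- "pad"   # adnate species
  expect_error(as_trait_table(tt), "not-applicable")
  tt2 <- toy_traits(); tt2$growth_form[2] <- "tall"
  expect_error(as_trait_table(tt2), "growth_form")
})

test_that("a transposed community table is detected and fixed", {
  dir <- withr::local_tempdir()
  write.csv(as.data.frame(t(toy_community())), file.path(dir, "community.csv"))
  write.csv(toy_traits(), file.path(dir, "traits.csv"))
  write.csv(toy_env(), file.path(dir, "environment.csv"))
  expect_warning(
    inp <- read_tables(file.path(dir, "community.csv"),
                       file.path(dir, "traits.csv"),
                       file.path(dir, "environment.csv")),
    "transposed")
  expect_identical(inp$community, toy_community())
})

test_that("expand_traits sums carrier abundances per category", {
  cm <- toy_community()
  tt <- toy_traits()
  tam <- expand_traits(cm, tt)
  # sp1 low-profile, sp2 high-profile, sp3 motile, sp4 planktonic
  expect_equal(unname(tam["site1", "growth_form:low-profile"]), 300)
  expect_equal(unname(tam["site1", "growth_form:planktonic"]), 0)
  expect_equal(unname(tam["site3", "growth_form:planktonic"]), 250)

  # disjoint single-carrier categories equal their carrier's count
  cm1 <- matrix(c(100, 400), 1, dimnames = list("s1", c("spA", "spB")))
  tt1 <- toy_traits()[1:2, ]
  rownames(tt1) <- c("spA", "spB")
  tam1 <- expand_traits(cm1, tt1)
  expect_equal(unname(tam1[1, "size:large"]), 100)
  expect_equal(unname(tam1[1, "size:small"]), 400)
  expect_equal(unname(tam1[1, "growth_form:low-profile"]), 100)
  expect_equal(unname(tam1[1, "growth_form:high-profile"]), 400)
})

test_that("expand_traits conserves site totals for complete trait variables", {
  sim <- small_sim(1)
  tam <- expand_traits(sim$community, sim$traits)
  tot <- rowSums(sim$community)
  for (v in c("size", "mobility", "attachment", "colonization",
              "growth_form", "nitrogen_fixation")) {
    cols <- grep(paste0("^", v, ":"), colnames(tam))
    expect_equal(unname(rowSums(tam[, cols, drop = FALSE])), unname(tot))
  }
  # peduncle_type has a not-applicable level: its columns sum to at most the total
  cols <- grep("^peduncle_type:", colnames(tam))
  expect_true(all(rowSums(tam[, cols, drop = FALSE]) <= tot))
})

test_that("write_outputs writes csvs plus a manifest", {
  dir <- withr::local_tempdir()
  man <- write_outputs(list(a = data.frame(x = 1:3)), dir, seed = 7,
                       params = list(k = 2))
  expect_true(file.exists(file.path(dir, "a.csv")))
  expect_true(file.exists(file.path(dir, "manifest.json")))
  js <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(js$seed, 7)
  back <- read.csv(file.path(dir, "a.csv"), row.names = 1)
  expect_equal(back$x, 1:3)
})
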