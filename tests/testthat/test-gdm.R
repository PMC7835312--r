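test_that("I-spline basis hits its boundaries and is monotone", {
  x <- seq(0, 10, length.out = 201)
  b <- ispline_basis(x)
  expect_equal(unname(b[1, ]), c(0, 0, 0))
  expect_equal(unname(b[201, ]), c(1, 1, 1))
  # interior points: each basis is strictly inside (0, 1) on its support
  b_lo <- ispline_basis(2.5, knots = attr(b, "knots"))
  b_hi <- ispline_basis(7.5, knots = attr(b, "knots"))
  expect_true(all(b_lo[1:2] > 0 & b_lo[1:2] < 1))
  expect_true(all(b_hi[2:3] > 0 & b_hi[2:3] < 1))
  for (k in 1:3) expect_true(all(diff(b[, k]) >= -1e-12))
  expect_true(all(b >= 0 & b <= 1))
  expect_error(ispline_basis(rep(2, 5)), "constant")
})

test_that("site-pair table has one row per unordered pair", {
  env <- toy_env()
  r <- matrix(c(0, .2, .4, .2, 0, .3, .4, .3, 0), 3,
              dimnames = list(rownames(env), rownames(env)))
  spt <- build_site_pair_table(r, env)
  expect_equal(nrow(spt), 3)
  expect_equal(spt$distance, c(.2, .4, .3))
  expect_setequal(attr(spt, "predictors"),
                  setdiff(names(env), "distance_from_site1"))

  env2 <- env[1:2, ]
  expect_equal(nrow(build_site_pair_table(r[1:2, 1:2], env2)), 1)
  r_bad <- r; r_bad[1, 2] <- r_bad[2, 1] <- 1.4
  expect_error(build_site_pair_table(r_bad, env), "\\[0, 1\\]")

  n <- 51
  rn <- paste0("s", 1:n)
  big <- matrix(0.5, n, n, dimnames = list(rn, rn)); diag(big) <- 0
  envn <- data.frame(a = rnorm(n), row.names = rn)
  expect_equal(nrow(build_site_pair_table(big, envn)), 51 * 50 / 2)
})

test_that("the link and deviance behave at the trivial point", {
  # zero coefficients: eta = 0 so fitted dissimilarity is 1 - e^0 = 0
  env <- data.frame(a = 1:6, row.names = paste0("s", 1:6))
  r <- matrix(0.3, 6, 6, dimnames = list(rownames(env), rownames(env)))
  diag(r) <- 0
  spt <- build_site_pair_table(r, env)
  m <- fit_gdm(spt)
  zero <- m
  zero$coefficients[] <- 0
  expect_equal(unname(predict(zero)), rep(0, nrow(spt)))
})

test_that("GDM recovers a self-generated response almost perfectly", {
  set.seed(13)
  n <- 25
  z <- sort(runif(n, 0, 5))
  env <- data.frame(z = z, row.names = paste0("s", 1:n))
  eta <- 0.1 + abs(outer(z, z, "-")) * 0.3
  mu <- 1 - exp(-eta); diag(mu) <- 0
  dimnames(mu) <- list(rownames(env), rownames(env))
  spt <- build_site_pair_table(mu, env)
  m <- fit_gdm(spt)
  expect_gt(m$deviance_explained, 95)
  expect_true(all(coef(m) >= 0))
  expect_lt(max(abs(m$fitted - spt$distance)), 0.05)
})

test_that("fitted dissimilarity is monotone in every predictor difference", {
  set.seed(14)
  n <- 20
  env <- data.frame(a = runif(n), b = runif(n), row.names = paste0("s", 1:n))
  d <- matrix(runif(n * n, 0.1, 0.9), n); d <- (d + t(d)) / 2; diag(d) <- 0
  dimnames(d) <- list(rownames(env), rownames(env))
  m <- fit_gdm(build_site_pair_table(d, env))
  for (p in c("a", "b")) {
    kn <- m$knots[[p]]
    grid <- seq(kn[1], kn[3], length.out = 300)
    a_p <- coef(m)[paste0(p, ".spline", 1:3)]
    f <- drop(ispline_basis(grid, kn) %*% a_p)
    expect_true(all(diff(f) >= -1e-12))
  }
  # full model explains at least as much as any single-predictor submodel
  for (p in c("a", "b")) {
    sub <- build_site_pair_table(d, env[p])
    expect_gte(m$deviance_explained + 1e-8,
               fit_gdm(sub)$deviance_explained)
  }
})

test_that("permutation importance separates signal from noise", {
  set.seed(15)
  n <- 18
  z <- sort(runif(n, 0, 4))
  env <- data.frame(z = z, noise = rnorm(n), row.names = paste0("s", 1:n))
  mu <- 1 - exp(-(0.05 + 0.4 * abs(outer(z, z, "-"))))
  diag(mu) <- 0
  dimnames(mu) <- list(rownames(env), rownames(env))
  m <- fit_gdm(build_site_pair_table(mu, env))
  pi <- permutation_importance(m, n_perm = 20, seed = 3)
  imp <- pi$importance
  expect_equal(imp$predictor[1], "z")
  expect_gt(imp$importance[imp$predictor == "z"], 10)
  expect_lt(abs(imp$importance[imp$predictor == "noise"]), 5)
  expect_gt(imp$p[imp$predictor == "noise"], 0.05)
  expect_lte(imp$p[imp$predictor == "z"], 0.05)
  expect_lte(pi$model_p, 0.05)
})
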