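#' Monotone I-spline basis
#'
#' Order-2 I-splines with knots at the minimum, median and maximum of the
#' predictor. Each of the three basis functions is monotone non-decreasing,
#' 0 at the predictor minimum and 1 at its maximum, so non-negative
#' coefficients yield a monotone fitted transform.
#'
#' @param x predictor values.
#' @param knots optional numeric c(min, mid, max); computed from `x` when
#'   NULL. If the median coincides with an endpoint (heavily tied data) the
#'   midpoint of the range is used instead.
#' @return n x 3 matrix of basis values in \[0, 1\]; knots as an attribute.
#' @export
ispline_basis <- function(x, knots = NULL) {
  if (is.null(knots)) {
    a <- min(x); b <- max(x)
    if (a == b) stop("constant predictor")
    m <- median(x)
    if (m <= a || m >= b) m <- (a + b) / 2
    knots <- c(a, m, b)
  }
  a <- knots[1]; m <- knots[2]; b <- knots[3]
  stopifnot(a < m, m < b)
  i1 <- ifelse(x <= a, 0, ifelse(x >= m, 1, 1 - ((m - x) / (m - a))^2))
  i2 <- ifelse(x <= a, 0,
        ifelse(x <= m, (x - a)^2 / ((b - a) * (m - a)),
        ifelse(x <  b, 1 - (b - x)^2 / ((b - a) * (b - m)), 1)))
  i3 <- ifelse(x <= m, 0, ifelse(x >= b, 1, ((x - m) / (b - m))^2))
  out <- cbind(i1, i2, i3)
  attr(out, "knots") <- knots
  out
}

#' Build a site-pair table for dissimilarity modelling
#'
#' One row per unordered site pair i < j with the response dissimilarity and
#' both sites' predictor values, the input format of [fit_gdm()].
#'
#' @param response_matrix symmetric site x site dissimilarity matrix with
#'   values in \[0, 1\].
#' @param env environment table (transformed as desired); geographic columns
#'   are excluded from the predictors.
#' @param predictors character vector of predictor names (default: all
#'   non-geographic env columns).
#' @return data.frame of class `site_pair_table` with columns `site1`,
#'   `site2`, `distance`, `s1.<p>`, `s2.<p>`; the site-level predictor table
#'   is kept in the `site_env` attribute (used by permutation tests).
#' @export
build_site_pair_table <- function(response_matrix, env,
                                  predictors = NULL) {
  env <- as_environment_table(env)
  r <- as.matrix(response_matrix)
  sites <- rownames(env)
  if (!is.null(rownames(r))) {
    if (!all(sites %in% rownames(r))) stop("site sets do not match")
    r <- r[sites, sites]
  } else if (nrow(r) != nrow(env)) stop("site sets do not match")
  if (any(r < 0 | r > 1)) stop("response dissimilarities must lie in [0, 1]")
  if (is.null(predictors))
    predictors <- setdiff(names(env), c("distance_from_site1", "lon", "lat"))
  n <- nrow(env)
  ij <- which(upper.tri(r), arr.ind = TRUE)
  ij <- ij[order(ij[, 1], ij[, 2]), , drop = FALSE]
  spt <- data.frame(site1 = sites[ij[, 1]], site2 = sites[ij[, 2]],
                    distance = r[ij])
  for (p in predictors) {
    spt[[paste0("s1.", p)]] <- env[[p]][ij[, 1]]
    spt[[paste0("s2.", p)]] <- env[[p]][ij[, 2]]
  }
  structure(spt, predictors = predictors,
            site_env = env[predictors], class = c("site_pair_table", "data.frame"))
}

## Design matrix: intercept column + |I_k(x_i) - I_k(x_j)| per predictor and
## spline. Knots are computed from the pooled s1/s2 values unless supplied.
gdm_design <- function(spt, knots = NULL) {
  predictors <- attr(spt, "predictors")
  cols <- list(`(Intercept)` = rep(1, nrow(spt)))
  kn <- list()
  for (p in predictors) {
    v <- c(spt[[paste0("s1.", p)]], spt[[paste0("s2.", p)]])
    b <- ispline_basis(v, knots = knots[[p]])
    kn[[p]] <- attr(b, "knots")
    n <- nrow(spt)
    dif <- abs(b[seq_len(n), , drop = FALSE] - b[n + seq_len(n), , drop = FALSE])
    colnames(dif) <- paste0(p, ".spline", 1:3)
    cols[[p]] <- dif
  }
  list(X = do.call(cbind, cols), knots = kn)
}

gdm_deviance <- function(d, mu, eps = 1e-9) {
  mu <- pmin(pmax(mu, eps), 1 - eps)
  t1 <- ifelse(d > 0, d * log(d / mu), 0)
  t2 <- ifelse(d < 1, (1 - d) * log((1 - d) / (1 - mu)), 0)
  2 * sum(t1 + t2)
}

## IRLS with a non-negative least-squares inner step for the
## negative-exponential link mu = 1 - exp(-eta), eta = X beta, beta >= 0.
gdm_irls <- function(X, d, beta0 = NULL, tol = 1e-8, max_iter = 100,
                     eps = 1e-9) {
  n <- nrow(X); p <- ncol(X)
  beta <- if (is.null(beta0)) c(max(-log(1 - min(mean(d), 1 - eps)), eps),
                                rep(0, p - 1)) else beta0
  dev <- gdm_deviance(d, 1 - exp(-drop(X %*% beta)), eps)
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- pmin(pmax(1 - exp(-eta), eps), 1 - eps)
    mu_prime <- pmax(1 - mu, eps)               # d mu / d eta
    w <- mu_prime^2 / (mu * (1 - mu))
    z <- eta + (d - mu) / mu_prime
    sw <- sqrt(w)
    fit <- pracma::lsqnonneg(X * sw, z * sw)
    beta_new <- fit$x
    dev_new <- gdm_deviance(d, 1 - exp(-drop(X %*% beta_new)), eps)
    ## step-halving if the quadratic step overshoots
    step <- 1
    while (dev_new > dev + 1e-12 && step > 1e-4) {
      step <- step / 2
      beta_try <- beta + step * (beta_new - beta)
      dev_try <- gdm_deviance(d, 1 - exp(-drop(X %*% beta_try)), eps)
      if (dev_try < dev_new) { beta_new <- beta_try; dev_new <- dev_try }
    }
    converged <- abs(dev - dev_new) < tol
    beta <- beta_new; dev <- dev_new
    if (converged) break
  }
  list(beta = beta, deviance = dev, iterations = iter,
       converged = iter < max_iter)
}

#' Fit a generalized dissimilarity model
#'
#' Models pairwise compositional dissimilarity as
#' mu_ij = 1 - exp(-eta_ij) with
#' eta_ij = a0 + sum_p sum_k a_pk |I_pk(x_pi) - I_pk(x_pj)|,
#' where the I_pk are monotone I-spline transforms of predictor p and all
#' coefficients are non-negative, so fitted dissimilarity never decreases as
#' sites become environmentally more different. Coefficients minimize the
#' binomial-form deviance by iteratively reweighted least squares with a
#' non-negative least-squares inner step. The null deviance comes from the
#' intercept-only model (fitted dissimilarity = mean observed).
#'
#' @param spt site-pair table from [build_site_pair_table()].
#' @param tol deviance-change convergence tolerance (default 1e-8).
#' @param max_iter maximum IRLS iterations.
#' @return object of class `gdm`: coefficients, knots, deviance, null
#'   deviance, `deviance_explained` (percent), fitted values, the call.
#' @export
fit_gdm <- function(spt, tol = 1e-8, max_iter = 100) {
  des <- gdm_design(spt)
  d <- spt$distance
  if (nrow(des$X) < ncol(des$X))
    stop("fewer site pairs than coefficients")
  fit <- gdm_irls(des$X, d, tol = tol, max_iter = max_iter)
  if (fit$iterations >= max_iter)
    warning("IRLS reached max_iter without meeting the deviance tolerance")
  null_dev <- gdm_deviance(d, rep(mean(d), length(d)))
  eta <- drop(des$X %*% fit$beta)
  structure(list(
    coefficients = setNames(fit$beta, colnames(des$X)),
    knots = des$knots,
    predictors = attr(spt, "predictors"),
    deviance = fit$deviance,
    null_deviance = null_dev,
    deviance_explained = 100 * (1 - fit$deviance / null_dev),
    fitted = 1 - exp(-eta),
    observed = d,
    iterations = fit$iterations,
    spt = spt,
    call = match.call()),
    class = "gdm")
}

#' @export
print.gdm <- function(x, ...) {
  cat("Generalized dissimilarity model\n")
  cat("  ", length(x$observed), " site pairs, ", length(x$predictors),
      " predictors (3 I-splines each)\n", sep = "")
  cat(sprintf("  deviance: %.4f  null: %.4f  explained: %.2f%%\n",
              x$deviance, x$null_deviance, x$deviance_explained))
  invisible(x)
}

#' @export
coef.gdm <- function(object, ...) object$coefficients

#' @export
summary.gdm <- function(object, ...) {
  co <- object$coefficients[-1]
  pred <- sub("\\.spline[123]$", "", names(co))
  tab <- data.frame(predictor = object$predictors,
                    coef_sum = vapply(object$predictors,
                                      function(p) sum(co[pred == p]), 0))
  tab <- tab[order(-tab$coef_sum), ]
  rownames(tab) <- NULL
  out <- list(model = object, predictor_table = tab)
  class(out) <- "summary.gdm"
  out
}

#' @export
print.summary.gdm <- function(x, ...) {
  print(x$model)
  cat("\nPredictor spline-coefficient sums (maximum height of the fitted\n")
  cat("transform; larger = stronger modelled effect):\n")
  print(x$predictor_table, digits = 4)
  invisible(x)
}

#' @export
predict.gdm <- function(object, newdata = NULL, ...) {
  spt <- if (is.null(newdata)) object$spt else newdata
  des <- gdm_design(spt, knots = object$knots)
  drop(1 - exp(-des$X %*% object$coefficients))
}

#' @export
plot.gdm <- function(x, ...) {
  pred <- x$predictors
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(pred) + 1))
  on.exit(graphics::par(old))
  plot(x$observed, x$fitted, xlab = "observed dissimilarity",
       ylab = "fitted", main = "GDM fit", pch = 16, cex = 0.5, ...)
  graphics::abline(0, 1, lty = 2)
  for (p in pred) {
    kn <- x$knots[[p]]
    grid <- seq(kn[1], kn[3], length.out = 200)
    b <- ispline_basis(grid, knots = kn)
    a <- x$coefficients[paste0(p, ".spline", 1:3)]
    plot(grid, drop(b %*% a), type = "l", xlab = p, ylab = "f(x)",
         main = p)
  }
  invisible(x)
}

## Rebuild pair predictor columns after permuting site-level values.
permute_spt <- function(spt, perm_sites, which_pred = NULL) {
  env <- attr(spt, "site_env")
  predictors <- attr(spt, "predictors")
  sites <- rownames(env)
  if (is.null(which_pred)) which_pred <- predictors
  env_perm <- env
  env_perm[which_pred] <- env[perm_sites, which_pred, drop = FALSE]
  i1 <- match(spt$site1, sites); i2 <- match(spt$site2, sites)
  for (p in which_pred) {
    spt[[paste0("s1.", p)]] <- env_perm[[p]][i1]
    spt[[paste0("s2.", p)]] <- env_perm[[p]][i2]
  }
  spt
}

#' Permutation importance and significance for a GDM
#'
#' For each predictor, its site-level values are permuted across sites
#' `n_perm` times and the model refitted; importance is the mean percent
#' decrease in deviance explained relative to the full model, and the
#' predictor p value is the fraction of permutations whose fit is at least
#' as good as the full model's. The whole-model p value permutes all
#' predictors jointly. Permutation operates on sites, not pairs, preserving
#' the metric structure of the pair table.
#'
#' @param model fitted `gdm`.
#' @param n_perm number of permutations (default 50).
#' @param seed integer seed.
#' @return list with `importance` (data.frame: predictor, importance, p),
#'   `model_p`, `n_perm`, and the count of failed refits.
#' @export
permutation_importance <- function(model, n_perm = 50, seed = 1) {
  spt <- model$spt
  predictors <- model$predictors
  n_sites <- nrow(attr(spt, "site_env"))
  de_full <- model$deviance_explained
  set.seed(seed)
  perms <- replicate(n_perm, sample(n_sites), simplify = FALSE)
  failures <- 0L
  refit_de <- function(spt2) {
    tryCatch(fit_gdm(spt2)$deviance_explained,
             error = function(e) { failures <<- failures + 1L; NA_real_ })
  }
  imp <- data.frame(predictor = predictors, importance = NA_real_, p = NA_real_)
  for (k in seq_along(predictors)) {
    de <- vapply(perms, function(pr)
      refit_de(permute_spt(spt, pr, predictors[k])), 0)
    imp$importance[k] <- mean(100 * (de_full - de) / de_full, na.rm = TRUE)
    imp$p[k] <- mean(de >= de_full, na.rm = TRUE)
  }
  de_all <- vapply(perms, function(pr) refit_de(permute_spt(spt, pr)), 0)
  model_p <- mean(de_all >= de_full, na.rm = TRUE)
  imp <- imp[order(-imp$importance), ]
  rownames(imp) <- NULL
  list(importance = imp, model_p = model_p, n_perm = n_perm,
       failed_fits = failures)
}
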