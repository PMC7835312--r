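#' Linear distance-decay model of community similarity
#'
#' Ordinary least-squares fit of similarity against distance (geographic km
#' from the reference site, or environmental heterogeneity). The
#' self-comparison point (distance 0, similarity 1) is excluded by default:
#' it is an identity, not an observation. Significance is the two-sided
#' F test of the slope; the coefficient of determination is adjusted R
#' squared, 1 - (1 - R2)(n - 1)/(n - 2). A constant response is reported
#' with slope 0 and R2 0 by convention.
#'
#' @param similarity,distance equal-length numeric vectors; pairs with NA
#'   similarity are dropped.
#' @param drop_self exclude points with distance exactly 0 (default TRUE).
#' @param log_similarity fit log(similarity) instead (log-linear decay
#'   form); requires positive similarities.
#' @return object of class `decay_fit`: slope, intercept, r2, r2_adj, F
#'   statistic, p, n, `form` ("linear" or "log-linear") and the underlying
#'   `lm` fit.
#' @export
fit_decay <- function(similarity, distance, drop_self = TRUE,
                      log_similarity = FALSE) {
  stopifnot(length(similarity) == length(distance))
  keep <- !is.na(similarity) & !is.na(distance)
  if (drop_self) keep <- keep & distance != 0
  s <- similarity[keep]; d <- distance[keep]
  if (length(s) < 3) stop("need at least 3 points")
  if (var(d) == 0) stop("zero variance in distance")
  if (log_similarity) {
    if (any(s <= 0)) stop("log-linear form requires positive similarities")
    s <- log(s)
  }
  fit <- lm(s ~ d)
  n <- length(s)
  if (var(s) == 0) {
    out <- list(slope = 0, intercept = s[1], r2 = 0, r2_adj = 0,
                F = NA_real_, p = NA_real_, n = n,
                form = if (log_similarity) "log-linear" else "linear",
                lm = fit)
  } else {
    sm <- summary(fit)
    out <- list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
                r2 = sm$r.squared, r2_adj = sm$adj.r.squared,
                F = unname(sm$fstatistic[1]),
                p = unname(pf(sm$fstatistic[1], sm$fstatistic[2],
                              sm$fstatistic[3], lower.tail = FALSE)),
                n = n, form = if (log_similarity) "log-linear" else "linear",
                lm = fit)
  }
  class(out) <- "decay_fit"
  out
}

#' @export
print.decay_fit <- function(x, ...) {
  cat("Distance-decay fit (", x$form, "), n = ", x$n, "\n", sep = "")
  cat(sprintf("  slope = %.5g  intercept = %.5g\n", x$slope, x$intercept))
  cat(sprintf("  adj. R2 = %.3f  F = %.3g  p = %.3g\n",
              x$r2_adj, x$F, x$p))
  invisible(x)
}

#' @export
coef.decay_fit <- function(object, ...)
  c(intercept = object$intercept, slope = object$slope)

#' @export
predict.decay_fit <- function(object, distance, ...) {
  eta <- object$intercept + object$slope * distance
  if (object$form == "log-linear") exp(eta) else eta
}

#' @export
summary.decay_fit <- function(object, ...) summary(object$lm, ...)

#' Distance that halves community similarity
#'
#' The distance at which the fitted similarity falls to half its value at
#' 1 km. For a linear fit S(x) = intercept + slope x this is
#' (S(1)/2 - intercept)/slope; for the log-linear form it is
#' 1 + ln(2)/|slope|. A non-negative slope gives no halving: +Inf is
#' returned with a warning.
#'
#' @param fit `decay_fit` from a geographic-distance fit.
#' @return halving distance in the fit's distance units (km).
#' @export
halving_distance <- function(fit) {
  if (fit$slope >= 0) {
    warning("non-negative slope: similarity never halves; returning Inf")
    return(Inf)
  }
  if (fit$form == "log-linear") return(1 + log(2) / abs(fit$slope))
  s1 <- fit$intercept + fit$slope
  if (s1 <= 0) stop("fitted similarity at 1 km is not positive")
  (s1 / 2 - fit$intercept) / fit$slope
}

#' Similarity versus environmental heterogeneity over all site pairs
#'
#' OLS regression of pairwise similarity on pairwise environmental
#' heterogeneity using all n(n-1)/2 unordered pairs.
#'
#' @param sim_matrix site x site similarity matrix.
#' @param E site x site environmental-heterogeneity matrix
#'   ([env_heterogeneity()]).
#' @return `decay_fit` (self pairs are off-diagonal only, so none dropped).
#' @export
fit_similarity_vs_heterogeneity <- function(sim_matrix, E) {
  s <- as.matrix(sim_matrix); e <- as.matrix(E)
  if (!is.null(rownames(s)) && !is.null(rownames(e))) {
    if (!setequal(rownames(s), rownames(e))) stop("site sets do not match")
    e <- e[rownames(s), rownames(s)]
  } else stopifnot(all(dim(s) == dim(e)))
  ut <- upper.tri(s)
  fit_decay(s[ut], e[ut], drop_self = FALSE)
}
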