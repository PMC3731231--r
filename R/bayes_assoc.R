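## Bayes-factor association machinery.
##
## Single-SNP and conditional multi-SNP Bayes factors from a conjugate
## normal linear model: y = mu + beta_a * g + beta_d * d + e, with a flat
## prior on the intercept(s), the Jeffreys limit for the residual variance,
## and effect priors beta | sigma ~ N(0, sigma^2 * D).  The dominance
## indicator d is 1 for (near-)heterozygous dosages.  BFs are averaged over
## a grid of plausible additive-effect scales, with the dominance scale tied
## to a quarter of the additive scale.

#' Effect-size prior grid for Bayesian association
#'
#' The additive effect prior standard deviations (in units of the residual
#' SD; traits are standard-normal residuals, so effectively trait-SD units)
#' define a grid that the Bayes factor averages over with uniform weights.
#' The dominance prior SD is tied to `sigma_a / 4`.
#'
#' @param sigma_a numeric vector of additive prior SDs (> 0).
#' @param weights grid weights; default uniform. Must sum to 1.
#' @return an object of class `prior_grid`.
#' @examples
#' prior_grid()
#' prior_grid(sigma_a = c(0.1, 0.4))
#' @export
prior_grid <- function(sigma_a = c(0.05, 0.1, 0.2, 0.4),
                       weights = rep(1 / length(sigma_a), length(sigma_a))) {
  if (any(sigma_a <= 0)) stop("`sigma_a` must be positive", call. = FALSE)
  if (length(weights) != length(sigma_a) || abs(sum(weights) - 1) > 1e-8) {
    stop("`weights` must match `sigma_a` and sum to 1", call. = FALSE)
  }
  structure(list(sigma_a = sigma_a, sigma_d = sigma_a / 4, weights = weights),
            class = "prior_grid")
}

#' @export
print.prior_grid <- function(x, ...) {
  cat("Effect-size prior grid (additive SD, dominance SD = additive/4):\n")
  print(data.frame(sigma_a = x$sigma_a, sigma_d = x$sigma_d, weight = x$weights))
  invisible(x)
}

## Dominance indicator: 1 when the (possibly mean-imputed) dosage is closest
## to the heterozygote.
dominance_indicator <- function(g) as.numeric(abs(g - 1) < 0.5)

## Core closed form: log10 BF of the model with design X (columns already
## chosen; prior covariance sigma^2 * D) against the covariate-free null.
## `groups` allows per-group flat intercepts (used by the bivariate module);
## X and y are centered within groups and the effective dimension is
## n - n_groups.
log10bf_gaussian <- function(y, X, D, groups = NULL) {
  st <- bf_suffstats(y, X, groups)
  bf_from_stats(st, D)
}

## Sufficient statistics (computed once, reused across the prior grid).
bf_suffstats <- function(y, X, groups = NULL) {
  n <- length(y)
  X <- matrix(X, nrow = n)
  if (is.null(groups)) {
    yc <- y - mean(y)
    Xc <- sweep(X, 2L, colMeans(X))
    df <- n - 1L
  } else {
    groups <- as.factor(groups)
    yc <- y - ave(y, groups)
    Xc <- apply(X, 2L, function(col) col - ave(col, groups))
    Xc <- matrix(Xc, nrow = n)
    df <- n - nlevels(groups)
  }
  list(A = sum(yc^2), M = crossprod(Xc), u = crossprod(Xc, yc),
       k = ncol(Xc), df = df)
}

bf_from_stats <- function(st, D) {
  ld <- determinant(diag(st$k) + st$M %*% D, logarithm = TRUE)
  S <- st$A - drop(t(st$u) %*% solve(st$M + solve(D), st$u))
  -0.5 * as.numeric(ld$modulus) / log(10) - (st$df / 2) * log10(S / st$A)
}

## Vectorised single-SNP scan: log10 BF for y against every column of G
## (dosage matrix), grid-averaged. Returns a numeric vector.
ubf_scan <- function(y, G, prior = prior_grid()) {
  G <- as.matrix(G)
  n <- length(y)
  stopifnot(nrow(G) == n, n >= 3L)
  yc <- y - mean(y)
  A <- sum(yc^2)
  Gc <- sweep(G, 2L, colMeans(G))
  Dm <- matrix(dominance_indicator(G), nrow = n)
  Dc <- sweep(Dm, 2L, colMeans(Dm))
  Sgg <- colSums(Gc^2)
  if (any(Sgg <= 0)) stop("monomorphic genotype", call. = FALSE)
  Sdd <- colSums(Dc^2)
  Sgd <- colSums(Gc * Dc)
  Sgy <- colSums(Gc * yc)
  Sdy <- colSums(Dc * yc)
  out <- matrix(NA_real_, nrow = ncol(G), ncol = length(prior$sigma_a))
  for (j in seq_along(prior$sigma_a)) {
    sa2 <- prior$sigma_a[j]^2
    sd2 <- prior$sigma_d[j]^2
    logdet <- log((1 + Sgg * sa2) * (1 + Sdd * sd2) - Sgd^2 * sa2 * sd2)
    det2 <- (Sgg + 1 / sa2) * (Sdd + 1 / sd2) - Sgd^2
    quad <- ((Sdd + 1 / sd2) * Sgy^2 - 2 * Sgd * Sgy * Sdy +
               (Sgg + 1 / sa2) * Sdy^2) / det2
    S <- A - quad
    out[, j] <- -0.5 * logdet / log(10) - ((n - 1) / 2) * log10(S / A)
  }
  log10_weighted_sum(out, prior$weights)
}

#' Single-SNP log10 Bayes factor
#'
#' Closed-form Bayes factor for association between a quantitative trait and
#' one SNP, under a linear model with additive-dosage and dominance terms and
#' a grid prior over effect scales (averaged with uniform weights). Evidence
#' is relative to the intercept-only null; the form is invariant to location
#' and scale changes of `y` and to allele flips `g -> 2 - g`.
#'
#' @param y numeric trait vector (typically standard-normal residuals).
#' @param g dosage vector in `[0, 2]`, same length as `y`.
#' @param prior a [prior_grid()].
#' @return log10 Bayes factor (scalar).
#' @examples
#' set.seed(1)
#' g <- rbinom(100, 2, 0.3)
#' y <- 0.5 * g + rnorm(100)
#' univariate_log10bf(y, g)
#' @export
univariate_log10bf <- function(y, g, prior = prior_grid()) {
  if (length(y) != length(g)) stop("`y` and `g` lengths differ", call. = FALSE)
  if (length(y) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (stats::var(g) == 0) stop("monomorphic genotype", call. = FALSE)
  ubf_scan(y, matrix(g, ncol = 1L), prior)
}

#' Conditional (multivariate) log10 Bayes factor
#'
#' Evidence for the focal SNP given a conditioning set: the Bayes factor of
#' the joint model on all `k` SNPs against the model dropping the focal SNP.
#' Each SNP contributes an additive and a dominance column; the prior grid's
#' additive scale is shared across SNPs at each grid point. For `k = 1` this
#' equals [univariate_log10bf()].
#'
#' @param y trait vector.
#' @param G dosage matrix, one column per SNP; the conditioning set plus the
#'   focal SNP.
#' @param prior a [prior_grid()].
#' @param focal column index of the focal SNP (default: last column).
#' @return conditional log10 Bayes factor.
#' @export
multivariate_log10bf <- function(y, G, prior = prior_grid(), focal = ncol(G)) {
  G <- as.matrix(G)
  n <- length(y)
  stopifnot(nrow(G) == n)
  if (any(apply(G, 2L, stats::var) == 0)) {
    stop("monomorphic genotype", call. = FALSE)
  }
  Gc <- sweep(G, 2L, colMeans(G))
  if (qr(Gc)$rank < ncol(G)) stop("collinear columns", call. = FALSE)
  full <- joint_log10bf(y, G, prior)
  if (ncol(G) == 1L) return(full)
  reduced <- joint_log10bf(y, G[, -focal, drop = FALSE], prior)
  full - reduced
}

## Joint model BF (all SNPs in G vs the null), grid-averaged.
joint_log10bf <- function(y, G, prior, groups = NULL, flip = NULL) {
  G <- as.matrix(G)
  k <- ncol(G)
  Dm <- matrix(dominance_indicator(G), nrow = nrow(G))
  if (!is.null(flip)) {
    G[flip, ] <- -G[flip, ]
    Dm[flip, ] <- -Dm[flip, ]
  }
  X <- cbind(G, Dm)
  st <- bf_suffstats(y, X, groups)
  vals <- vapply(seq_along(prior$sigma_a), function(j) {
    D <- diag(c(rep(prior$sigma_a[j]^2, k), rep(prior$sigma_d[j]^2, k)),
              nrow = 2L * k)
    bf_from_stats(st, D)
  }, numeric(1L))
  as.numeric(log10_weighted_sum(vals, prior$weights))
}

#' Frequentist effect estimate for one SNP
#'
#' Ordinary least squares of the trait on the dosage with an intercept,
#' reporting the per-minor-allele effect, the coefficient of determination
#' and the standard error of the slope.
#'
#' @inheritParams univariate_log10bf
#' @return list with `beta`, `r2`, `se`.
#' @export
effect_estimate <- function(y, g) {
  n <- length(y)
  if (n < 3L) stop("need at least 3 observations", call. = FALSE)
  if (stats::var(g) == 0) stop("monomorphic genotype", call. = FALSE)
  gc <- g - mean(g)
  yc <- y - mean(y)
  sxx <- sum(gc^2)
  beta <- sum(gc * yc) / sxx
  res <- yc - beta * gc
  rss <- sum(res^2)
  tss <- sum(yc^2)
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_
  se <- sqrt(rss / (n - 2) / sxx)
  list(beta = beta, r2 = r2, se = se)
}
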