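# Independent oracles used across the suite.  These deliberately avoid the
# package's own closed forms / interval machinery.

# Monte-Carlo estimate of the single-SNP log10 Bayes factor.
#
# Uses the exact importance identity
#   BF = E[ p(y | beta, sigma) / p0(y | sigma) ],
# with sigma^2 drawn from the null posterior Inv-Gamma((n-1)/2, A/2) and
# beta from its conditional prior N(0, sigma^2 D).  The weight is a bare
# likelihood ratio, so no part of the closed-form integral is reused.
mc_log10bf <- function(y, g, prior = eqtlcre::prior_grid(), n_draws = 1e6) {
  n <- length(y)
  yc <- y - mean(y)
  A <- sum(yc^2)
  gc <- g - mean(g)
  d <- as.numeric(abs(g - 1) < 0.5)
  dc <- d - mean(d)
  M11 <- sum(gc^2); M22 <- sum(dc^2); M12 <- sum(gc * dc)
  u1 <- sum(gc * yc); u2 <- sum(dc * yc)
  per_grid <- vapply(seq_along(prior$sigma_a), function(j) {
    sig2 <- 1 / stats::rgamma(n_draws, shape = (n - 1) / 2, rate = A / 2)
    b1 <- sqrt(sig2) * prior$sigma_a[j] * stats::rnorm(n_draws)
    b2 <- sqrt(sig2) * prior$sigma_d[j] * stats::rnorm(n_draws)
    # A - RSS(beta) = 2 u'beta - beta' M beta
    expo <- (2 * (u1 * b1 + u2 * b2) -
               (M11 * b1^2 + 2 * M12 * b1 * b2 + M22 * b2^2)) / (2 * sig2)
    m <- max(expo)
    log10(mean(exp(expo - m))) + m / log(10)
  }, numeric(1L))
  mx <- max(per_grid)
  log10(sum(prior$weights * 10^(per_grid - mx))) + mx
}

# Brute-force padded point-in-interval overlap (0-based half-open + pad).
brute_overlap <- function(pos, chrom, iv_chrom, iv_start, iv_end, pad) {
  vapply(seq_along(pos), function(i) {
    any(iv_chrom == chrom[i] &
          pos[i] >= iv_start - pad & pos[i] < iv_end + pad)
  }, logical(1L))
}

# Brute-force intervening-midpoint test.
brute_intervening <- function(snp, tss, iv_start, iv_end) {
  if (snp == tss) return(FALSE)
  lo <- min(snp, tss); hi <- max(snp, tss)
  mids <- floor((iv_start + iv_end) / 2)
  any(mids > lo & mids < hi)
}

# Exact two-sided Fisher p by hypergeometric enumeration for a 2x2 table
# [[a, b], [c, d]]: sum of point probabilities <= that of the observed table.
enum_fisher_p <- function(a, b, c, d) {
  m <- a + b; k <- a + c
  support <- max(0L, k - (c + d)):min(m, k)
  probs <- stats::dhyper(support, m, c + d, k)
  sum(probs[probs <= stats::dhyper(a, m, c + d, k) * (1 + 1e-7)])
}

# Exact two-sided binomial McNemar p by enumeration over discordant counts.
enum_mcnemar_p <- function(b10, b01) {
  nd <- b10 + b01
  if (nd == 0L) return(1)
  probs <- stats::dbinom(0:nd, nd, 0.5)
  min(1, sum(probs[probs <= probs[b10 + 1L] * (1 + 1e-7)]))
}

# Logistic regression log-likelihood maximised by a generic optimizer.
optim_logistic <- function(X, yv) {
  nll <- function(beta) {
    eta <- drop(X %*% beta)
    sum(log1p(exp(-(2 * yv - 1) * eta)))
  }
  fit <- stats::optim(rep(0, ncol(X)), nll, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  fit$par
}
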