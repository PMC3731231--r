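make_geno <- function(dosages) {
  p <- ncol(dosages)
  structure(list(sample_ids = sprintf("s%d", seq_len(nrow(dosages))),
                 snp_ids = sprintf("snp%d", seq_len(p)),
                 chrom = rep("chr1", p), pos = seq_len(p) * 1000L,
                 major = rep("A", p), minor = rep("G", p),
                 maf = colMeans(dosages, na.rm = TRUE) / 2,
                 dosages = dosages),
            class = "genotype_matrix")
}

test_that("HWE filter keeps equilibrium genotypes and removes gross deviation", {
  # (25, 50, 25): exact HWE, chi-square 0
  g_hwe <- rep(c(0, 1, 2), c(25, 50, 25))
  expect_equal(eqtlcre:::hwe_chisq_p(g_hwe), 1, tolerance = 1e-12)
  # (50, 0, 50): chi-square = 100
  g_bad <- rep(c(0, 2), c(50, 50))
  expect_equal(eqtlcre:::hwe_chisq_p(g_bad),
               pchisq(100, 1, lower.tail = FALSE), tolerance = 1e-12)

  dos <- cbind(snpA = g_hwe, snpB = g_bad)
  rownames(dos) <- sprintf("s%d", 1:100)
  filt <- filter_genotypes(make_geno(dos), hwe_alpha = 1e-4)
  expect_equal(filt$snp_ids, "snp1")

  # no missingness, hwe_alpha = 0: identity
  filt0 <- filter_genotypes(make_geno(dos), hwe_alpha = 0)
  expect_equal(filt0$dosages, dos, ignore_attr = TRUE)
})

test_that("call-rate filtering and mean imputation behave as specified", {
  set.seed(4)
  dos <- matrix(rbinom(600, 2, 0.3), nrow = 60)
  dos[1, ] <- NA                      # sample 1: all missing
  dos[10:12, 2] <- NA                 # snp 2: a few missing
  dos[-(1:5), 3] <- NA                # snp 3: mostly missing
  filt <- filter_genotypes(make_geno(dos), sample_call_rate_min = 0.5,
                           snp_call_rate_min = 0.9, hwe_alpha = 0)
  expect_equal(nrow(filt$dosages), 59)        # sample 1 dropped
  expect_false("snp3" %in% filt$snp_ids)      # low call-rate SNP dropped
  expect_false(anyNA(filt$dosages))
  j <- match("snp2", filt$snp_ids)
  observed <- dos[-1, 2][!is.na(dos[-1, 2])]
  expect_equal(unique(filt$dosages[c(9:11) , j]), mean(observed))
  expect_error(filter_genotypes(make_geno(dos), sample_call_rate_min = 1.01),
               "must be")
})

test_that("normalized traits are exact standard-normal quantile sets", {
  set.seed(7)
  raw <- matrix(2^rnorm(600, 8, 2), nrow = 30)
  norm <- normalize_expression(raw, knn_k = 5)
  n <- nrow(norm)
  expected <- qnorm(((1:n) - 0.5) / n)
  for (j in seq_len(ncol(norm))) {
    expect_equal(sort(norm[, j]), expected, tolerance = 1e-12)
  }

  # monotone structure (common profile plus per-sample shift): the pipeline
  # preserves within-trait sample order end to end
  base <- sort(2^rnorm(20, 8, 1))
  shift <- rnorm(30)
  raw2 <- 2^(outer(shift, log2(base), `+`))
  norm2 <- normalize_expression(raw2)
  for (j in c(1, 10, 20)) {
    expect_equal(cor(raw2[, j], norm2[, j], method = "spearman"), 1)
  }
  expect_error(normalize_expression(raw[1, , drop = FALSE]), "at least 2")
})

test_that("k-NN imputation matches the brute-force nearest-columns oracle", {
  set.seed(8)
  n <- 40; p <- 25; k <- 10
  x <- matrix(rnorm(n * p), n, p)
  x[, 1:5] <- x[, 1:5] + rnorm(n)     # correlated group
  masked <- x
  holes <- cbind(sample(n, 30, TRUE), sample(p, 30, TRUE))
  masked[holes] <- NA
  imp <- eqtlcre:::knn_impute(masked, k = k)
  # oracle: nested loops, Euclidean over complete pairs
  for (r in seq_len(nrow(holes))) {
    i <- holes[r, 1]; j <- holes[r, 2]
    d <- rep(Inf, p)
    for (l in seq_len(p)) {
      if (l == j) next
      ok <- !is.na(masked[, j]) & !is.na(masked[, l])
      if (any(ok)) d[l] <- sqrt(mean((masked[ok, j] - masked[ok, l])^2))
    }
    nn <- order(d)[1:k]
    expect_equal(imp[i, j], mean(masked[i, nn], na.rm = TRUE),
                 tolerance = 1e-12)
  }
})

test_that("PC removal follows the PVE-difference rule and recovers factors", {
  set.seed(9)
  n <- 120; p <- 150
  f <- rnorm(n)                        # one strong planted factor
  load <- rnorm(p, sd = 1)
  raw <- outer(f, load) + matrix(rnorm(n * p, sd = 0.7), n, p)
  colnames(raw) <- paste0("t", 1:p)
  q <- normalize_expression(raw, log_transform = FALSE)

  out <- remove_pcs(q, pve_delta = 0.01)
  expect_equal(out$report$n_removed, 1L)
  resid_cor <- apply(out$residuals, 2, function(col) cor(col, f))
  expect_lt(mean(abs(resid_cor)), 0.1)
  # the removed PC is essentially the planted factor
  pc1 <- prcomp(q, center = TRUE)$x[, 1]
  expect_gt(abs(cor(pc1, f)), 0.9)
  expect_true(all(diff(out$report$pve) <= 1e-12))

  # pve_delta = 1: remove nothing; output is the per-trait renormalized input
  out1 <- remove_pcs(q, pve_delta = 1)
  expect_equal(out1$report$n_removed, 0L)
  expect_equal(out1$residuals, apply(q, 2, eqtlcre:::qnorm_transform),
               ignore_attr = TRUE)

  # idempotence: a second pass removes nothing more
  out2 <- remove_pcs(out$residuals, pve_delta = 0.01)
  expect_equal(out2$report$n_removed, 0L)

  expect_error(remove_pcs(q, pve_delta = 0), "> 0")
})

test_that("probe clustering separates anticorrelated probes only", {
  set.seed(10)
  n <- 200
  f <- rnorm(n)
  same1 <- f + 0.3 * rnorm(n)
  same2 <- f + 0.3 * rnorm(n)
  anti <- -f + 0.3 * rnorm(n)
  expr <- cbind(p1 = same1, p2 = anti, q1 = same1, q2 = same2, r1 = f)
  expr <- apply(expr, 2, eqtlcre:::qnorm_transform)
  rownames(expr) <- sprintf("s%d", 1:n)
  map <- c(p1 = "gA", p2 = "gA", q1 = "gB", q2 = "gB", r1 = "gC")
  cl <- cluster_probes(expr, map, max_clusters = 3)

  expect_equal(ncol(cl$gA), 2L)                 # r = -0.9 pair splits
  expect_equal(ncol(cl$gB), 1L)                 # correlated pair stays
  expect_equal(cl$gB[, 1], rowMeans(expr[, c("q1", "q2")]),
               ignore_attr = TRUE)
  expect_equal(ncol(cl$gC), 1L)                 # single probe passthrough
  expect_equal(cl$gC[, 1], expr[, "r1"], ignore_attr = TRUE)

  # two identical probes: one cluster, trait equals either probe
  expr2 <- cbind(a1 = expr[, "p1"], a2 = expr[, "p1"])
  cl2 <- cluster_probes(expr2, c(a1 = "g", a2 = "g"), max_clusters = 3)
  expect_equal(ncol(cl2$g), 1L)
  expect_equal(cl2$g[, 1], expr[, "p1"], ignore_attr = TRUE)

  expect_error(cluster_probes(expr, map, max_clusters = 0), ">= 1")
})

test_that("per-population normalization pools rank-normal populations", {
  set.seed(11)
  x <- matrix(rnorm(200), nrow = 40)
  pops <- rep(c("CEU", "YRI"), each = 20)
  x[pops == "YRI", ] <- x[pops == "YRI", ] + 3   # population shift
  out <- per_population_normalize(x, pops)
  for (p in c("CEU", "YRI")) {
    expect_lt(max(abs(colMeans(out[pops == p, ]))), 1e-8)
  }
  # permuting samples within a population permutes rows identically
  perm <- c(sample(1:20), 21:40)
  out_perm <- per_population_normalize(x[perm, ], pops[perm])
  expect_equal(out_perm, out[perm, ], ignore_attr = TRUE)
  expect_error(per_population_normalize(x, c("a", rep("b", 39))), ">= 2")
})
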