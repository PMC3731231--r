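test_that("LD blocks follow the boundary rule exactly", {
  map <- list(positions = seq(1000, by = 1000, length.out = 7),
              rates = c(0.1, 0.1, 2.0, 0.1, 3.0, 0.1))
  bl <- ld_blocks(map, 0.9)$block
  expect_equal(bl, c(1, 1, 1, 2, 2, 3, 3))
  expect_equal(unname(table(bl)), c(3L, 2L, 2L), ignore_attr = TRUE)

  expect_equal(max(ld_blocks(list(positions = 1:5 * 100,
                                  rates = rep(0.1, 4)), 0.9)$block), 1L)
  # threshold at or below the minimum rate: every SNP its own block
  expect_equal(ld_blocks(list(positions = 1:5 * 100,
                              rates = rep(0.5, 4)), 0.5)$block, 1:5)
  expect_error(ld_blocks(list(positions = numeric(0), rates = numeric(0))),
               "empty")
  expect_error(ld_blocks(map, 0), "> 0")
})

test_that("tier scan recovers planted single eQTLs in the right block", {
  st <- make_study(n_genes = 30, n_samples = 200, r2 = 0.2, seed = 21)
  expr <- make_residuals(st)
  recs <- scan_study(expr, st$geno, st$gm, st$blocks, bf_floor = 0)
  t1 <- recs[recs$tier == 1L, ]
  truth_block <- st$blocks[match(st$truth$snp_id, st$geno$snp_ids)]
  m <- match(st$truth$gene_id, t1$gene_id)
  expect_true(all(!is.na(m)))
  expect_gte(mean(t1$block[m] == truth_block), 0.9)
  # strong signal: the tier-1 UBF is large for nearly all genes
  expect_gte(mean(t1$ubf[m] > 3), 0.9)
})

test_that("tier scan keeps tiers in distinct blocks with conditional BFs", {
  st <- make_study(n_genes = 20, n_samples = 300, r2 = 0.15, n_tiers = 2,
                   seed = 22)
  expr <- make_residuals(st)
  recs <- scan_study(expr, st$geno, st$gm, st$blocks, bf_floor = 0)
  for (g in unique(recs$gene_id)) {
    rr <- recs[recs$gene_id == g, ]
    expect_false(any(duplicated(rr$block)))
  }
  # both planted tiers recovered among the gene's top-2 records
  hits <- vapply(unique(st$truth$gene_id), function(g) {
    tb <- st$blocks[match(st$truth$snp_id[st$truth$gene_id == g],
                          st$geno$snp_ids)]
    rb <- recs$block[recs$gene_id == g & recs$tier <= 2]
    all(tb %in% rb)
  }, logical(1))
  expect_gte(mean(hits), 0.7)
})

test_that("pure-noise genes rarely clear a log10 BF floor of 2", {
  st <- make_study(n_genes = 30, n_samples = 200, r2 = 0, seed = 23)
  expr <- make_residuals(st)
  recs <- scan_study(expr, st$geno, st$gm, st$blocks, bf_floor = 2)
  frac_clean <- 1 - length(unique(recs$gene_id)) / nrow(st$gm)
  expect_gte(frac_clean, 0.9)
})

test_that("conditioning on the causal SNP drains evidence from LD partners", {
  # one causal SNP per block; block-mates in strong LD lose most of their
  # univariate evidence once the causal SNP is conditioned on, and the
  # drop grows with LD
  map <- simulate_recomb_map(30, hotspot_every = 10)
  geno <- simulate_genotypes(300, map, c(0.2, 0.5), 0.9, seed = 41)
  set.seed(42)
  causal <- 5L
  y <- 0.5 * geno$dosages[, causal] + rnorm(300)
  bl <- ld_blocks(map, 0.9)$block
  mates <- setdiff(which(bl == bl[causal]), causal)
  drops <- vapply(mates, function(j) {
    ub <- univariate_log10bf(y, geno$dosages[, j])
    mb <- multivariate_log10bf(y, geno$dosages[, c(causal, j)], focal = 2)
    c(ub - mb, cor(geno$dosages[, causal], geno$dosages[, j])^2)
  }, numeric(2))
  expect_true(all(drops[1, ] > 0))
  # higher LD, larger drop (rank correlation over the block mates)
  expect_gt(cor(drops[1, ], drops[2, ], method = "spearman"), 0.5)
})

test_that("forward stepwise BIC matches the stats::step oracle", {
  set.seed(25)
  n <- 200
  for (rep in 1:5) {
    G <- matrix(rbinom(n * 15, 2, 0.3), n, 15)
    colnames(G) <- paste0("s", 1:15)
    y <- 0.4 * G[, 2] + 0.3 * G[, 9] + rnorm(n)
    mine <- forward_stepwise_bic(y, G, dominance = FALSE)
    df <- data.frame(y = y, G)
    orc <- stats::step(lm(y ~ 1, data = df),
                       scope = formula(paste("~", paste(colnames(G),
                                                        collapse = "+"))),
                       direction = "forward", k = log(n), trace = 0)
    orc_sel <- sort(match(setdiff(names(coef(orc)), "(Intercept)"),
                          colnames(G)))
    expect_identical(sort(mine), orc_sel)
  }
})

test_that("stepwise false-inclusion rate matches the BIC theory oracle", {
  set.seed(26)
  n <- 200
  p <- 50
  # a lone regressor enters iff n*log(RSS0/RSS1) > log(n), i.e. its
  # squared t exceeds t2_min below; under the global null the chance that
  # none of p independent SNPs enters is about (1 - alpha)^p
  t2_min <- (exp(log(n) / n) - 1) * (n - 2)
  alpha <- 2 * pt(-sqrt(t2_min), df = n - 2)
  expected_empty <- (1 - alpha)^p
  empty <- 0L
  reps <- 60
  for (rep in seq_len(reps)) {
    G <- matrix(rbinom(n * p, 2, 0.3), n, p)
    y <- rnorm(n)
    if (length(forward_stepwise_bic(y, G, dominance = FALSE)) == 0L) {
      empty <- empty + 1L
    }
  }
  se <- sqrt(expected_empty * (1 - expected_empty) / reps)
  expect_lt(abs(empty / reps - expected_empty), 3 * se + 0.05)

  # the 2-df per-SNP default is stricter under the null
  empty2 <- 0L
  for (rep in seq_len(reps)) {
    G <- matrix(rbinom(n * p, 2, 0.3), n, p)
    if (length(forward_stepwise_bic(rnorm(n), G)) == 0L) {
      empty2 <- empty2 + 1L
    }
  }
  expect_gt(empty2 / reps, expected_empty)

  # strong independent signals are always included
  hits <- 0L
  for (rep in 1:20) {
    G <- matrix(rbinom(n * 10, 2, 0.3), n, 10)
    y <- 0.6 * G[, 3] + 0.6 * G[, 7] + rnorm(n)
    sel <- forward_stepwise_bic(y, G)
    if (all(c(3L, 7L) %in% sel)) hits <- hits + 1L
  }
  expect_gte(hits / 20, 0.95)

  # single perfect predictor
  G1 <- matrix(rbinom(n * 5, 2, 0.4), n, 5)
  expect_identical(forward_stepwise_bic(G1[, 2], G1), 2L)
})

test_that("permutation FDR is calibrated on null data and bounded", {
  st <- make_study(n_genes = 40, n_samples = 150, r2 = 0, seed = 26)
  expr <- make_residuals(st)
  tab <- permutation_fdr(expr, st$geno, st$gm, st$blocks, seed = 27,
                         max_tiers = 2L)
  expect_true(all(tab$fdr >= 0 & tab$fdr <= 1))
  for (t in unique(tab$tier)) {
    tt <- tab[tab$tier == t, ]
    supported <- tt$n_obs > 0
    expect_true(all(diff(tt$fdr[supported]) <= 1e-12))  # monotone in cutoff
    expect_true(all(diff(tt$n_obs) <= 0))               # counts non-increasing
    expect_true(all(tt$fdr[tt$n_obs >= 20] >= 0.5))
  }
  # FDR=1 reported where nothing is observed
  expect_true(all(tab$fdr[tab$n_obs == 0] == 1))
  # the FDR-10% cutoff is never reached on null data
  expect_identical(fdr_cutoff(tab, 1L, 0.10), Inf)
})

test_that("permutation FDR separates planted signal at the 10% cutoff", {
  st <- make_study(n_genes = 40, n_samples = 150, r2 = 0.3,
                   signal_genes = sprintf("gene%04d", 1:20), seed = 28)
  expr <- make_residuals(st)
  tab <- permutation_fdr(expr, st$geno, st$gm, st$blocks, seed = 29,
                         max_tiers = 2L)
  cut1 <- fdr_cutoff(tab, 1L, 0.10)
  expect_true(is.finite(cut1))
  obs <- attr(tab, "observed")
  passed <- unique(obs$gene_id[obs$tier == 1 & obs$ubf >= cut1])
  signal <- st$truth$gene_id
  expect_gte(mean(signal %in% passed), 0.8)
  null_genes <- setdiff(st$gm$gene_id, signal)
  expect_lte(mean(null_genes %in% passed), 0.2)
})

test_that("stepwise/BIC and the tier scan agree on AH SNP counts", {
  st <- make_study(n_genes = 20, n_samples = 300, r2 = 0.15, n_tiers = 2,
                   seed = 30)
  expr <- make_residuals(st)
  recs <- scan_study(expr, st$geno, st$gm, st$blocks, bf_floor = 2)
  agree <- vapply(unique(st$truth$gene_id), function(g) {
    idx <- eqtlcre:::cis_snp_index(st$gm[st$gm$gene_id == g, ], st$geno)
    k_fwd <- length(forward_stepwise_bic(expr[, g],
                                         st$geno$dosages[, idx]))
    k_tier <- sum(recs$gene_id == g)
    k_fwd == k_tier
  }, logical(1))
  expect_gte(mean(agree), 0.55)
})
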